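#' Plot mean detection AUROC against noise factor
#'
#' Housekeeping pairs and the random-pair null, with standard-error
#' ribbons. The gap between the two curves (and the per-factor Wilcoxon
#' p-values in the report summary) is the recommended reading of the
#' analysis: high pair AUROC with low random AUROC indicates a clean,
#' replicable experiment; both curves high indicates systematic artifact.
#'
#' @param object A `pairqc_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pairqc_report
#' @export
autoplot.pairqc_report <- function(object, ...) {
  d <- object$summary |>
    tidyr::pivot_longer(
      cols = -c("noise_factor", "n_runs", "p_wilcox"),
      names_to = c(".value", "pair_kind"),
      names_pattern = "(mean_auroc|se_auroc)_(.*)"
    ) |>
    dplyr::mutate(pair_kind = dplyr::recode(
      .data$pair_kind,
      pairs = "housekeeping pairs", random = "random pairs"
    ))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = 100 * .data$noise_factor, y = .data$mean_auroc,
      colour = .data$pair_kind, fill = .data$pair_kind
    )
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_auroc - .data$se_auroc,
        ymax = .data$mean_auroc + .data$se_auroc
      ),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(
      x = "noise factor (%)", y = "mean detection AUROC",
      colour = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot housekeeping-pair AUROC against random-pair AUROC
#'
#' One point per noise factor on the pairs-vs-null plane. Points well
#' above the identity line are factors at which biological co-expression,
#' not technical artifact, detects the perturbation.
#'
#' @param report A `pairqc_report`.
#' @return A ggplot.
#' @export
plot_pair_null <- function(report) {
  ggplot2::ggplot(
    report$summary,
    ggplot2::aes(
      x = .data$mean_auroc_random, y = .data$mean_auroc_pairs,
      label = paste0(100 * .data$noise_factor, "%")
    )
  ) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::coord_cartesian(xlim = c(0.4, 1), ylim = c(0.4, 1)) +
    ggplot2::labs(
      x = "mean AUROC, random pairs", y = "mean AUROC, housekeeping pairs"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a replicability coverage curve
#'
#' @param object A `pairqc_coverage` tibble from
#'   [coverage_vs_sample_size()].
#' @param ... Unused.
#' @return A ggplot of the fraction of replicably measured genes against
#'   sample size.
#' @method autoplot pairqc_coverage
#' @export
autoplot.pairqc_coverage <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$coverage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "number of samples",
      y = "fraction of genes with significant self-correlation"
    ) +
    ggplot2::theme_minimal()
}
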