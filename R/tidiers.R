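#' Tidy a replicability report
#'
#' @param x A `pairqc_report` from [run_experiment()].
#' @param type `"summary"` (default): one row per noise factor with mean
#'   and SE AUROCs for housekeeping and random pairs and the Wilcoxon
#'   p-value; `"runs"`: the full run log, one row per perturbation run.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pairqc_report
#' @export
tidy.pairqc_report <- function(x, type = c("summary", "runs"), ...) {
  type <- match.arg(type)
  if (type == "summary") x$summary else x$runs
}

#' One-row summary of a replicability report
#'
#' @param x A `pairqc_report`.
#' @param ... Unused.
#' @return A one-row tibble: experiment dimensions, the headline noise
#'   estimate (first target AUROC), and the smallest per-factor Wilcoxon
#'   p-value.
#' @method glance pairqc_report
#' @export
glance.pairqc_report <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    n_samples = p$n_samples,
    n_genes = p$n_genes,
    n_pairs = p$n_pairs,
    n_random = p$n_random,
    repeats = p$repeats,
    mode = p$mode,
    noise_estimate = x$noise_estimates$noise_estimate[1L],
    target_auroc = x$noise_estimates$target_auroc[1L],
    min_p_wilcox = suppressWarnings(min(x$summary$p_wilcox, na.rm = TRUE)),
    n_warnings = length(x$warnings)
  )
}
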