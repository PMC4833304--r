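# Gene-level replicability across replicate experiments: self-correlations,
# significance, coverage extrapolation, self-ranks, filter summaries.

align_replicates <- function(x, y) {
  mx <- check_expr_matrix(as_expr_matrix(x, "x"), "x")
  my <- check_expr_matrix(as_expr_matrix(y, "y"), "y")
  if (!identical(dim(mx), dim(my)) ||
      !identical(rownames(mx), rownames(my)) ||
      !identical(colnames(mx), colnames(my))) {
    abort("`x` and `y` must be aligned gene-by-gene and sample-by-sample.")
  }
  list(x = mx, y = my)
}

# Row-wise Pearson correlation of two aligned matrices; constant rows -> NA.
row_correlations <- function(mx, my) {
  xc <- mx - rowMeans(mx)
  yc <- my - rowMeans(my)
  sx <- rowSums(xc^2)
  sy <- rowSums(yc^2)
  out <- rowSums(xc * yc) / sqrt(sx * sy)
  out[sx == 0 | sy == 0] <- NA_real_
  out
}

#' Gene-level replicability: each gene's self-correlation across replicates
#'
#' For each gene, the correlation between its expression profile in
#' experiment `x` and in the replicate experiment `y`, across the shared
#' samples. This — not sample-sample correlation — is the operative
#' measure of how replicable conditional variation in expression is:
#' sample-sample correlations are inflated by genes sitting in disjoint
#' dynamic ranges, and can stay high even when no individual gene's
#' variation replicates.
#'
#' @param x,y Aligned expression tables (same genes, same samples).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Named numeric vector of per-gene correlations in `[-1, 1]`;
#'   genes constant in either experiment are `NA`.
#' @export
gene_self_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  al <- align_replicates(x, y)
  if (ncol(al$x) < 3L) abort("Need at least 3 samples per gene.")
  if (method == "spearman") {
    # constant rows must stay NA even though their ranks are constant too
    con <- row_correlations(al$x, al$y)
    r <- row_correlations(row_midranks(al$x), row_midranks(al$y))
    r[is.na(con)] <- NA_real_
    r
  } else {
    row_correlations(al$x, al$y)
  }
}

correlation_statistic <- function(r, n, method = c("fisher_z", "t"),
                                  inflation = 1.06) {
  method <- match.arg(method)
  if (method == "fisher_z") {
    0.5 * log((1 + r) / (1 - r)) * sqrt(n - 3) / inflation
  } else {
    r * sqrt(n - 2) / sqrt(1 - r^2)
  }
}

#' Significance of a replicability correlation
#'
#' Converts correlations to one-sided (upper-tail: positive replicability)
#' p-values, via either the Fisher z transform,
#' `z = atanh(r) * sqrt(n - 3) / 1.06` (the 1.06 variance-inflation
#' divisor is retained as published; set `inflation = 1` for the textbook
#' statistic), referred to the standard normal, or the t statistic
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @param n Sample count (>= 4).
#' @param method `"fisher_z"` (default) or `"t"`.
#' @param alternative `"greater"` (default: one-sided positive
#'   replicability) or `"two.sided"`.
#' @param inflation Divisor applied to the Fisher z statistic (default
#'   1.06).
#' @return p-value(s) in `(0, 1]`; `|r| = 1` returns the smallest
#'   representable double with a warning, `NA` stays `NA`.
#' @export
correlation_significance <- function(r, n, method = c("fisher_z", "t"),
                                     alternative = c("greater", "two.sided"),
                                     inflation = 1.06) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  check_scalar_number(n, "n", lower = 4)
  if (any(abs(r) > 1, na.rm = TRUE)) abort("`r` must lie in [-1, 1].")
  degenerate <- !is.na(r) & abs(r) == 1
  if (any(degenerate)) {
    warn("Correlations of exactly +/-1 reported at the smallest representable p-value.")
  }
  stat <- correlation_statistic(r, n, method, inflation)
  p <- if (method == "fisher_z") {
    pnorm(stat, lower.tail = FALSE)
  } else {
    pt(stat, df = n - 2, lower.tail = FALSE)
  }
  if (alternative == "two.sided") p <- 2 * pmin(p, 1 - p)
  p[degenerate & r > 0] <- .Machine$double.xmin
  p[degenerate & r < 0] <- if (alternative == "two.sided") {
    .Machine$double.xmin
  } else {
    1
  }
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Adjust p-values for multiple testing
#'
#' Holm step-down (family-wise error, the default used for replicability
#' calls) or Benjamini-Hochberg step-up (FDR), via [stats::p.adjust()].
#'
#' @param p Numeric p-values in `[0, 1]` (`NA` allowed and propagated).
#' @param method `"holm"` (default) or `"bh"`.
#' @return Adjusted q-values, same length and order.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("`p` must lie in [0, 1].")
  p.adjust(p, method = c(holm = "holm", bh = "BH")[[method]])
}

#' Fraction of genes with replicable expression as sample size varies
#'
#' Holding the observed distribution of self-correlations fixed, vary the
#' sample count `n` inside the t statistic, recompute adjusted p-values,
#' and report the fraction of genes significant at `alpha` for each `n` —
#' an extrapolation of how much of the transcriptome an experiment of that
#' size would measure replicably.
#'
#' @param corrs Per-gene correlations (e.g. [gene_self_correlation()]).
#' @param n_grid Integer sample sizes (each >= 4).
#' @param alpha Significance level on the adjusted p-values (default 0.05).
#' @param adjust `"holm"` (default) or `"bh"`.
#' @param count_undefined Count `NA` correlations in the denominator as
#'   never-significant (`FALSE` by default: they are dropped entirely).
#' @return A tibble (`n`, `n_significant`, `n_genes`, `coverage`) of class
#'   `pairqc_coverage`.
#' @export
coverage_vs_sample_size <- function(corrs, n_grid, alpha = 0.05,
                                    adjust = c("holm", "bh"),
                                    count_undefined = FALSE) {
  adjust <- match.arg(adjust)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  n_total <- if (count_undefined) length(corrs) else sum(!is.na(corrs))
  corrs <- corrs[!is.na(corrs)]
  if (!length(corrs)) abort("`corrs` contains no defined correlations.")
  if (any(n_grid < 4)) abort("Every sample size in `n_grid` must be >= 4.")
  rows <- purrr::map(sort(unique(as.integer(n_grid))), function(n) {
    q <- adjust_pvalues(
      suppressWarnings(correlation_significance(corrs, n, method = "t")),
      adjust
    )
    tibble::tibble(
      n = n, n_significant = sum(q < alpha), n_genes = n_total,
      coverage = sum(q < alpha) / n_total
    )
  })
  structure(dplyr::bind_rows(rows),
            class = c("pairqc_coverage", class(tibble::tibble())))
}

#' Rank of each gene's self-correlation against all other genes
#'
#' For each gene in `x`, correlate its profile with every gene profile in
#' the replicate `y`; the self-rank is the fraction of genes in `y` whose
#' correlation to it is at most the self-correlation. A self-rank of 1
#' means the gene's best match in the replicate is itself — the behaviour
#' a replicable measurement should show.
#'
#' @inheritParams gene_self_correlation
#' @return Named numeric vector of self-ranks in `(0, 1]`; `NA` for
#'   constant genes.
#' @export
self_correlation_rank <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  al <- align_replicates(x, y)
  mx <- al$x
  my <- al$y
  con <- apply(mx, 1L, var) == 0 | apply(my, 1L, var) == 0
  if (method == "spearman") {
    mx <- row_midranks(mx)
    my <- row_midranks(my)
  }
  cc <- suppressWarnings(cor(t(mx), t(my)))
  self <- diag(cc)
  out <- vapply(seq_len(nrow(cc)), function(i) {
    row <- cc[i, ]
    ok <- !is.na(row)
    if (!ok[i]) return(NA_real_)
    sum(row[ok] <= self[i]) / sum(ok)
  }, numeric(1))
  out[con] <- NA_real_
  names(out) <- rownames(al$x)
  out
}

#' Absolute log2 fold change between two sample groups
#'
#' `FC = |log2(mean_a / mean_b)|` per gene. When no groups are given, the
#' first half of the samples is treated as one condition and the second
#' half as the other (the convention of a balanced treated/untreated
#' design).
#'
#' @param x Expression table or matrix.
#' @param group_a,group_b Disjoint nonempty sample name/index sets.
#' @return Named numeric vector of per-gene absolute log2 fold changes;
#'   genes with a zero group mean are `NA`.
#' @export
fold_change <- function(x, group_a = NULL, group_b = NULL) {
  m <- check_expr_matrix(as_expr_matrix(x))
  n <- ncol(m)
  if (is.null(group_a) && is.null(group_b)) {
    group_a <- seq_len(floor(n / 2))
    group_b <- seq.int(floor(n / 2) + 1L, n)
  }
  ia <- resolve_samples(m, group_a)
  ib <- resolve_samples(m, group_b)
  if (length(intersect(ia, ib))) abort("`group_a` and `group_b` must be disjoint.")
  ma <- rowMeans(m[, ia, drop = FALSE])
  mb <- rowMeans(m[, ib, drop = FALSE])
  out <- abs(log2(ma / mb))
  out[ma == 0 | mb == 0] <- NA_real_
  out
}

#' Per-gene replicability table for a pair of replicate experiments
#'
#' One row per gene: self-correlation, one-sided p-value, adjusted
#' q-value, self-rank among all genes of the replicate, log2 mean
#' expression, and absolute log2 fold change between the two sample
#' groups of `x`.
#'
#' @inheritParams gene_self_correlation
#' @param method Correlation method (default `"spearman"`).
#' @param sig_method `"fisher_z"` (default) or `"t"` for the p-values.
#' @param adjust `"holm"` (default) or `"bh"`.
#' @param group_a,group_b Sample groups for the fold change; default
#'   half/half (see [fold_change()]).
#' @param self_rank Also compute [self_correlation_rank()] (all-pairs
#'   correlation; quadratic in gene count). Default `TRUE`.
#' @return A tibble with columns `gene_id`, `correlation`, `p_value`,
#'   `q_value`, `self_rank`, `mean_expression`, `fold_change`.
#' @export
replicability_table <- function(x, y, method = c("spearman", "pearson"),
                                sig_method = c("fisher_z", "t"),
                                adjust = c("holm", "bh"),
                                group_a = NULL, group_b = NULL,
                                self_rank = TRUE) {
  method <- match.arg(method)
  sig_method <- match.arg(sig_method)
  adjust <- match.arg(adjust)
  al <- align_replicates(x, y)
  n <- ncol(al$x)
  corr <- gene_self_correlation(al$x, al$y, method)
  p <- suppressWarnings(correlation_significance(corr, n, sig_method))
  tibble::tibble(
    gene_id = rownames(al$x),
    correlation = unname(corr),
    p_value = unname(p),
    q_value = unname(adjust_pvalues(p, adjust)),
    self_rank = if (self_rank) {
      unname(self_correlation_rank(al$x, al$y, method))
    } else {
      NA_real_
    },
    mean_expression = unname(log2((rowMeans(al$x) + rowMeans(al$y)) / 2)),
    fold_change = unname(fold_change(al$x, group_a, group_b))
  )
}

#' Summarise replicability before and after expression/fold-change filters
#'
#' Recapitulates the heuristic quality filters — discard the
#' lowest-expressing fraction of genes and those with small fold changes —
#' and reports how the replicable fraction responds: gene counts, the
#' fraction of genes at or above the correlation threshold, and mean
#' correlation, before and after filtering, plus the fraction of
#' sub-threshold genes within mean-expression and fold-change bins.
#'
#' @param table A [replicability_table()] result.
#' @param corr_threshold Correlation defining "replicable" (default 0.9).
#' @param expr_quantile Fraction of lowest-expressing genes to discard
#'   (default 1/3).
#' @param fc_threshold Minimum absolute log2 fold change kept (default 1).
#' @param n_bins Bins for the expression/fold-change breakdowns.
#' @return A list of class `pairqc_filter_summary`: `before`, `after`
#'   (counts, replicable fraction, mean correlation), `by_expression`,
#'   `by_fold_change` (binned sub-threshold fractions), and the thresholds.
#' @export
filter_summary <- function(table, corr_threshold = 0.9, expr_quantile = 1 / 3,
                           fc_threshold = 1, n_bins = 10L) {
  check_scalar_number(corr_threshold, "corr_threshold", lower = -1, upper = 1)
  check_scalar_number(expr_quantile, "expr_quantile", lower = 0, upper = 1)
  check_scalar_number(fc_threshold, "fc_threshold", lower = 0)
  tbl <- table[!is.na(table$correlation), , drop = FALSE]
  summarise_set <- function(d) {
    if (!nrow(d)) {
      return(tibble::tibble(
        n_genes = 0L, fraction_replicable = NA_real_,
        mean_correlation = NA_real_
      ))
    }
    tibble::tibble(
      n_genes = nrow(d),
      fraction_replicable = mean(d$correlation >= corr_threshold),
      mean_correlation = mean(d$correlation)
    )
  }
  expr_cut <- quantile(tbl$mean_expression, expr_quantile, na.rm = TRUE,
                       names = FALSE)
  keep <- !is.na(tbl$mean_expression) & tbl$mean_expression >= expr_cut &
    !is.na(tbl$fold_change) & tbl$fold_change >= fc_threshold
  after <- tbl[keep, , drop = FALSE]
  if (!nrow(after)) {
    warn("The filters remove every gene; post-filter fractions are undefined.")
  }
  bin_fraction <- function(value) {
    d <- tbl[!is.na(value), , drop = FALSE]
    v <- value[!is.na(value)]
    if (!nrow(d)) return(tibble::tibble())
    bins <- cut(v, breaks = unique(quantile(v, seq(0, 1, length.out = n_bins + 1L))),
                include.lowest = TRUE)
    d |>
      dplyr::mutate(bin = bins, midpoint = v) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(
        n_genes = dplyr::n(),
        midpoint = mean(.data$midpoint),
        fraction_subthreshold = mean(.data$correlation < corr_threshold),
        .groups = "drop"
      )
  }
  structure(
    list(
      before = summarise_set(tbl),
      after = summarise_set(after),
      by_expression = bin_fraction(tbl$mean_expression),
      by_fold_change = bin_fraction(tbl$fold_change),
      thresholds = list(
        corr_threshold = corr_threshold, expr_quantile = expr_quantile,
        fc_threshold = fc_threshold
      )
    ),
    class = "pairqc_filter_summary"
  )
}

#' @export
print.pairqc_filter_summary <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf(
    "Replicability filter summary (replicable: corr >= %g; drop bottom %.0f%% expression, |log2 FC| < %g)\n",
    th$corr_threshold, 100 * th$expr_quantile, th$fc_threshold
  ))
  cat("Before:\n")
  print(as.data.frame(x$before), row.names = FALSE, digits = 4)
  cat("After:\n")
  print(as.data.frame(x$after), row.names = FALSE, digits = 4)
  invisible(x)
}
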