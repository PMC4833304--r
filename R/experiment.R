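# Orchestration: repeated perturb -> score -> AUROC runs across noise
# factors, housekeeping pairs vs a random-pair null, summary report.

# Precompute everything reusable across runs on one experiment.
prep_experiment <- function(m) {
  list(
    m = m,
    sorted = t(apply(m, 1L, sort)),
    ranks = row_midranks(m),
    var_genes = variable_genes(m)
  )
}

# Index-based random-pair draw against a precomputed variable-gene list and
# numeric exclusion keys; the fast path used inside repeated runs
# (sample_random_pairs() is the validated public equivalent).
draw_random_pairs <- function(var_genes, n_pairs, excl_keys) {
  g <- length(var_genes)
  total <- choose(g, 2) - length(excl_keys)
  if (n_pairs > total) {
    abort(sprintf(
      "Requested %d random pairs but only %.0f distinct pairs are available.",
      n_pairs, total
    ))
  }
  keys <- numeric(0)
  while (length(keys) < n_pairs) {
    need <- n_pairs - length(keys)
    i <- sample.int(g, 2L * need + 8L, replace = TRUE)
    j <- sample.int(g, 2L * need + 8L, replace = TRUE)
    ok <- i != j
    k <- pmin(i[ok], j[ok]) * g + pmax(i[ok], j[ok])
    k <- k[!duplicated(k) & !(k %in% keys) & !(k %in% excl_keys)]
    keys <- c(keys, k[seq_len(min(length(k), need))])
  }
  ia <- keys %/% g
  ib <- keys %% g
  swap <- ib == 0
  ib[swap] <- g
  ia[swap] <- ia[swap] - 1L
  new_pair_table(var_genes[ia], var_genes[ib], "random")
}

pair_excl_keys <- function(pairs, var_genes) {
  if (is.null(pairs)) return(numeric(0))
  g <- length(var_genes)
  ia <- match(pairs$gene_a, var_genes)
  ib <- match(pairs$gene_b, var_genes)
  ok <- !is.na(ia) & !is.na(ib)
  unique(pmin(ia[ok], ib[ok]) * g + pmax(ia[ok], ib[ok]))
}

# One perturb/score/AUROC run. All randomness (target choice, shifts, the
# random-pair draw when `random_pairs` is NULL) comes from `seed`.
run_once <- function(prep, pairs, random_pairs, noise_factor, mode, seed,
                     n_random = nrow(pairs), shift = "signed",
                     direction = "both", studentize = "external",
                     excl_keys = pair_excl_keys(pairs, prep$var_genes)) {
  m <- prep$m
  n <- ncol(m)
  withr::with_seed(seed, {
    targets <- if (mode == "single_sample") {
      sample.int(n, 1L)
    } else {
      sample.int(n, max(1L, floor(n / 2)))
    }
    if (is.null(random_pairs)) {
      random_pairs <- draw_random_pairs(prep$var_genes, n_random, excl_keys)
    }
    mp <- perturb_matrix(m, noise_factor, targets, shift,
                         sorted = prep$sorted, ranks = prep$ranks)
    genes <- unique(c(pairs$gene_a, pairs$gene_b,
                      random_pairs$gene_a, random_pairs$gene_b))
    ranked <- row_midranks(mp[genes, , drop = FALSE])
    sc_p <- aggregate_scores(pair_rank_scores(ranked, pairs, direction, studentize))
    sc_r <- aggregate_scores(pair_rank_scores(ranked, random_pairs, direction, studentize))
    tibble::tibble(
      noise_factor = noise_factor,
      seed = seed,
      perturbed = list(targets),
      auroc_pairs = auroc(sc_p, targets),
      auroc_random = auroc(sc_r, targets)
    )
  })
}

#' One perturbation run: inject noise, score, compute detection AUROCs
#'
#' Picks target sample(s) at random, perturbs them with
#' [perturb_samples()]'s noise model, scores every sample against both the
#' housekeeping pair set and the random null set on the same perturbed
#' matrix, and returns the two detection AUROCs.
#'
#' @param x Expression table or matrix.
#' @param pairs Housekeeping [pair_table] (filtered with [filter_pairs()]
#'   if needed).
#' @param noise_factor Noise factor in `[0, 1]`.
#' @param random_pairs Optional pre-drawn random [pair_table]; when `NULL`
#'   an equal-sized set is drawn within the run.
#' @param mode `"single_sample"` perturbs one sample (leave-one-out
#'   flavour); `"half_samples"` perturbs a random half, each independently
#'   (the 2-fold, condition-confounded scenario).
#' @param seed Integer seed; the run is a pure function of its inputs.
#' @param shift,direction,studentize Passed to [perturb_samples()] /
#'   [pair_outlier_scores()].
#' @return One-row tibble: `noise_factor`, `seed`, `perturbed` (list
#'   column of target indices), `auroc_pairs`, `auroc_random`.
#' @export
run_single <- function(x, pairs, noise_factor,
                       random_pairs = NULL,
                       mode = c("single_sample", "half_samples"),
                       seed = 1L, shift = c("signed", "one_sided"),
                       direction = c("both", "yx", "xy"),
                       studentize = c("external", "internal")) {
  mode <- match.arg(mode)
  shift <- match.arg(shift)
  direction <- match.arg(direction)
  studentize <- match.arg(studentize)
  m <- check_expr_matrix(as_expr_matrix(x))
  check_scalar_number(noise_factor, "noise_factor", lower = 0, upper = 1)
  if (ncol(m) < 10L) {
    warn(sprintf(
      "Experiment has %d samples; at least 10 are recommended for a meaningful analysis.",
      ncol(m)
    ))
  }
  pairs <- filter_pairs(pairs, m, min_pairs = 0L)
  run_once(prep_experiment(m), pairs, random_pairs, noise_factor, mode,
           as.integer(seed), shift = shift, direction = direction,
           studentize = studentize)
}

#' Estimate experiment replicability across a grid of noise factors
#'
#' The headline analysis: for each noise factor, `repeats` independent
#' perturbation runs are performed ([run_single()]); the per-factor mean
#' detection AUROCs of the housekeeping pairs and of the random-pair null
#' are reported together with standard errors and a two-sided Wilcoxon
#' rank-sum p-value comparing the two per-run AUROC distributions. The
#' noise level detectable at `target_auroc` is then interpolated from the
#' mean curve ([estimate_noise_level()]) as the experiment's quality
#' metric: experiments in which even small injected perturbations are
#' detected show pristine co-expression (low intrinsic noise), while
#' experiments where large perturbations pass unnoticed were noisy to
#' begin with. Recommended reading of the result: the pairs AUROC, the
#' random AUROC and the p-value at a noise factor in the 5-25% range.
#'
#' @param x Expression table or matrix (>= 10 samples recommended).
#' @param pairs Housekeeping [pair_table].
#' @param noise_factors Noise-factor grid in `[0, 1]`.
#' @param repeats Runs per factor (100 by default; 1000 recommended for
#'   final reports).
#' @param mode,shift,direction,studentize See [run_single()].
#' @param seed Master seed; per-run seeds are derived deterministically, so
#'   the full report is reproducible and independent of execution order.
#' @param n_random Size of the random null set (default: same as the
#'   filtered pair set).
#' @param redraw_random Redraw the random set each run (default `TRUE`,
#'   averaging out any one null set's idiosyncrasy); `FALSE` fixes one set
#'   for strict repeat comparability.
#' @param exclude_pairs_from_random Exclude the housekeeping pairs
#'   themselves from the random draw (default `TRUE`).
#' @param target_auroc AUROC level(s) at which to interpolate the noise
#'   estimate; the first is the headline estimate.
#' @return A `pairqc_report` object; see [tidy.pairqc_report()],
#'   [glance.pairqc_report()], [autoplot.pairqc_report()] and
#'   [write_report()].
#' @examples
#' sim <- make_coexpressed_dataset(
#'   n_samples = 16, n_pairs = 40, pair_rank_correlation = 0.9,
#'   n_background_genes = 40, seed = 1
#' )
#' rep <- run_experiment(sim$expr, sim$pairs,
#'   noise_factors = c(0, 0.25, 1), repeats = 5, seed = 1
#' )
#' tidy(rep)
#' @export
run_experiment <- function(x, pairs,
                           noise_factors = c(0, 0.01, 0.05, 0.1, 0.25, 0.5, 1),
                           repeats = 100L,
                           mode = c("single_sample", "half_samples"),
                           seed = 1L,
                           n_random = NULL,
                           redraw_random = TRUE,
                           exclude_pairs_from_random = TRUE,
                           target_auroc = c(0.8, 0.6),
                           shift = c("signed", "one_sided"),
                           direction = c("both", "yx", "xy"),
                           studentize = c("external", "internal")) {
  mode <- match.arg(mode)
  shift <- match.arg(shift)
  direction <- match.arg(direction)
  studentize <- match.arg(studentize)
  m <- check_expr_matrix(as_expr_matrix(x))
  if (any(noise_factors < 0 | noise_factors > 1)) {
    abort("`noise_factors` must lie in [0, 1].")
  }
  if (repeats < 1L) abort("`repeats` must be >= 1.")
  warnings_log <- character(0)
  if (ncol(m) < 10L) {
    msg <- sprintf(
      "Experiment has %d samples; at least 10 are recommended for a meaningful analysis.",
      ncol(m))
    warn(msg)
    warnings_log <- c(warnings_log, msg)
  }
  pairs <- withCallingHandlers(
    filter_pairs(pairs, m),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (is.null(n_random)) n_random <- nrow(pairs)
  exclude <- if (exclude_pairs_from_random) pairs else NULL

  seeds <- derive_seeds(seed, length(noise_factors) * repeats + 1L)
  fixed_random <- if (!redraw_random) {
    sample_random_pairs(m, n_random, exclude = exclude, seed = seeds[1L])
  }
  prep <- prep_experiment(m)
  excl_keys <- pair_excl_keys(exclude, prep$var_genes)

  grid <- tidyr::expand_grid(
    noise_factor = noise_factors,
    run = seq_len(repeats)
  )
  runs <- purrr::pmap(
    list(grid$noise_factor, seq_len(nrow(grid))),
    function(f, k) {
      run_once(prep, pairs, fixed_random, f, mode, seeds[k + 1L],
               n_random = n_random, shift = shift, direction = direction,
               studentize = studentize, excl_keys = excl_keys)
    }
  )
  runs <- dplyr::bind_cols(
    dplyr::select(grid, "run"),
    dplyr::bind_rows(runs)
  )
  runs <- dplyr::relocate(runs, "noise_factor")

  if (repeats < 2L) {
    warnings_log <- c(
      warnings_log,
      "repeats = 1: Wilcoxon p-values and standard errors not computed."
    )
  }
  summary <- runs |>
    dplyr::group_by(.data$noise_factor) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_auroc_pairs = mean(.data$auroc_pairs),
      se_auroc_pairs = sd_or_na(.data$auroc_pairs),
      mean_auroc_random = mean(.data$auroc_random),
      se_auroc_random = sd_or_na(.data$auroc_random),
      p_wilcox = if (dplyr::n() >= 2L) {
        wilcoxon_rank_sum(.data$auroc_pairs, .data$auroc_random)
      } else {
        NA_real_
      },
      .groups = "drop"
    )

  report <- structure(
    list(
      summary = summary,
      runs = runs,
      noise_estimates = NULL,
      params = list(
        n_samples = ncol(m), n_genes = nrow(m), n_pairs = nrow(pairs),
        n_random = n_random, noise_factors = noise_factors,
        repeats = repeats, mode = mode, seed = seed,
        redraw_random = redraw_random, shift = shift,
        direction = direction, studentize = studentize,
        target_auroc = target_auroc
      ),
      warnings = warnings_log
    ),
    class = "pairqc_report"
  )
  report$noise_estimates <- tibble::tibble(
    target_auroc = target_auroc,
    noise_estimate = vapply(
      target_auroc,
      function(t) quiet_noise_estimate(report, t),
      numeric(1)
    )
  )
  report
}

sd_or_na <- function(x) if (length(x) >= 2L) sd(x) / sqrt(length(x)) else NA_real_

quiet_noise_estimate <- function(report, target) {
  tryCatch(
    suppressWarnings(estimate_noise_level(report, target)),
    error = function(e) NA_real_
  )
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Compares two AUROC (or any) distributions. Exact enumeration is used
#' for small untied samples and the normal approximation with tie
#' correction otherwise (via [stats::wilcox.test()]); two samples that are
#' entirely tied give p = 1.
#'
#' @param a,b Nonempty numeric vectors.
#' @return A p-value in `(0, 1]`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) abort("`a` and `b` must be nonempty.")
  pooled <- c(a, b)
  if (all(pooled == pooled[1L])) return(1)
  p <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided")$p.value
  )
  if (!is.finite(p)) p <- 1
  min(max(p, .Machine$double.xmin), 1)
}

#' Interpolate the noise factor detectable at a target AUROC
#'
#' The quality metric: linear interpolation of mean AUROC against
#' log10(noise factor) over the tested factors in `(0, 1]`, returning the
#' noise factor at which the curve crosses `target_auroc`. A small estimate
#' means even subtle perturbations are detectable — a "quiet", highly
#' replicable experiment.
#'
#' @param report A `pairqc_report` (or its [tidy()] summary tibble).
#' @param target_auroc Target AUROC, strictly between 0.5 and 1.
#' @param pair_kind Interpolate the `"pairs"` (default) or `"random"`
#'   mean-AUROC curve.
#' @return The interpolated noise factor, or `NA` (with a warning) if the
#'   curve never reaches the target within the tested range. If the curve
#'   already exceeds the target at the smallest tested factor, that factor
#'   is returned with a warning that the true level lies at or below it.
#' @export
estimate_noise_level <- function(report, target_auroc = 0.8,
                                 pair_kind = c("pairs", "random")) {
  pair_kind <- match.arg(pair_kind)
  check_scalar_number(target_auroc, "target_auroc")
  if (target_auroc <= 0.5 || target_auroc >= 1) {
    abort("`target_auroc` must be strictly between 0.5 and 1.")
  }
  s <- if (inherits(report, "pairqc_report")) report$summary else report
  col <- paste0("mean_auroc_", pair_kind)
  s <- s[s$noise_factor > 0 & is.finite(s[[col]]), , drop = FALSE]
  s <- s[order(s$noise_factor), , drop = FALSE]
  if (nrow(s) < 2L) {
    abort("Need mean AUROCs at >= 2 nonzero noise factors to interpolate.")
  }
  lf <- log10(s$noise_factor)
  y <- s[[col]]
  if (y[1L] >= target_auroc) {
    warn(sprintf(
      "Mean AUROC already exceeds %.3g at the smallest tested factor (%g); the detectable noise level is at or below it.",
      target_auroc, s$noise_factor[1L]
    ))
    return(s$noise_factor[1L])
  }
  for (i in seq_len(length(y) - 1L)) {
    y0 <- y[i]
    y1 <- y[i + 1L]
    if ((y0 - target_auroc) * (y1 - target_auroc) <= 0 && y0 != y1) {
      x <- lf[i] + (target_auroc - y0) / (y1 - y0) * (lf[i + 1L] - lf[i])
      return(10^x)
    }
    if (y1 == target_auroc) return(s$noise_factor[i + 1L])
  }
  warn(sprintf(
    "Mean AUROC never reaches %.3g within the tested noise factors; noise level undefined.",
    target_auroc
  ))
  NA_real_
}

#' @export
print.pairqc_report <- function(x, ...) {
  p <- x$params
  cat("Co-expression replicability report\n")
  cat(sprintf(
    "  %d samples, %d genes; %d housekeeping pairs vs %d random pairs\n",
    p$n_samples, p$n_genes, p$n_pairs, p$n_random
  ))
  cat(sprintf(
    "  %d repeats per factor, mode = %s, seed = %s\n",
    p$repeats, p$mode, p$seed
  ))
  cat("\nPer noise factor (mean detection AUROC):\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  ne <- x$noise_estimates
  cat("\nEstimated noise level (factor at target AUROC):\n")
  for (i in seq_len(nrow(ne))) {
    cat(sprintf(
      "  AUROC %.2f -> %s\n", ne$target_auroc[i],
      if (is.na(ne$noise_estimate[i])) "not reached" else
        sprintf("%.4g", ne$noise_estimate[i])
    ))
  }
  if (length(x$warnings)) {
    cat("\nWarnings:\n")
    cat(paste0("  - ", x$warnings, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write a report to disk
#'
#' Writes the per-factor summary as TSV, and the full run log, noise
#' estimates, parameters and warnings as JSON, so a run is reproducible
#' from its artifacts.
#'
#' @param report A `pairqc_report`.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, prefix = "pairqc") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, "_summary.tsv"))
  json <- file.path(dir, paste0(prefix, "_report.json"))
  readr::write_tsv(report$summary, tsv)
  runs <- report$runs
  runs$perturbed <- vapply(
    runs$perturbed, function(i) paste(i, collapse = ","), character(1)
  )
  jsonlite::write_json(
    list(
      summary = report$summary,
      noise_estimates = report$noise_estimates,
      runs = runs,
      params = report$params,
      warnings = report$warnings
    ),
    json,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(c(summary = tsv, report = json))
}
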