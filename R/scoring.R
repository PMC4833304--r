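#' Score samples for co-expression disruption of one gene pair
#'
#' Both profiles are midranked across samples, a least-squares line is fit
#' between the ranked profiles, and each sample is scored by the midrank of
#' its absolute externally studentized (leave-one-out) residual — the
#' sample deviating most from the line of best fit receives rank n
#' ("worst"). Because pairs are unordered, the regression is run in both
#' directions and the two absolute residuals per sample are averaged before
#' ranking (set `direction` to use a single fixed direction instead).
#'
#' @param x_profile,y_profile Numeric vectors of equal length (>= 3), the
#'   two genes' expression across samples; neither may be constant.
#' @param direction `"both"` (default, direction-symmetric), `"yx"`
#'   (regress y on x) or `"xy"`.
#' @param studentize `"external"` (default; leave-one-out residual
#'   variance) or `"internal"` for ordinary standardized residuals, kept
#'   for sensitivity checks — only the ranks of `|residual|` are used
#'   downstream, so the choice rarely matters.
#' @return Numeric vector of per-sample rank scores (a midranked
#'   permutation of 1..n); higher = more outlying.
#' @export
pair_outlier_scores <- function(x_profile, y_profile,
                                direction = c("both", "yx", "xy"),
                                studentize = c("external", "internal")) {
  direction <- match.arg(direction)
  studentize <- match.arg(studentize)
  n <- length(x_profile)
  if (length(y_profile) != n) abort("Profiles must have equal length.")
  if (n < 3L) abort("Need at least 3 samples for residual scoring.")
  if (var(x_profile) == 0 || var(y_profile) == 0) {
    abort("Constant profiles have no defined regression; filter pairs first.")
  }
  rx <- rbind(midrank(x_profile))
  ry <- rbind(midrank(y_profile))
  a <- switch(direction,
    both = (abs_studentized(rx, ry, studentize) +
              abs_studentized(ry, rx, studentize)) / 2,
    yx = abs_studentized(rx, ry, studentize),
    xy = abs_studentized(ry, rx, studentize)
  )
  midrank(drop(a))
}

# |studentized residual| of row-wise simple regressions Y ~ X.
# X, Y: n_pairs x n_samples matrices (already ranked). Degenerate rows
# (perfect fit) get all-zero residuals so every sample ties.
abs_studentized <- function(X, Y, studentize = "external") {
  n <- ncol(X)
  xc <- X - rowMeans(X)
  yc <- Y - rowMeans(Y)
  sxx <- rowSums(xc^2)
  beta <- rowSums(xc * yc) / sxx
  e <- yc - beta * xc
  h <- 1 / n + xc^2 / sxx
  sse <- rowSums(e^2)
  if (studentize == "external") {
    # s^2 excluding sample i; df = n - 3 (slope, intercept, deleted point)
    s2 <- (sse - e^2 / (1 - h)) / (n - 3)
  } else {
    s2 <- matrix(sse / (n - 2), nrow(X), n)
  }
  denom <- s2 * (1 - h)
  out <- abs(e) / sqrt(denom)
  # perfect or near-perfect fits: zero residuals everywhere -> all tied;
  # a residual with no leave-one-out variance left is maximally outlying
  tol <- sqrt(.Machine$double.eps)
  flat <- sse <= tol * pmax(rowSums(yc^2), 1)
  out[flat, ] <- 0
  bad <- !is.finite(out)
  if (any(bad)) out[bad] <- ifelse(abs(e[bad]) <= tol, 0, Inf)
  out
}

# Per-pair rank-score matrix (n_pairs x n_samples) for a pair set against a
# gene-ranked expression matrix.
pair_rank_scores <- function(ranked, pairs, direction = "both",
                             studentize = "external") {
  ia <- match(pairs$gene_a, rownames(ranked))
  ib <- match(pairs$gene_b, rownames(ranked))
  if (anyNA(ia) || anyNA(ib)) {
    abort("Pair gene missing from the expression matrix; run filter_pairs().")
  }
  X <- ranked[ia, , drop = FALSE]
  Y <- ranked[ib, , drop = FALSE]
  a <- switch(direction,
    both = (abs_studentized(X, Y, studentize) +
              abs_studentized(Y, X, studentize)) / 2,
    yx = abs_studentized(X, Y, studentize),
    xy = abs_studentized(Y, X, studentize)
  )
  sc <- row_midranks(a)
  dimnames(sc) <- list(NULL, colnames(ranked))
  sc
}

#' Aggregate per-pair rank scores into one score per sample
#'
#' The per-sample arithmetic mean of rank scores across pairs.
#'
#' @param score_rows Matrix (pairs x samples) of rank scores, e.g. rows
#'   from [pair_outlier_scores()].
#' @return Numeric vector of per-sample aggregate scores.
#' @export
aggregate_scores <- function(score_rows) {
  score_rows <- rbind(score_rows)
  if (nrow(score_rows) == 0L || ncol(score_rows) == 0L) {
    abort("`score_rows` must contain at least one pair's scores.")
  }
  colMeans(score_rows)
}

#' Area under the ROC curve for detecting the perturbed sample(s)
#'
#' Computed analytically from the Mann-Whitney U statistic with midrank tie
#' handling: with P the midranks of the positive samples' scores among all
#' samples (ascending), TP positives and TN negatives,
#' `AUROC = (sum(P) - TP(TP+1)/2) / (TP*TN)` — equivalently the fraction of
#' (positive, negative) pairs in which the positive scores higher, counting
#' ties as 1/2. Scores are oriented so that higher = worse: a perturbed
#' sample always ranked worst gives AUROC 1, an undetectable one 0.5 on
#' average.
#'
#' @param scores Numeric per-sample scores (higher = more outlying).
#' @param positives Indices (or logical mask, or sample names if `scores`
#'   is named) of the truly perturbed samples; nonempty, proper subset.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, positives) {
  n <- length(scores)
  if (is.logical(positives)) positives <- which(positives)
  if (is.character(positives)) positives <- match(positives, names(scores))
  positives <- unique(as.integer(positives))
  if (anyNA(positives) || any(positives < 1L) || any(positives > n)) {
    abort("`positives` must index into `scores`.")
  }
  tp <- length(positives)
  if (tp == 0L || tp >= n) {
    abort("`positives` must be a nonempty proper subset of the samples.")
  }
  r <- midrank(scores)
  (sum(r[positives]) - tp * (tp + 1) / 2) / (tp * (n - tp))
}
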