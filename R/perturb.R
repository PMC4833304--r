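#' Interpolate a gene's empirical expression distribution at a continuous rank
#'
#' A gene's observed values across samples, sorted ascending, define a
#' piecewise-linear continuous distribution over ranks 1..n: integer ranks
#' return the order statistics themselves, fractional ranks interpolate
#' linearly between adjacent order statistics. This is the sampling
#' distribution the noise model draws replacement values from, which keeps
#' every perturbed value inside the gene's measured range.
#'
#' @param profile Numeric vector of one gene's values across samples
#'   (sorted internally; length >= 2).
#' @param r Continuous rank(s) in `[1, n]`.
#' @return Interpolated expression value(s), one per element of `r`.
#' @examples
#' value_at_rank(c(1, 3, 9), 2) # 3
#' value_at_rank(c(1, 3, 9), 1.5) # 2
#' @export
value_at_rank <- function(profile, r) {
  if (!is.numeric(profile) || length(profile) < 2L) {
    abort("`profile` must be a numeric vector of length >= 2.")
  }
  n <- length(profile)
  if (any(!is.finite(r)) || any(r < 1) || any(r > n)) {
    abort(sprintf("`r` must lie within [1, %d].", n))
  }
  s <- sort(profile)
  lo <- pmin(floor(r), n - 1L)
  frac <- r - lo
  s[lo] * (1 - frac) + s[lo + 1L] * frac
}

# Interpolate many rows at once: `sorted` is genes x n (rows ascending),
# `r` a vector of one continuous rank per row.
values_at_ranks <- function(sorted, r) {
  n <- ncol(sorted)
  g <- seq_len(nrow(sorted))
  lo <- pmin(floor(r), n - 1L)
  frac <- r - lo
  sorted[cbind(g, lo)] * (1 - frac) + sorted[cbind(g, lo + 1L)] * frac
}

#' Restore a sample's marginal expression distribution after perturbation
#'
#' Replaces the perturbed sample's values by the original sample's order
#' statistics taken in the perturbed rank order. The sample's value
#' multiset is exactly conserved — the perturbation is invisible to any
#' per-sample marginal statistic — and only the gene-to-value assignment
#' changes.
#'
#' @param perturbed Numeric vector: the sample after per-gene perturbation.
#' @param original Numeric vector of equal length: the sample before.
#' @return Numeric vector: `original`'s values, reordered to follow
#'   `perturbed`'s ranks.
#' @export
remap_sample_distribution <- function(perturbed, original) {
  if (length(perturbed) != length(original)) {
    abort("`perturbed` and `original` must have equal length.")
  }
  sort(original)[rank(perturbed, ties.method = "first")]
}

#' Perturb samples within each gene's empirical distribution
#'
#' The noise model: for every gene in a targeted sample, take the gene's
#' (midrank-tied) rank in that sample, shift it by a uniform draw whose
#' half-width is `noise_factor` times the sample count (so a noise factor
#' of 0.10 in a 100-sample experiment moves a gene by at most 10 rank
#' positions), clamp to `[1, n]`, and replace the value by the gene's
#' interpolated empirical distribution at the new rank
#' ([value_at_rank()]). Each perturbed sample is then remapped onto its own
#' original value multiset ([remap_sample_distribution()]), so no
#' per-sample marginal statistic changes. `noise_factor = 0` is the
#' identity; `noise_factor = 1` resamples each gene's value effectively
#' unconstrained from its empirical distribution ("random").
#'
#' When several samples are targeted, each is perturbed independently from
#' the original matrix, so perturbed samples do not contaminate each
#' other's sampling distributions.
#'
#' @param x Expression table or matrix.
#' @param noise_factor Fraction of the rank range, in `[0, 1]`.
#' @param samples Sample names or indices to perturb (nonempty).
#' @param seed Optional integer seed; with a seed the result is a pure
#'   function of `(x, noise_factor, samples, seed)`. Per-gene draws are
#'   consumed in gene order.
#' @param shift `"signed"` (default) draws the rank shift uniformly on
#'   `[-f*n, +f*n]`; `"one_sided"` on `[0, f*n]`, nudging ranks upward only.
#' @return A perturbed expression table of the same shape; untargeted
#'   samples are unchanged.
#' @export
perturb_samples <- function(x, noise_factor, samples, seed = NULL,
                            shift = c("signed", "one_sided")) {
  m <- check_expr_matrix(as_expr_matrix(x))
  check_scalar_number(noise_factor, "noise_factor", lower = 0, upper = 1)
  shift <- match.arg(shift)
  idx <- resolve_samples(m, samples)
  out <- perturb_matrix(
    m, noise_factor, idx, shift,
    sorted = t(apply(m, 1L, sort)), ranks = row_midranks(m), seed = seed
  )
  if (is.matrix(x)) out else expr_as_tibble(out)
}

resolve_samples <- function(m, samples) {
  if (length(samples) == 0L) abort("`samples` must be nonempty.")
  if (is.character(samples)) {
    idx <- match(samples, colnames(m))
    if (anyNA(idx)) {
      abort(sprintf("Unknown sample name: '%s'.", samples[is.na(idx)][1L]))
    }
  } else {
    idx <- as.integer(samples)
    if (any(idx < 1L) || any(idx > ncol(m))) abort("Sample index out of range.")
  }
  unique(idx)
}

# Core worker. `sorted` (rows ascending) and `ranks` (row midranks) are the
# original matrix's profiles, precomputed once so repeated runs on the same
# experiment stay cheap.
perturb_matrix <- function(m, noise_factor, idx, shift = "signed",
                           sorted, ranks, seed = NULL) {
  n <- ncol(m)
  g <- nrow(m)
  with_seed_if(seed, {
    for (s in idx) {
      delta <- if (shift == "signed") {
        runif(g, -noise_factor * n, noise_factor * n)
      } else {
        runif(g, 0, noise_factor * n)
      }
      new_rank <- pmin(pmax(ranks[, s] + delta, 1), n)
      new_vals <- values_at_ranks(sorted, new_rank)
      m[, s] <- remap_sample_distribution(new_vals, m[, s])
    }
  })
  m
}
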