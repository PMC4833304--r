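# Synthetic expression generators with known co-expression, replicability
# and dynamic-range structure, so every pipeline stage is testable against
# ground truth without external data.

# A target Spearman correlation between two monotone transforms of
# bivariate normals is hit by setting the latent Pearson correlation to
# 2*sin(pi*rho_s/6) (the exact normal rank-correlation relation).
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Gene-specific monotone map from a latent standard-normal score to a
# positive expression scale: value = 2^(mu + sigma * z). Log-normal style
# dynamic ranges are a fixture choice, not a claim about real data.
range_map <- function(z, mu, sigma) 2^(mu + sigma * z)

#' Simulate an experiment with co-expressed gene pairs of known strength
#'
#' Each pair shares a latent per-sample condition signal plus independent
#' noise, calibrated so the expected Spearman correlation between pair
#' members equals `pair_rank_correlation`; background genes are
#' independent. Every gene's latent score is then mapped through its own
#' monotone transform onto a positive, gene-specific dynamic range, which
#' preserves rank structure while giving genes the disjoint-range character
#' of real expression data.
#'
#' @param n_samples Number of samples (>= 4).
#' @param n_pairs Number of co-expressed pairs (two dedicated genes each).
#' @param pair_rank_correlation Target Spearman correlation within pairs,
#'   in `[0, 1)`; 0 makes the "pairs" indistinguishable from random pairs.
#' @param n_background_genes Independent genes added alongside the pairs.
#' @param seed Optional integer seed; generation is a pure function of
#'   `(parameters, seed)`.
#' @return A list: `expr` (expression table), `pairs` ([pair_table]),
#'   `truth` (latent Pearson correlation, per-gene range parameters, seed).
#' @export
make_coexpressed_dataset <- function(n_samples = 50L, n_pairs = 1000L,
                                     pair_rank_correlation = 0.9,
                                     n_background_genes = 500L,
                                     seed = NULL) {
  check_scalar_number(n_samples, "n_samples", lower = 4)
  check_scalar_number(n_pairs, "n_pairs", lower = 1)
  check_scalar_number(n_background_genes, "n_background_genes", lower = 0)
  check_scalar_number(pair_rank_correlation, "pair_rank_correlation")
  if (pair_rank_correlation < 0 || pair_rank_correlation >= 1) {
    abort("`pair_rank_correlation` must lie in [0, 1).")
  }
  rho <- spearman_to_pearson(pair_rank_correlation)
  n_genes <- 2L * n_pairs + n_background_genes
  with_seed_if(seed, {
    latent <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
    if (n_pairs > 0L && rho > 0) {
      z <- matrix(rnorm(n_pairs * n_samples), n_pairs, n_samples)
      for (k in 0:1) {
        rows <- seq_len(n_pairs) * 2L - 1L + k
        latent[rows, ] <- sqrt(rho) * z + sqrt(1 - rho) * latent[rows, ]
      }
    }
    mu <- runif(n_genes, 2, 12)
    sigma <- runif(n_genes, 0.5, 2)
    m <- range_map(latent, mu, sigma)
    ids <- sprintf("G%05d", seq_len(n_genes))
    dimnames(m) <- list(ids, sprintf("S%03d", seq_len(n_samples)))
    ga <- ids[seq_len(n_pairs) * 2L - 1L]
    gb <- ids[seq_len(n_pairs) * 2L]
    list(
      expr = expr_as_tibble(m),
      pairs = new_pair_table(ga, gb, "housekeeping"),
      truth = list(
        pair_rank_correlation = pair_rank_correlation,
        latent_pearson = rho,
        mu = mu, sigma = sigma, seed = seed
      )
    )
  })
}

#' Simulate a pair of replicate experiments with known gene-level replicability
#'
#' Experiments X and Y share a per-gene, per-sample condition signal whose
#' weight is set so each gene's latent correlation between X and Y equals
#' its replicability target. With `disjoint_ranges = TRUE`, genes are laid
#' out on non-overlapping expression intervals (each gene varies only
#' within its own narrow dynamic range), which makes sample-sample
#' correlations between X and Y columns high regardless of how little any
#' individual gene's variation replicates — the Simpson's-paradox behaviour
#' that makes sample-level correlation a misleading replicability measure.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (>= 4).
#' @param replicability_targets Per-gene target correlations in `[-1, 1]`,
#'   recycled to `n_genes`. Interpreted on the Spearman scale.
#' @param disjoint_ranges Assign non-overlapping per-gene expression
#'   intervals (default `TRUE`); `FALSE` draws overlapping random ranges.
#' @param seed Optional integer seed.
#' @return A list: `x`, `y` (aligned expression tables) and `truth`
#'   (targets, range parameters, seed).
#' @export
make_replicate_dataset <- function(n_genes = 500L, n_samples = 20L,
                                   replicability_targets = 0.7,
                                   disjoint_ranges = TRUE,
                                   seed = NULL) {
  check_scalar_number(n_genes, "n_genes", lower = 1)
  check_scalar_number(n_samples, "n_samples", lower = 4)
  t <- rep_len(replicability_targets, n_genes)
  if (any(abs(t) > 1)) abort("`replicability_targets` must lie in [-1, 1].")
  rho <- sign(t) * spearman_to_pearson(abs(t))
  with_seed_if(seed, {
    s <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
    ex <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
    ey <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
    a <- sqrt(abs(rho))
    b <- sqrt(1 - abs(rho))
    zx <- a * s + b * ex
    zy <- sign(rho) * a * s + b * ey
    # targets of exactly +/-1 must reproduce the shared signal exactly
    # (keyed on the target: the rank-to-Pearson map is only float-exact at 0)
    exact <- abs(t) == 1
    if (any(exact)) {
      zx[exact, ] <- s[exact, ]
      zy[exact, ] <- sign(rho[exact]) * s[exact, ]
    }
    if (disjoint_ranges) {
      spacing <- 3
      mu <- spacing * seq_len(n_genes)
      sigma <- rep(spacing / 8, n_genes)
      # keep the absolute scale bounded: compress onto log2 range [0, 30]
      scale <- 30 / max(mu + 4 * sigma[1])
      mu <- mu * scale
      sigma <- sigma * scale
    } else {
      mu <- runif(n_genes, 2, 12)
      sigma <- runif(n_genes, 0.5, 2)
    }
    ids <- sprintf("G%05d", seq_len(n_genes))
    smp <- sprintf("S%03d", seq_len(n_samples))
    mx <- range_map(zx, mu, sigma)
    my <- range_map(zy, mu, sigma)
    dimnames(mx) <- dimnames(my) <- list(ids, smp)
    list(
      x = expr_as_tibble(mx),
      y = expr_as_tibble(my),
      truth = list(
        replicability_targets = t, latent_pearson = rho,
        mu = mu, sigma = sigma, disjoint_ranges = disjoint_ranges,
        seed = seed
      )
    )
  })
}
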