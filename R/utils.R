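# Shared internal helpers.

# Midranks (average ties), the convention assumed by the Spearman/Wilcoxon
# machinery downstream.
midrank <- function(x) rank(x, ties.method = "average")

# Row-wise midranks of a numeric matrix. Computed by column-wise
# comparison counts — O(g * n^2) element ops but fully vectorized, much
# faster than per-row rank() calls for the wide-and-short matrices used
# here: midrank(x_j) = (#{x < x_j} + #{x <= x_j} + 1) / 2.
row_midranks <- function(m) {
  n <- ncol(m)
  out <- m
  for (j in seq_len(n)) {
    v <- m[, j]
    out[, j] <- (rowSums(m < v) + rowSums(m <= v) + 1) / 2
  }
  dimnames(out) <- dimnames(m)
  out
}

# Deterministic child seeds so runs are independent of execution order and
# reproducible from one master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}
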