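# Shared fixtures and independent oracles for the test suite.

# Small random expression table (tibble form) with positive values.
tiny_expr <- function(n_genes = 6, n_samples = 8, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(exp(rnorm(n_genes * n_samples, 4, 1)), n_genes, n_samples)
    dimnames(m) <- list(
      sprintf("g%02d", seq_len(n_genes)),
      sprintf("s%02d", seq_len(n_samples))
    )
    pairqc:::expr_as_tibble(m)
  })
}

expr_mat <- function(x) pairqc:::as_expr_matrix(x)

# O(n^2) pairwise-comparison AUROC oracle: fraction of (positive, negative)
# score pairs where the positive scores higher, ties counting 1/2.
auroc_oracle <- function(scores, positives) {
  pos <- scores[positives]
  neg <- scores[-positives]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Externally studentized residuals of y ~ x by brute-force leave-one-out
# refits: delete point i, refit, predict i, scale by the prediction SE.
rstudent_oracle <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    fit <- lm(y[-i] ~ x[-i])
    s <- summary(fit)$sigma
    X <- cbind(1, x[-i])
    x0 <- c(1, x[i])
    pred <- sum(coef(fit) * x0)
    se <- s * sqrt(1 + drop(t(x0) %*% solve(crossprod(X)) %*% x0))
    (y[i] - pred) / se
  }, numeric(1))
}

# Exact two-sided Wilcoxon rank-sum p-value by exhaustive enumeration of
# all C(n1 + n2, n1) group assignments of the pooled values.
wilcox_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  min(1, mean(abs(u - mu) >= abs(obs - mu) - 1e-12))
}
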