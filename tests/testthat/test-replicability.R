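test_that("gene self-correlations match direct per-gene recomputation", {
  sim <- make_replicate_dataset(n_genes = 40, n_samples = 12, seed = 3,
                                replicability_targets = 0.6,
                                disjoint_ranges = FALSE)
  mx <- expr_mat(sim$x)
  my <- expr_mat(sim$y)
  for (method in c("pearson", "spearman")) {
    ours <- gene_self_correlation(sim$x, sim$y, method)
    direct <- vapply(seq_len(nrow(mx)), function(i) {
      cor(mx[i, ], my[i, ], method = method)
    }, numeric(1))
    expect_equal(unname(ours), direct, tolerance = 1e-12)
  }
  expect_equal(unname(gene_self_correlation(sim$x, sim$x)),
               rep(1, nrow(mx)))
  # anti-correlated replicate: per-gene reflection around the mean
  neg <- pairqc:::expr_as_tibble(max(mx) - mx + 1)
  neg$gene_id <- sim$x$gene_id
  expect_equal(unname(gene_self_correlation(sim$x, neg, "pearson")),
               rep(-1, nrow(mx)))
  # constant genes are flagged undefined
  mc <- mx
  mc[3, ] <- 2
  expect_true(is.na(gene_self_correlation(mc, my)[3]))
  expect_error(gene_self_correlation(sim$x, sim$y[, 1:4]), "aligned")
})

test_that("correlation significance reproduces the published statistics", {
  # z = atanh(r) * sqrt(n-3) / 1.06 against an independent high-precision
  # evaluation for r = 0.9, n = 18
  z_expected <- 0.5 * log(19) * sqrt(15) / 1.06
  expect_equal(pairqc:::correlation_statistic(0.9, 18, "fisher_z"),
               z_expected, tolerance = 1e-14)
  expect_equal(correlation_significance(0.9, 18, "fisher_z"),
               pnorm(z_expected, lower.tail = FALSE), tolerance = 1e-14)
  # t = r sqrt(n-2) / sqrt(1-r^2)
  expect_equal(pairqc:::correlation_statistic(0.5, 10, "t"),
               0.5 * sqrt(8) / sqrt(0.75), tolerance = 1e-14)
  # r = 0 -> one-sided p = 0.5 under both references
  expect_equal(correlation_significance(0, 12, "fisher_z"), 0.5)
  expect_equal(correlation_significance(0, 12, "t"), 0.5)
  # antisymmetry of the statistic, hence p(-r) = 1 - p(r)
  for (r in c(0.2, 0.7, 0.95)) {
    expect_equal(correlation_significance(-r, 15),
                 1 - correlation_significance(r, 15), tolerance = 1e-12)
    expect_equal(pairqc:::correlation_statistic(-r, 15, "t"),
                 -pairqc:::correlation_statistic(r, 15, "t"))
  }
  # the published variance-inflation divisor is on by default
  expect_gt(correlation_significance(0.8, 20),
            correlation_significance(0.8, 20, inflation = 1))
  # degenerate correlations
  expect_warning(p1 <- correlation_significance(1, 10), "smallest")
  expect_equal(p1, .Machine$double.xmin)
  expect_error(correlation_significance(1.2, 10), "-1, 1")
  expect_error(correlation_significance(0.5, 3), "n")
  # monotone decreasing in r at fixed n, and in n at fixed r > 0
  rs <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(correlation_significance(rs, 15)) < 0))
  ns <- c(5, 10, 20, 50, 100)
  for (m in c("fisher_z", "t")) {
    p <- vapply(ns, function(n) correlation_significance(0.4, n, m),
                numeric(1))
    expect_true(all(diff(p) < 0))
  }
})

test_that("p-value adjustment follows Holm step-down and BH step-up", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.01, 0.01)), rep(0.03, 3))
  # hand-executed Holm step-down
  p <- c(0.01, 0.04, 0.03, 0.005)
  expect_equal(adjust_pvalues(p),
               c(0.03, 0.06, 0.06, 0.02))
  withr::with_seed(5, {
    pr <- runif(50)
    expect_true(all(adjust_pvalues(pr) >= pr))
    expect_true(all(adjust_pvalues(pr, "holm") >= adjust_pvalues(pr, "bh")))
  })
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("coverage extrapolation matches a per-gene brute-force recomputation", {
  withr::with_seed(9, {
    corrs <- c(runif(80, 0, 0.95), rep(NA, 5))
    grid <- c(4, 8, 16, 32, 64)
    cov <- coverage_vs_sample_size(corrs, grid, alpha = 0.05)
    # loop oracle
    ok <- corrs[!is.na(corrs)]
    for (k in seq_along(grid)) {
      n <- grid[k]
      praw <- vapply(ok, function(r) {
        pt(r * sqrt(n - 2) / sqrt(1 - r^2), df = n - 2, lower.tail = FALSE)
      }, numeric(1))
      q <- p.adjust(praw, "holm")
      expect_equal(cov$coverage[k], mean(q < 0.05))
    }
    expect_true(all(diff(cov$coverage) >= 0)) # nondecreasing in n
    # nondecreasing in alpha as well
    cov2 <- coverage_vs_sample_size(corrs, grid, alpha = 0.2)
    expect_true(all(cov2$coverage >= cov$coverage))
  })
  expect_equal(coverage_vs_sample_size(rep(0, 10), c(10, 50))$coverage,
               c(0, 0))
  expect_error(coverage_vs_sample_size(c(NA_real_, NA_real_), 10), "no defined")
  expect_error(coverage_vs_sample_size(0.5, 3), ">= 4")
})

test_that("self-correlation ranks identify replicated genes as their own best match", {
  sim <- make_replicate_dataset(n_genes = 30, n_samples = 15, seed = 7,
                                replicability_targets = 0.9,
                                disjoint_ranges = FALSE)
  sr <- self_correlation_rank(sim$x, sim$x)
  expect_true(all(sr == 1)) # against itself every gene matches itself
  # brute-force oracle on the real replicate pair
  sr2 <- self_correlation_rank(sim$x, sim$y, "pearson")
  mx <- expr_mat(sim$x)
  my <- expr_mat(sim$y)
  for (i in c(1, 9, 30)) {
    cc <- vapply(seq_len(nrow(my)), function(j) cor(mx[i, ], my[j, ]),
                 numeric(1))
    expect_equal(unname(sr2[i]), mean(cc <= cc[i]))
  }
  # permuting which profile carries which gene label destroys the enrichment
  withr::with_seed(2, {
    perm <- sim$y
    perm[, -1] <- perm[sample(nrow(perm)), -1]
    sr3 <- self_correlation_rank(sim$x, perm)
    expect_gt(mean(sr2 == 1), mean(sr3 == 1) + 0.3)
  })
})

test_that("fold changes follow |log2 ratio| with the half/half default", {
  m <- matrix(c(
    4, 4, 1, 1,
    3, 3, 3, 3,
    8, 8, 2, 2
  ), 3, 4, byrow = TRUE, dimnames = list(c("a", "b", "c"), letters[1:4]))
  fc <- fold_change(m)
  expect_equal(unname(fc), c(2, 0, 2))
  expect_equal(fold_change(m, c(1, 2), c(3, 4)), fc)
  # |.| makes direction irrelevant
  expect_equal(fold_change(m, c(3, 4), c(1, 2)), fc)
  withr::with_seed(3, {
    mm <- expr_mat(tiny_expr(25, 8, seed = 12))
    direct <- abs(log2(rowMeans(mm[, 1:4]) / rowMeans(mm[, 5:8])))
    expect_equal(fold_change(mm), direct, tolerance = 1e-12)
  })
  z <- m
  z["b", ] <- 0
  expect_true(is.na(fold_change(z)["b"]))
  expect_error(fold_change(m, c(1, 2), c(2, 3)), "disjoint")
})

test_that("the replicability table assembles all per-gene statistics coherently", {
  sim <- make_replicate_dataset(n_genes = 60, n_samples = 14, seed = 13,
                                replicability_targets = runif(60),
                                disjoint_ranges = FALSE)
  tbl <- replicability_table(sim$x, sim$y)
  expect_named(tbl, c("gene_id", "correlation", "p_value", "q_value",
                      "self_rank", "mean_expression", "fold_change"))
  expect_true(all(tbl$q_value >= tbl$p_value, na.rm = TRUE))
  expect_true(all(tbl$correlation >= -1 & tbl$correlation <= 1, na.rm = TRUE))
  expect_true(all(tbl$self_rank > 0 & tbl$self_rank <= 1, na.rm = TRUE))
  expect_equal(tbl$correlation,
               unname(gene_self_correlation(sim$x, sim$y)))
})

test_that("filter summaries respond to the expression and fold-change filters", {
  withr::with_seed(31, {
    n <- 400
    # low-expression genes constructed to replicate poorly
    mean_expr <- sort(runif(n, 0, 12))
    corr <- ifelse(mean_expr < 4, runif(n, 0, 0.5), runif(n, 0.85, 1))
    tbl <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:n),
      correlation = corr,
      p_value = runif(n), q_value = runif(n),
      self_rank = runif(n),
      mean_expression = mean_expr,
      fold_change = runif(n, 0, 3)
    )
    fs <- filter_summary(tbl, corr_threshold = 0.9, expr_quantile = 1 / 3,
                         fc_threshold = 1)
    expect_gt(fs$after$fraction_replicable, fs$before$fraction_replicable)
    expect_lt(fs$after$n_genes, fs$before$n_genes)
    # filters that remove nothing leave the summary unchanged
    fs0 <- filter_summary(tbl, corr_threshold = 0.9, expr_quantile = 0,
                          fc_threshold = 0)
    expect_equal(fs0$after, fs0$before)
    # filters that remove everything warn and leave NA fractions
    expect_warning(
      fs1 <- filter_summary(tbl, expr_quantile = 1 / 3, fc_threshold = 99),
      "every gene"
    )
    expect_true(is.na(fs1$after$fraction_replicable))
    expect_error(filter_summary(tbl, corr_threshold = 2), "corr_threshold")
  })
})
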