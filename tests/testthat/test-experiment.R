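make_test_sim <- function(n_samples = 16, n_pairs = 60, rho = 0.9,
                          bg = 60, seed = 101) {
  make_coexpressed_dataset(
    n_samples = n_samples, n_pairs = n_pairs, pair_rank_correlation = rho,
    n_background_genes = bg, seed = seed
  )
}

test_that("a single run is deterministic and both AUROCs are valid", {
  sim <- make_test_sim()
  r1 <- run_single(sim$expr, sim$pairs, noise_factor = 0.25, seed = 7)
  r2 <- run_single(sim$expr, sim$pairs, noise_factor = 0.25, seed = 7)
  expect_identical(r1, r2)
  expect_true(r1$auroc_pairs >= 0 && r1$auroc_pairs <= 1)
  expect_true(r1$auroc_random >= 0 && r1$auroc_random <= 1)
  expect_length(r1$perturbed[[1]], 1)
})

test_that("full disruption of near-perfect co-expression is perfectly detected", {
  sim <- make_coexpressed_dataset(
    n_samples = 20, n_pairs = 150, pair_rank_correlation = 0.99,
    n_background_genes = 50, seed = 5
  )
  aurocs <- vapply(1:5, function(s) {
    run_single(sim$expr, sim$pairs, noise_factor = 1, seed = s)$auroc_pairs
  }, numeric(1))
  expect_gte(mean(aurocs), 0.99)
})

test_that("half-sample perturbation targets half the samples independently", {
  sim <- make_test_sim()
  r <- run_single(sim$expr, sim$pairs, noise_factor = 0.5,
                  mode = "half_samples", seed = 3)
  expect_length(r$perturbed[[1]], 8)
})

test_that("experiment reports bookkeep their run logs faithfully", {
  sim <- make_test_sim()
  rep <- run_experiment(sim$expr, sim$pairs, noise_factors = c(0, 0.25, 1),
                        repeats = 6, seed = 11)
  s <- tidy(rep)
  runs <- tidy(rep, type = "runs")
  expect_equal(nrow(runs), 18)
  for (f in c(0, 0.25, 1)) {
    sub <- runs[runs$noise_factor == f, ]
    expect_equal(s$mean_auroc_pairs[s$noise_factor == f],
                 mean(sub$auroc_pairs))
    expect_equal(s$mean_auroc_random[s$noise_factor == f],
                 mean(sub$auroc_random))
    expect_equal(s$se_auroc_pairs[s$noise_factor == f],
                 sd(sub$auroc_pairs) / sqrt(6))
    expect_equal(s$p_wilcox[s$noise_factor == f],
                 wilcoxon_rank_sum(sub$auroc_pairs, sub$auroc_random))
  }
  g <- glance(rep)
  expect_equal(g$n_pairs, 60L)
  expect_equal(g$repeats, 6)
  # identical seed -> identical report
  rep2 <- run_experiment(sim$expr, sim$pairs, noise_factors = c(0, 0.25, 1),
                         repeats = 6, seed = 11)
  expect_equal(tidy(rep2), s)
})

test_that("strong pairs beat the random null at moderate noise", {
  sim <- make_test_sim(n_samples = 20, n_pairs = 100, rho = 0.95, bg = 100,
                       seed = 33)
  rep <- run_experiment(sim$expr, sim$pairs, noise_factors = 0.25,
                        repeats = 20, seed = 2)
  s <- tidy(rep)
  expect_gt(s$mean_auroc_pairs, s$mean_auroc_random)
  expect_lt(s$p_wilcox, 0.01)
})

test_that("repeats = 1 reports means without p-values and records a note", {
  sim <- make_test_sim()
  rep <- run_experiment(sim$expr, sim$pairs, noise_factors = c(0.1, 0.5),
                        repeats = 1, seed = 4)
  s <- tidy(rep)
  expect_true(all(is.na(s$p_wilcox)))
  expect_true(all(is.na(s$se_auroc_pairs)))
  runs <- tidy(rep, "runs")
  expect_equal(s$mean_auroc_pairs, runs$auroc_pairs)
  expect_true(any(grepl("repeats = 1", rep$warnings)))
})

test_that("small experiments trigger the minimum-sample warning", {
  sim <- make_test_sim(n_samples = 8, seed = 3)
  expect_warning(
    rep <- run_experiment(sim$expr, sim$pairs, noise_factors = 0.5,
                          repeats = 2, seed = 1),
    "at least 10"
  )
  expect_true(any(grepl("at least 10", rep$warnings)))
})

test_that("wilcoxon_rank_sum matches exact enumeration and handles ties", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)),
               wilcox_exact_oracle(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  withr::with_seed(19, {
    for (i in 1:15) {
      a <- rnorm(sample(3:6, 1))
      b <- rnorm(sample(3:6, 1))
      expect_equal(wilcoxon_rank_sum(a, b), wilcox_exact_oracle(a, b),
                   tolerance = 1e-12)
    }
  })
  expect_equal(wilcoxon_rank_sum(rep(1, 5), rep(1, 4)), 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")
  # null calibration: p approximately uniform for equal distributions
  withr::with_seed(23, {
    ps <- replicate(400, wilcoxon_rank_sum(rnorm(30), rnorm(30)))
    expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  })
})

test_that("noise-level interpolation solves the crossing on the log scale", {
  s <- tibble::tibble(
    noise_factor = c(0.01, 0.1),
    mean_auroc_pairs = c(0.55, 0.85),
    mean_auroc_random = c(0.5, 0.5)
  )
  # closed form: log10(f) = -2 + (0.70-0.55)/(0.85-0.55) * ((-1) - (-2))
  expect_equal(estimate_noise_level(s, 0.70), 10^(-2 + 0.15 / 0.30))
  # a target sitting exactly on a grid mean returns that factor
  expect_equal(estimate_noise_level(s, 0.85), 0.1)
  # unreachable target -> NA with warning
  expect_warning(out <- estimate_noise_level(s, 0.9), "never reaches")
  expect_true(is.na(out))
  # already above at the smallest factor -> boundary with warning
  expect_warning(out2 <- estimate_noise_level(s, 0.52), "at or below")
  expect_equal(out2, 0.01)
  expect_error(estimate_noise_level(s, 0.4), "between 0.5 and 1")
  expect_error(estimate_noise_level(s, 1), "between 0.5 and 1")
})

test_that("reports serialise to TSV + JSON artifacts", {
  sim <- make_test_sim()
  rep <- run_experiment(sim$expr, sim$pairs, noise_factors = c(0.1, 1),
                        repeats = 3, seed = 8)
  dir <- withr::local_tempdir()
  paths <- write_report(rep, dir)
  expect_true(all(file.exists(paths)))
  s <- readr::read_tsv(paths["summary"], show_col_types = FALSE)
  expect_equal(nrow(s), 2)
  j <- jsonlite::read_json(paths["report"])
  expect_named(j, c("summary", "noise_estimates", "runs", "params", "warnings"),
               ignore.order = TRUE)
  expect_equal(length(j$runs), 6)
})
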