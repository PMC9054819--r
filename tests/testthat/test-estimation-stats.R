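# Cohen's d and BCa bootstrap estimation.

test_that("cohen_d closed-form cases and oracle", {
  expect_equal(cohen_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohen_d(c(0, 1, 2), c(1, 2, 3)), 1.0)
  set.seed(8)
  for (i in 1:20) {
    g1 <- rnorm(sample(5:30, 1))
    g2 <- rnorm(sample(5:30, 1), 0.5)
    expect_equal(cohen_d(g1, g2), oracle_cohen_d(g1, g2), tolerance = 1e-12)
    # antisymmetry and affine invariance
    expect_equal(cohen_d(g2, g1), -cohen_d(g1, g2), tolerance = 1e-12)
    expect_equal(cohen_d(3 * g1 + 2, 3 * g2 + 2), cohen_d(g1, g2),
                 tolerance = 1e-10)
  }
  expect_error(cohen_d(rep(1, 5), rep(1, 5)), "zero pooled")
  expect_error(cohen_d(1, c(1, 2)), ">= 2")
  # Hedges correction shrinks toward zero
  g <- simulate_two_groups(10, 10, 1, seed = 2)
  expect_lt(abs(cohen_d(g$g1, g$g2, hedges = TRUE)),
            abs(cohen_d(g$g1, g$g2)))
})

test_that("bootstrap is deterministic under a fixed seed", {
  g <- simulate_two_groups(14, 14, 0.8, seed = 5)
  e1 <- bootstrap_effect(g$g1, g$g2, n_resamples = 500, seed = 9)
  e2 <- bootstrap_effect(g$g1, g$g2, n_resamples = 500, seed = 9)
  expect_identical(e1[c("d", "ci_low", "ci_high", "z0", "acceleration")],
                   e2[c("d", "ci_low", "ci_high", "z0", "acceleration")])
  expect_true(e1$ci_low <= e1$d && e1$d <= e1$ci_high)
})

test_that("BCa bounds match a direct transcription of the adjustment", {
  g <- simulate_two_groups(12, 12, 0.5, seed = 3)
  eff <- bootstrap_effect(g$g1, g$g2, n_resamples = 1000, seed = 4,
                          keep_resamples = TRUE)
  z_alpha <- qnorm(c(0.025, 0.975))
  adj <- pnorm(eff$z0 + (eff$z0 + z_alpha) /
                 (1 - eff$acceleration * (eff$z0 + z_alpha)))
  expect_equal(unname(quantile(eff$resamples, adj, type = 7)),
               c(eff$ci_low, eff$ci_high), tolerance = 1e-12)
  # jackknife acceleration recomputed independently
  theta <- c(vapply(seq_along(g$g1), function(i) oracle_cohen_d(g$g1[-i], g$g2),
                    numeric(1)),
             vapply(seq_along(g$g2), function(i) oracle_cohen_d(g$g1, g$g2[-i]),
                    numeric(1)))
  td <- mean(theta) - theta
  expect_equal(eff$acceleration, sum(td^3) / (6 * sum(td^2)^1.5),
               tolerance = 1e-12)
})

test_that("BCa approaches the percentile interval under a symmetric null", {
  g <- simulate_two_groups(50, 50, 0, seed = 21)
  bca <- bootstrap_effect(g$g1, g$g2, n_resamples = 2000, seed = 22)
  pct <- bootstrap_effect(g$g1, g$g2, n_resamples = 2000, seed = 22,
                          method = "percentile")
  expect_lt(abs(bca$z0), 0.1)
  expect_lt(abs(bca$ci_low - pct$ci_low), 0.1)
  expect_lt(abs(bca$ci_high - pct$ci_high), 0.1)
})

test_that("a 0% CI collapses to a single point (the bootstrap median)", {
  g <- simulate_two_groups(15, 15, 0.5, seed = 6)
  eff <- bootstrap_effect(g$g1, g$g2, n_resamples = 500, ci_level = 0,
                          method = "percentile", seed = 7,
                          keep_resamples = TRUE)
  expect_equal(eff$ci_low, eff$ci_high)
  expect_equal(eff$ci_low, unname(median(eff$resamples)))
})

test_that("degenerate resamples are counted, dropped, and capped at 50%", {
  # healthy groups produce no degenerate resamples
  g <- simulate_two_groups(14, 14, 0.5, seed = 1)
  eff <- bootstrap_effect(g$g1, g$g2, n_resamples = 300, seed = 2)
  expect_equal(eff$n_degenerate, 0L)
  # a constant group plus a two-point group: a resample is degenerate
  # whenever the two-point group draws a constant pair (~50% of draws);
  # seed 4 pushes the realized count over the 50% guard
  expect_error(bootstrap_effect(rep(1, 5), c(1, 2), n_resamples = 50,
                                seed = 4, method = "percentile"),
               "degenerate")
  # BCa itself refuses groups too small to jackknife
  expect_error(bootstrap_effect(c(1, 2), c(2, 3), n_resamples = 50, seed = 1),
               "jackknife")
})

test_that("multi_two_group is per-label deterministic and order-invariant", {
  mk <- function(seed) simulate_two_groups(14, 14, 0.8, seed = seed)
  pairs <- list(DG = mk(1), CA3 = mk(2), CA1 = mk(3))
  res <- multi_two_group(pairs, n_resamples = 300, seed = 17)
  expect_named(res, c("DG", "CA3", "CA1"))
  # single pair equals bootstrap_effect with the derived seed
  solo <- bootstrap_effect(pairs$CA1$g1, pairs$CA1$g2, n_resamples = 300,
                           seed = fiberpnn:::derive_seed(17, "CA1"))
  expect_equal(res$CA1$ci_low, solo$ci_low)
  expect_equal(res$CA1$ci_high, solo$ci_high)
  # permuting the pair order leaves each label's result unchanged
  res_perm <- multi_two_group(pairs[c("CA1", "DG", "CA3")], n_resamples = 300,
                              seed = 17)
  for (lab in names(pairs)) {
    expect_equal(res_perm[[lab]]$ci_low, res[[lab]]$ci_low)
    expect_equal(res_perm[[lab]]$ci_high, res[[lab]]$ci_high)
  }
  # a failing pair does not abort the others
  pairs$bad <- list(g1 = rep(1, 5), g2 = rep(1, 5))
  res2 <- multi_two_group(pairs, n_resamples = 100, seed = 17)
  expect_true(!is.null(res2$bad$error))
  expect_equal(res2$DG$d, res$DG$d)
})

test_that("CI width shrinks with group size", {
  w <- vapply(c(10, 40, 160), function(n) {
    g <- simulate_two_groups(n, n, 0.5, seed = n)
    e <- bootstrap_effect(g$g1, g$g2, n_resamples = 500, seed = 1)
    e$ci_high - e$ci_low
  }, numeric(1))
  expect_true(w[3] < w[1])
})
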