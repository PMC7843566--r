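test_that("Kruskal-Wallis H matches hand-ranked arithmetic", {
  tab <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                    x = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  kw <- kruskal_wallis(tab, "x")
  expect_equal(kw$H, 7.2)
  expect_equal(kw$H, oracle_kw_h(tab$x, tab$group))
  expect_equal(kw$df, 2)
  # fully tied data: H = 0, p = 1 by convention
  tied <- data.frame(group = rep(c("a", "b"), each = 4), x = rep(3, 8))
  expect_equal(kruskal_wallis(tied, "x"), list(H = 0, p = 1, df = 1))
  expect_error(kruskal_wallis(data.frame(group = "a", x = 1), "x"), "groups")
})

test_that("Kruskal-Wallis holds its nominal type-I error", {
  set.seed(31)
  reject <- replicate(1000, {
    tab <- data.frame(group = rep(c("a", "b", "c", "d"), times = c(8, 8, 8, 8)),
                      x = rnorm(32))
    kruskal_wallis(tab, "x")$p < 0.05
  })
  expect_gt(mean(reject), 0.035)
  expect_lt(mean(reject), 0.065)
})

test_that("Mann-Whitney comparisons agree with exact enumeration", {
  set.seed(12)
  for (i in 1:5) {
    x <- sample(100, 5); y <- sample(200, 6) + 0.5   # distinct values
    tab <- data.frame(group = rep(c("norm", "g"), c(5, 6)), x = c(x, y))
    res <- pairwise_vs_normal(tab, "x")
    expect_equal(res$p_raw, oracle_mw_exact_p(y, x), tolerance = 1e-10)
  }
})

test_that("pairwise comparisons apply the Bonferroni family correctly", {
  set.seed(13)
  tab <- data.frame(
    group = rep(c("norm", "OHT", "prep", "perim"), c(19, 17, 24, 50)),
    x = rnorm(110))
  res <- pairwise_vs_normal(tab, "x")
  expect_equal(nrow(res), 3)
  expect_equal(res$p_bonferroni, pmin(1, 3 * res$p_raw))
  # a group identical to norm is not significant
  tab2 <- data.frame(group = rep(c("norm", "g"), each = 10),
                     x = rep(seq(1, 10), 2))
  r2 <- pairwise_vs_normal(tab2, "x")
  expect_gt(r2$p_raw, 0.9)
  expect_false(r2$significant)
  # an extreme separation is significant after correction
  tab3 <- data.frame(group = rep(c("norm", "perim"), c(19, 50)),
                     x = c(rnorm(19, 10, 1), rnorm(50, 0, 1)))
  r3 <- pairwise_vs_normal(tab3, "x")
  expect_lt(r3$p_bonferroni, 0.001)
  expect_true(r3$significant)
  expect_error(pairwise_vs_normal(tab3[tab3$group != "norm", ], "x"),
               "reference")
})

test_that("Spearman correlation is calibrated against the copula identity", {
  tab <- data.frame(group = "g", x = 1:20, rnfl_um = (1:20)^2)
  expect_equal(spearman_correlation(tab, "x")$R, 1)
  set.seed(14)
  # bivariate normal with latent r = 0.5: E[rho_s] = 6/pi * asin(r/2)
  target <- 6 / pi * asin(0.25)
  rhat <- replicate(500, {
    z <- rnorm(110); e <- rnorm(110)
    tabr <- data.frame(group = "g", x = 0.5 * z + sqrt(1 - 0.25) * e,
                       rnfl_um = z)
    spearman_correlation(tabr, "x")$R
  })
  expect_lt(abs(mean(rhat) - target), 0.05)
  # independence: mean estimate near 0
  r0 <- replicate(1000, spearman_correlation(
    data.frame(group = "g", x = rnorm(30), rnfl_um = rnorm(30)), "x")$R)
  expect_lt(abs(mean(r0)), 0.03)
  const <- data.frame(group = "g", x = rep(1, 5), rnfl_um = 1:5)
  expect_error(spearman_correlation(const, "x"), "constant")
})

test_that("regression slopes are exact and order-invariant", {
  tab <- data.frame(group = "g", x = 0.06 * seq(40, 100), rnfl_um = seq(40, 100))
  rs <- regression_slope(tab, "x")
  expect_equal(rs$slope_per_10, 0.6)
  expect_equal(rs$intercept, 0, tolerance = 1e-10)
  set.seed(15)
  tab2 <- data.frame(group = "g", x = rnorm(30), rnfl_um = rnorm(30))
  perm <- tab2[sample(30), ]
  expect_equal(regression_slope(perm, "x")$slope,
               regression_slope(tab2, "x")$slope)
  expect_error(regression_slope(
    data.frame(group = "g", x = 1:5, rnfl_um = rep(2, 5)), "x"), "constant")
})

test_that("the repeated-measures CV inverts its own generative model", {
  reps <- data.frame(subject_id = rep(1:9, each = 2), repeat_id = rep(1:2, 9),
                     x = rep(seq(2, 10), each = 2))
  expect_equal(cv_repeated(reps, "x"), 0)
  reps2 <- reps; reps2$x <- reps2$x * 3.7
  expect_equal(cv_repeated(reps2, "x"), 0)          # scale invariance
  set.seed(16)
  cvhat <- replicate(500, {
    mu <- runif(9, 4, 8)
    x <- rep(mu, each = 2) * (1 + rnorm(18, 0, 0.086))
    cv_repeated(data.frame(subject_id = rep(1:9, each = 2),
                           repeat_id = rep(1:2, 9), x = x), "x")
  })
  expect_lt(abs(mean(cvhat) - 0.086) / 0.086, 0.15)
  bad <- reps[-1, ]
  expect_error(cv_repeated(bad, "x"), "exactly 2 repeats")
})

test_that("tests are invariant to row order and ID relabeling", {
  co <- generate_cohort(glaucoma_cohort_spec(seed = 8))
  perm <- co[sample(nrow(co)), ]
  expect_equal(kruskal_wallis(perm, "peak_amplitude"),
               kruskal_wallis(co, "peak_amplitude"))
  expect_equal(spearman_correlation(perm, "steepness"),
               spearman_correlation(co, "steepness"))
  relab <- co; relab$subject_id <- paste0("Z", seq_len(nrow(co)))
  expect_equal(kruskal_wallis(relab, "peak_amplitude"),
               kruskal_wallis(co, "peak_amplitude"))
})
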