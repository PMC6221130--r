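toy_stats <- function(beta_x, beta_y, se_x = 0.01, se_y = 1) {
  structure(data.frame(snp_id = seq_along(beta_x), beta_x = beta_x,
                       se_x = se_x, beta_y = beta_y, se_y = se_y,
                       n_x = 1000L, n_y = 1000L),
            class = c("mr_sumstats", "data.frame"))
}

test_that("IVW reduces to the weighted mean of Wald ratios", {
  # two SNPs, ratios {1, 3}, equal weights -> 2
  st <- toy_stats(beta_x = c(1, 1), beta_y = c(1, 3))
  expect_equal(summary_mr(st, "ivw")$estimate, 2, tolerance = 1e-12)
  # a single SNP: IVW is that SNP's Wald ratio
  st1 <- toy_stats(beta_x = 2, beta_y = 1)
  expect_equal(summary_mr(st1, "ivw")$estimate, 0.5, tolerance = 1e-12)
  # zero exposure association: SNP excluded with a warning
  st0 <- toy_stats(beta_x = c(0, 1, 1), beta_y = c(5, 1, 3))
  expect_warning(est <- summary_mr(st0, "ivw"), "zero exposure")
  expect_equal(est$estimate, 2, tolerance = 1e-12)
})

test_that("Egger regression recovers exact lines and reduces to IVW through origin", {
  st <- toy_stats(beta_x = c(1, 2, 3, 4), beta_y = 0.7 * c(1, 2, 3, 4))
  eg <- summary_mr(st, "egger")
  expect_equal(eg$estimate, 0.7, tolerance = 1e-10)
  expect_equal(eg$intercept, 0, tolerance = 1e-10)
  # no-intercept weighted regression slope == IVW (computed in closed form)
  st2 <- toy_stats(beta_x = c(1, 2), beta_y = c(1.2, 1.7), se_y = c(1, 2))
  w <- 1 / st2$se_y^2
  slope0 <- sum(w * st2$beta_x * st2$beta_y) / sum(w * st2$beta_x^2)
  expect_equal(summary_mr(st2, "ivw")$estimate, slope0, tolerance = 1e-12)
  expect_error(summary_mr(st2, "egger"), class = "triomr_invalid_argument")
})

test_that("weighted median and MBE agree with their defining identities", {
  st <- toy_stats(beta_x = c(1, 1, 1), beta_y = c(1, 2, 100))
  expect_equal(summary_mr(st, "weighted_median", n_boot = 50, seed = 1)$estimate,
               2, tolerance = 1e-8)
  stc <- toy_stats(beta_x = c(1, 1, 1, 1), beta_y = c(3, 3, 3, 3))
  expect_equal(summary_mr(stc, "mbe", n_boot = 50, seed = 2)$estimate, 3,
               tolerance = 1e-8)
  # weighted median pulls toward the heavier ratio
  stw <- toy_stats(beta_x = c(1, 1, 1), beta_y = c(1, 2, 3),
                   se_y = c(0.1, 1, 1))
  expect_lt(summary_mr(stw, "weighted_median", n_boot = 50, seed = 3)$estimate, 2)
})

test_that("per-SNP summary statistics equal the marginal regressions", {
  trios <- sim_small_trios(small_cross_cfg(n_trios = 2000,
                                           n_snps_X = 15, n_snps_Y = 5),
                           seed = 71)
  inst <- sample_instruments(trios, 8, seed = 4)
  st <- snp_summary_stats(trios, inst, half = "A")
  w <- estimate_weights(trios, inst, half = "A")
  expect_equal(st$beta_x, w$weights, tolerance = 1e-10)
  expect_equal(nrow(st), 8)
  # per-SNP slope agrees with lm on one SNP
  idx <- which(trios$split == "A")
  f <- lm(trios$y[idx] ~ trios$g_o[idx, inst[1]])
  expect_equal(st$beta_y[1], unname(coef(f)[2]), tolerance = 1e-10)
  expect_equal(st$se_y[1], summary(f)$coefficients[2, 2], tolerance = 1e-8)
  # permuted outcome: mean association ~ 0
  trios_p <- trios
  set.seed(72)
  trios_p$y <- sample(trios$y)
  stp <- snp_summary_stats(trios_p, inst, half = "A")
  expect_lt(abs(mean(stp$beta_y)), 3 * sd(stp$beta_y) / sqrt(8) + 0.01)
  # two-sample mode uses the opposite half for the exposure regressions
  st2 <- snp_summary_stats(trios, inst, half = "A", two_sample = TRUE)
  expect_false(isTRUE(all.equal(st2$beta_x, st$beta_x)))
  expect_equal(st2$beta_y, st$beta_y, tolerance = 1e-12)
})

test_that("heterogeneity statistics behave at the null and detect structure", {
  st <- toy_stats(beta_x = c(1, 1, 1), beta_y = c(2, 2, 2))
  ht <- heterogeneity_tests(st)
  expect_equal(ht$Q$statistic, 0, tolerance = 1e-12)
  expect_equal(ht$Q$p.value, 1, tolerance = 1e-12)
  expect_identical(ht$Q$df, 2L)
  # calibrated rejection under a homogeneous simulated null
  set.seed(73)
  rej <- mean(replicate(400, {
    bx <- rnorm(8, 0.1, 0.01)
    by <- 0.5 * bx + rnorm(8, 0, 0.02)
    st <- toy_stats(bx, by, se_x = 0.01, se_y = 0.02)
    heterogeneity_tests(st)$Q$p.value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.04)
  # exposure/outcome score correlation flags cross-trait assortment
  trios_a <- sim_small_trios(small_cross_cfg(n_trios = 4000, P = 1), seed = 74)
  gx <- triomr:::panel_set(trios_a$panel, "GX")
  gy <- triomr:::panel_set(trios_a$panel, "GY")
  ct <- score_correlation_test(rowSums(trios_a$g_o[, gx]),
                               rowSums(trios_a$g_o[, gy]))
  expect_lt(ct$p.value, 0.01)
})
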