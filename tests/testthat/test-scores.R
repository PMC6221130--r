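test_that("weights recover marginal genotype-exposure slopes", {
  # noiseless X = sum of allele counts -> unit slopes under linkage equilibrium
  set.seed(41)
  n <- 4000
  g <- matrix(rbinom(n * 6, 2, 0.3), n, 6)
  trios <- manual_trios(g_o = g, x = rowSums(g), y = rnorm(n))
  w <- estimate_weights(trios, 1:6, half = "A")
  expect_length(w$weights, 6)
  expect_true(all(abs(w$weights - 1) < 0.1))

  # exposure permuted independently of genotype -> slopes around 0
  trios_p <- manual_trios(g_o = g, x = sample(rowSums(g)), y = rnorm(n))
  wp <- estimate_weights(trios_p, 1:6, half = "A")
  expect_lt(abs(mean(wp$weights)), 0.05)

  # monomorphic SNP: weight 0 with a warning
  g2 <- cbind(g, 1L)
  trios_m <- manual_trios(g_o = g2, x = rowSums(g), y = rnorm(n))
  expect_warning(wm <- estimate_weights(trios_m, 1:7, half = "A"),
                 "monomorphic")
  expect_identical(wm$weights[7], 0)
})

test_that("score arithmetic, linearity and conservation hold", {
  g <- rbind(c(0L, 1L), c(2L, 2L))
  trios <- manual_trios(g_o = g, x = c(1, 2), y = c(0, 0),
                        split = factor(c("B", "B"), levels = c("A", "B")))
  w <- structure(list(snps = 1:2, weights = c(0.5, 1), half = "A"),
                 class = "allele_weights")
  sc <- build_scores(trios, w, half = "B")
  expect_equal(sc$S, c(1, 3))
  # linearity in the weights
  w2 <- w; w2$weights <- 3 * w$weights
  expect_equal(build_scores(trios, w2, half = "B")$S, 3 * sc$S)
  # all-zero weights
  w0 <- w; w0$weights <- c(0, 0)
  expect_equal(build_scores(trios, w0, half = "B")$S, c(0, 0))

  # conservation on simulated trios: parent score = transmitted + nontransmitted
  trios_s <- sim_small_trios(seed = 43)
  inst <- sample_instruments(trios_s, 8, seed = 2)
  ws <- estimate_weights(trios_s, inst, half = "A")
  scs <- build_scores(trios_s, ws, half = "B")
  t_m_score <- as.numeric(trios_s$t_m[scs$idx, inst] %*% ws$weights)
  t_f_score <- as.numeric(trios_s$t_f[scs$idx, inst] %*% ws$weights)
  expect_equal(t_m_score + scs$W_m, scs$S_m, tolerance = 1e-12)
  expect_equal(t_f_score + scs$W_f, scs$S_f, tolerance = 1e-12)
  # offspring score = transmitted halves of the parents
  expect_equal(scs$S, t_m_score + t_f_score, tolerance = 1e-12)
  # ... = mid-parent score + Mendelian sampling deviation with mean ~ 0
  dev <- scs$S - (scs$S_m + scs$S_f) / 2
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(length(dev)))
})

test_that("overfitting guard refuses same-half scoring unless overridden", {
  trios <- sim_small_trios(seed = 44)
  inst <- sample_instruments(trios, 5, seed = 3)
  w <- estimate_weights(trios, inst, half = "A")
  expect_error(build_scores(trios, w, half = "A"),
               class = "triomr_invalid_argument")
  sc <- build_scores(trios, w, half = "A", allow_same_half = TRUE)
  expect_length(sc$S, sum(trios$split == "A"))
  # external numeric weights score the full sample
  sce <- build_scores(trios, rep(1, 5), snps = inst)
  expect_length(sce$S, trios$n)
})

test_that("phase-free nontransmitted inference matches the truth when determined", {
  trios <- sim_small_trios(small_cross_cfg(n_trios = 500), seed = 45)
  inf <- infer_nontransmitted(trios$g_o, trios$g_m, trios$g_f)
  determined <- !(trios$g_m == 1L & trios$g_f == 1L & trios$g_o == 1L)
  expect_identical(inf$nt_m[determined],
                   as.numeric(trios$nt_m)[determined])
  expect_identical(inf$nt_f[determined],
                   as.numeric(trios$nt_f)[determined])
  amb <- !determined
  expect_true(all(inf$nt_m[amb] == 0.5))
  expect_identical(inf$n_ambiguous, as.integer(rowSums(amb)))
  # Mendelian inconsistency detected
  expect_error(infer_nontransmitted(matrix(2L), matrix(0L), matrix(0L)),
               class = "triomr_invalid_argument")
})
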