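test_that("draw_panel respects frequency bounds and rejects bad arguments", {
  p <- draw_panel(10, 0.5, 0.5, seed = 1)
  expect_equal(p$freq, rep(0.5, 10))
  p2 <- draw_panel(50, 0.1, 0.5, seed = 2)
  expect_length(p2$freq, 50)
  expect_true(all(p2$freq >= 0.1 & p2$freq <= 0.5))
  expect_error(draw_panel(0, 0.1, 0.5), class = "triomr_invalid_argument")
  expect_error(draw_panel(5, 0, 0.5), class = "triomr_invalid_argument")
  expect_error(draw_panel(5, 0.5, 0.1), class = "triomr_invalid_argument")
})

test_that("founder genotypes follow Hardy-Weinberg at the panel frequency", {
  n <- 25000
  panel <- draw_panel(3, 0.5, 0.5)
  pop <- simulate_founders(panel, n, seed = 7)
  G <- pop_genotypes(pop)
  expect_true(all(G %in% 0:2))
  # genotype class proportions ~ Binomial(2, 1/2): 1/4, 1/2, 1/4
  for (j in 1:3) {
    tab <- tabulate(G[, j] + 1L, 3L) / (2 * n)
    se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / (2 * n))
    expect_true(all(abs(tab - c(.25, .5, .25)) < 4.5 * se))
  }
  # mean allele count ~ 2p for a drawn panel
  panel2 <- draw_panel(20, 0.1, 0.5, seed = 3)
  pop2 <- simulate_founders(panel2, n, seed = 8)
  mg <- colMeans(pop_genotypes(pop2))
  se2 <- sqrt(2 * panel2$freq * (1 - panel2$freq) / (2 * n))
  expect_true(all(abs(mg - 2 * panel2$freq) < 4.5 * se2))
})

test_that("phenotype model calibrates heritability and variance budget", {
  cfg <- scenario_config(n_trios = 15000, n_snps_X = 30, n_snps_Y = 10,
                         h2_X = 0.5, h2_Y = 0.1)
  set.seed(11)
  pop <- compute_phenotypes(
    simulate_founders(triomr:::scenario_panel(cfg), cfg$n_trios), cfg)
  h2_hat <- var(pop$phen$gscore_X) / var(pop$phen$X)
  expect_lt(abs(h2_hat - 0.5), 0.02)
  expect_lt(abs(var(pop$phen$X) - 1), 0.03)
  expect_lt(abs(var(pop$phen$Y) - 1), 0.03)

  # h2_X = 0: genetic score uncorrelated with X
  cfg0 <- scenario_config(n_trios = 8000, n_snps_X = 30, n_snps_Y = 10,
                          h2_X = 0, h2_Y = 0.1)
  set.seed(12)
  pop0 <- compute_phenotypes(
    simulate_founders(triomr:::scenario_panel(cfg0), cfg0$n_trios), cfg0)
  ZX <- triomr:::score_sums_cpp(pop0$hap1, pop0$hap2, 1:30)
  expect_lt(abs(cor(ZX, pop0$phen$X)), 0.025)

  # independent panels: no causal effect, no confounding -> ZX independent of Y
  cfgi <- scenario_config(n_trios = 8000, n_snps_X = 30, n_snps_Y = 10,
                          h2_X = 0.5, h2_Y = 0.5, beta_XY = 0,
                          confounder_share = 0)
  set.seed(13)
  popi <- compute_phenotypes(
    simulate_founders(triomr:::scenario_panel(cfgi), cfgi$n_trios), cfgi)
  ZXi <- triomr:::score_sums_cpp(popi$hap1, popi$hap2, 1:30)
  expect_lt(abs(cor(ZXi, popi$phen$Y)), 0.025)

  expect_error(scenario_config(h2_X = 0.9, confounder_share = 0.2),
               class = "triomr_invalid_argument")
})

test_that("proxy noise is calibrated so cor(trait, proxy) = P", {
  set.seed(21)
  x <- rnorm(40000)
  expect_identical(make_proxy(x, 1), x)
  expect_error(make_proxy(x, 0), class = "triomr_invalid_argument")
  for (P in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
    xp <- make_proxy(x, P)
    expect_lt(abs(cor(x, xp) - P), 0.02)
  }
})

test_that("auxiliary phenotype definitions evaluate in declared order", {
  defs <- list(phenotype_def("A", c(X = 1), noise_sd = 0),
               phenotype_def("B", c(A = 2, U = 1), noise_sd = 0))
  cfg <- scenario_config(n_trios = 200, n_snps_X = 5, n_snps_Y = 5,
                         phenotype_defs = defs)
  set.seed(31)
  pop <- compute_phenotypes(
    simulate_founders(triomr:::scenario_panel(cfg), cfg$n_trios), cfg)
  expect_equal(pop$phen$A, pop$phen$X)
  expect_equal(pop$phen$B, 2 * pop$phen$X + pop$phen$U)
  bad <- scenario_config(n_trios = 100, n_snps_X = 5, n_snps_Y = 5,
                         phenotype_defs = list(
                           phenotype_def("C", c(nope = 1))))
  set.seed(32)
  expect_error(compute_phenotypes(
    simulate_founders(triomr:::scenario_panel(bad), 100), bad),
    class = "triomr_invalid_argument")
})
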