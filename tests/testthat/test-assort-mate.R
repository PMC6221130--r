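make_phenotyped_pops <- function(n = 3000, seed = 1, cfg = NULL) {
  if (is.null(cfg))
    cfg <- scenario_config(n_trios = n, n_snps_X = 10, n_snps_Y = 5,
                           h2_X = 0.5, h2_Y = 0.5)
  set.seed(seed)
  pop <- compute_phenotypes(
    simulate_founders(triomr:::scenario_panel(cfg), n), cfg)
  list(f = triomr:::pop_subset(pop, which(pop$sex == 1L)),
       m = triomr:::pop_subset(pop, which(pop$sex == 2L)))
}

test_that("cross-trait sorting gives Spearman correlation 1 within each set", {
  pops <- make_phenotyped_pops()
  cp <- assort_pairs(pops$f, pops$m, assortment_spec("cross_trait", "X", "Y"),
                     P = 1, seed = 5)
  s1 <- cp$set == 1L
  # set 1: women sorted on X, men on Y -> perfect rank concordance
  expect_equal(cor(pops$f$phen$X[cp$wife[s1]], pops$m$phen$Y[cp$husband[s1]],
                   method = "spearman"), 1)
  # set 2: roles swapped
  expect_equal(cor(pops$f$phen$Y[cp$wife[!s1]], pops$m$phen$X[cp$husband[!s1]],
                   method = "spearman"), 1)
})

test_that("single-trait sorting co-sorts both sexes on the same trait", {
  pops <- make_phenotyped_pops(seed = 2)
  cp <- assort_pairs(pops$f, pops$m, assortment_spec("single_trait", "X"),
                     P = 1, seed = 6)
  for (s in 1:2) {
    i <- cp$set == s
    expect_equal(cor(pops$f$phen$X[cp$wife[i]], pops$m$phen$X[cp$husband[i]],
                     method = "spearman"), 1)
  }
})

test_that("random mating yields null spouse correlation; sizes must match", {
  pops <- make_phenotyped_pops(seed = 3)
  cp <- assort_pairs(pops$f, pops$m, assortment_spec("none"), seed = 7)
  expect_lt(abs(cor(pops$f$phen$X[cp$wife], pops$m$phen$X[cp$husband])), 0.06)
  expect_error(
    assort_pairs(pops$f, triomr:::pop_subset(pops$m, 1:10),
                 assortment_spec("none")),
    class = "triomr_invalid_argument")
})

test_that("spouse-pairing is exchangeable under random mating (replicated)", {
  # 200 pairings of fixed phenotypes: mean correlation ~ 0 within 3 MC SEs
  set.seed(8)
  xf <- rnorm(1000); xm <- rnorm(1000)
  cors <- replicate(200, {
    w <- sample.int(1000); h <- sample.int(1000)
    cor(xf[w], xm[h])
  })
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(200))
})

test_that("spouse correlation increases strictly with assortment strength", {
  cors <- vapply(c(0.2, 0.6, 1.0), function(P) {
    mean(vapply(1:100, function(r) {
      set.seed(1000 + r)
      n <- 500
      xf <- rnorm(n); ym <- rnorm(n)
      xpf <- make_proxy(xf, P); ypm <- make_proxy(ym, P)
      # one sorted set suffices to measure the coupling strength
      cor(xf[order(xpf)], ym[order(ypm)])
    }, numeric(1)))
  }, numeric(1))
  expect_true(cors[1] < cors[2] && cors[2] < cors[3])
})

test_that("meiosis conserves alleles and transmits fairly", {
  pops <- make_phenotyped_pops(n = 4000, seed = 4)
  cp <- assort_pairs(pops$f, pops$m, assortment_spec("none"), seed = 9)
  off <- mate(cp, pops$f, pops$m, n_offspring = 2, seed = 10)
  child <- off$offspring
  n <- 4000
  g_m <- pop_genotypes(pops$f)[rep(cp$wife, 2), ]
  g_f <- pop_genotypes(pops$m)[rep(cp$husband, 2), ]
  t_m <- child$hap1
  t_f <- child$hap2
  # offspring genotype = maternal + paternal transmitted
  expect_true(all(pop_genotypes(child) >= 0 & pop_genotypes(child) <= 2))
  expect_identical(pop_genotypes(child), t_m + t_f)
  # transmitted + nontransmitted = parent genotype, per SNP and parent
  expect_identical(t_m + off$nt_m, g_m)
  expect_identical(t_f + off$nt_f, g_f)
  # fair transmission from heterozygous parent SNPs (>= 1e4 meioses)
  het <- g_m == 1L
  expect_gt(sum(het), 1e4)
  p_hat <- mean(t_m[het])
  expect_lt(abs(p_hat - 0.5), 4.5 * sqrt(0.25 / sum(het)))
})
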