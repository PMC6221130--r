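# shared fixtures: small scenarios keep the unit suite fast; the
# acceptance file runs the full-size study conditions

small_cross_cfg <- function(n_trios = 2000, P = 1, h2_X = 0.5, h2_Y = 0.5,
                            beta_XY = 0, n_generations = 1,
                            n_snps_X = 20, n_snps_Y = 10,
                            n_instrument_snps = min(10, n_snps_X), seed = NULL) {
  scenario_config(n_trios = n_trios, n_snps_X = n_snps_X, n_snps_Y = n_snps_Y,
                  h2_X = h2_X, h2_Y = h2_Y, beta_XY = beta_XY, P = P,
                  assortment = assortment_spec("cross_trait", "X", "Y"),
                  n_generations = n_generations,
                  n_instrument_snps = n_instrument_snps, seed = seed)
}

small_random_cfg <- function(n_trios = 2000, h2_X = 0.5, h2_Y = 0.5,
                             beta_XY = 0, seed = NULL, ...) {
  scenario_config(n_trios = n_trios, n_snps_X = 20, n_snps_Y = 10,
                  h2_X = h2_X, h2_Y = h2_Y, beta_XY = beta_XY,
                  assortment = assortment_spec("none"), seed = seed, ...)
}

sim_small_trios <- function(cfg = small_cross_cfg(), seed = 42) {
  build_trio_dataset(advance_generations(cfg, seed = seed))
}

# hand-made trio dataset with known genotypes (no simulation)
manual_trios <- function(g_o, x, y, split = NULL, g_m = NULL, g_f = NULL,
                         nt_m = NULL, nt_f = NULL, x_m = NULL, x_f = NULL) {
  n <- nrow(g_o)
  if (is.null(split))
    split <- factor(rep(c("A", "B"), length.out = n), levels = c("A", "B"))
  triomr:::new_trio_dataset(g_o = g_o, g_m = g_m, g_f = g_f,
                            nt_m = nt_m, nt_f = nt_f,
                            x = x, y = y, x_m = x_m, x_f = x_f,
                            split = split, panel = NULL)
}

# independent textbook 2SLS oracle: explicit projection-matrix algebra
oracle_2sls <- function(y, endog, exog = NULL, instruments) {
  W <- cbind(1, endog, exog)
  Z <- cbind(1, instruments, exog)
  PZ <- Z %*% solve(t(Z) %*% Z) %*% t(Z)
  beta <- solve(t(W) %*% PZ %*% W, t(W) %*% PZ %*% y)
  res <- y - W %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(W))
  vc <- s2 * solve(t(W) %*% PZ %*% W)
  list(beta = as.numeric(beta), vcov = vc)
}
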