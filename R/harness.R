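#' Run a replicated Monte-Carlo scenario
#'
#' For each replicate: simulate the scenario ([advance_generations()] then
#' [build_trio_dataset()]), sample the instrument SNPs, estimate allele-score
#' weights in half A, score half B, and run every requested estimator. Each
#' replicate runs under a seed derived deterministically from `seed` and the
#' replicate index, so any replicate is reproducible in isolation and results
#' do not depend on execution order.
#'
#' @param cfg A [scenario_config()].
#' @param n_reps Number of replicates.
#' @param methods Character vector from `"tsls1"`, `"tsls2"`, `"tsls3"`,
#'   `"ivw"`, `"egger"`, `"weighted_median"`, `"mbe"`.
#' @param seed Master seed (defaults to `cfg$seed`, or 1).
#' @param robust Use robust SEs in the TSLS estimators.
#' @param n_boot Bootstrap replicates for weighted-median/MBE SEs.
#' @param verbose Print one line per replicate.
#' @return A `scenario_records` data frame, one row per replicate x method,
#'   with columns `replicate`, `seed`, `method`, `estimate`, `se`,
#'   `ci_lower`, `ci_upper`, `p.value`, `assort_stat`, `assort_p`,
#'   between-spouse correlations (`sp_cor_*`), and `error` (NA unless the
#'   replicate failed). The scenario config and failure count are attached as
#'   attributes.
#' @export
run_scenario <- function(cfg, n_reps, methods = c("tsls1", "tsls2", "tsls3"),
                         seed = NULL, robust = FALSE, n_boot = 200,
                         verbose = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  n_reps <- check_count(n_reps, "n_reps")
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("tsls1", "tsls2", "tsls3",
                                   "ivw", "egger", "weighted_median", "mbe"))
  seed <- seed %||% cfg$seed %||% 1L
  rows <- vector("list", n_reps)
  n_fail <- 0L
  for (r in seq_len(n_reps)) {
    seed_r <- derive_seed(seed, r)
    rec <- tryCatch(
      run_replicate(cfg, methods, seed_r, robust, n_boot),
      error = function(e) {
        data.frame(method = methods, estimate = NA_real_, se = NA_real_,
                   ci_lower = NA_real_, ci_upper = NA_real_,
                   p.value = NA_real_, assort_stat = NA_real_,
                   assort_p = NA_real_,
                   sp_cor_XX = NA_real_, sp_cor_XY = NA_real_,
                   sp_cor_YX = NA_real_, sp_cor_YY = NA_real_,
                   error = conditionMessage(e))
      })
    if (!all(is.na(rec$error))) n_fail <- n_fail + 1L
    rec <- cbind(replicate = r, seed = seed_r, rec)
    rows[[r]] <- rec
    if (verbose)
      message("replicate ", r, "/", n_reps, if (!all(is.na(rec$error)))
        paste0(" FAILED: ", rec$error[1]))
  }
  out <- do.call(rbind, rows)
  structure(out, cfg = cfg, n_fail = n_fail, master_seed = seed,
            class = c("scenario_records", "data.frame"))
}

run_replicate <- function(cfg, methods, seed_r, robust, n_boot) {
  sim <- advance_generations(cfg, seed = seed_r)
  need_parents <- any(methods %in% c("tsls2", "tsls3"))
  trios <- build_trio_dataset(sim, transmitted = FALSE,
                              parents = need_parents)
  inst <- sample_instruments(trios, cfg$n_instrument_snps)
  w <- estimate_weights(trios, inst, half = "A")
  sc <- build_scores(trios, w, half = "B")
  needs_ss <- any(methods %in% c("ivw", "egger", "weighted_median", "mbe"))
  ss <- if (needs_ss) snp_summary_stats(trios, inst, half = "B")
  one <- function(m) {
    est <- switch(m,
      tsls1 = mr_tsls1(sc, trios, robust),
      tsls2 = mr_tsls2(sc, trios, robust),
      tsls3 = mr_tsls3(sc, trios, robust),
      summary_mr(ss, m, n_boot = n_boot))
    data.frame(method = m, estimate = est$estimate, se = est$se,
               ci_lower = est$ci_lower, ci_upper = est$ci_upper,
               p.value = est$p.value,
               assort_stat = est$assort_test$statistic %||% NA_real_,
               assort_p = est$assort_test$p.value %||% NA_real_)
  }
  res <- do.call(rbind, lapply(methods, one))
  res$sp_cor_XX <- sim$spouse_cor[["XX"]]
  res$sp_cor_XY <- sim$spouse_cor[["XY"]]
  res$sp_cor_YX <- sim$spouse_cor[["YX"]]
  res$sp_cor_YY <- sim$spouse_cor[["YY"]]
  res$error <- NA_character_
  res
}

#' Aggregate replicate records into a scenario summary
#'
#' @param records A `scenario_records` data frame from [run_scenario()].
#' @param true_beta True structural causal effect of the scenario (used for
#'   bias and false rejection; defaults to the config's `beta_XY`).
#' @return A `scenario_summary` data frame, one row per method, with
#'   `n_reps`, `mean_estimate`, `bias` (mean estimate minus truth),
#'   `mcse_bias` (empirical SE / sqrt(n_reps)), `empirical_se` (SD of the
#'   estimates), `mean_model_se`, `false_rejection` (share of 95% CIs
#'   excluding the truth), `power` (share of CIs excluding 0), and
#'   `assort_rejection` (share of assortment tests with p < 0.05).
#' @export
summarize_scenario <- function(records, true_beta = NULL) {
  stopifnot(is.data.frame(records))
  cfg <- attr(records, "cfg")
  true_beta <- true_beta %||% cfg$beta_XY %||%
    stop_invalid("true_beta is required when records carry no config")
  ok <- records[is.na(records$error) & !is.na(records$estimate), , drop = FALSE]
  if (!nrow(ok)) stop("no successful replicates to summarize")
  per_method <- lapply(split(ok, ok$method), function(d) {
    data.frame(
      method = d$method[1], n_reps = nrow(d),
      mean_estimate = mean(d$estimate),
      bias = mean(d$estimate) - true_beta,
      mcse_bias = sd(d$estimate) / sqrt(nrow(d)),
      empirical_se = sd(d$estimate),
      mean_model_se = mean(d$se),
      false_rejection = mean(d$ci_lower > true_beta | d$ci_upper < true_beta),
      power = mean(d$ci_lower > 0 | d$ci_upper < 0),
      assort_rejection = if (all(is.na(d$assort_p))) NA_real_
                         else mean(d$assort_p < 0.05, na.rm = TRUE))
  })
  out <- do.call(rbind, per_method)
  rownames(out) <- NULL
  out <- out[order(match(out$method, unique(records$method))), , drop = FALSE]
  structure(out, true_beta = true_beta, cfg = cfg,
            n_fail = attr(records, "n_fail"),
            spouse_cor = colMeans(ok[, grep("^sp_cor_", names(ok))],
                                  na.rm = TRUE),
            class = c("scenario_summary", "data.frame"))
}

#' @export
print.scenario_summary <- function(x, digits = 4, ...) {
  cat("Scenario summary (true beta = ", attr(x, "true_beta"),
      if (!is.null(attr(x, "n_fail")) && attr(x, "n_fail") > 0)
        paste0(", ", attr(x, "n_fail"), " failed replicate(s)"),
      ")\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  sp <- attr(x, "spouse_cor")
  if (!is.null(sp))
    cat("mean between-spouse correlations:",
        paste(sprintf("%s = %.3f", sub("sp_cor_", "", names(sp)), sp),
              collapse = ", "), "\n")
  invisible(x)
}

#' Preset scenario grids mirroring the simulation study designs
#'
#' * `table1` — one generation of cross-trait assortment on X and Y,
#'   `h2_X = 0.5`, no causal effect; grid of P in \{0.2, 0.6, 1.0\},
#'   `h2_Y` in \{0.1, 0.5\}, instrument SNPs in \{10, 50\} and GY size in
#'   \{10, 50\} (24 configs).
#' * `table2` — random mating, true effect 0.05, `h2_X` x `h2_Y` in
#'   \{0.1, 0.5\}^2 (4 configs).
#' * `figure2` — one generation, P in \{0.2, 0.4, 0.6, 0.8, 1.0\} x
#'   `h2_X`, `h2_Y` in \{0.1, 0.5\}^2.
#' * `figure3` — cross-trait assortment accumulated over 1..9 generations.
#' * `single_trait_suite` — single-trait assortment on X, on Y, and on an
#'   auxiliary trait genetically correlated with both X and Y via horizontal
#'   (loading on the genetic scores of all variants) or vertical (loading on
#'   the phenotypes) pleiotropy.
#' * `cross_trait_correlated_suite` — cross-trait assortment on two auxiliary
#'   traits correlated with X resp. Y via horizontal or vertical pleiotropy.
#'
#' @param name Preset name.
#' @param n_trios Couples per generation.
#' @param P Assortment strength for `figure3` and the auxiliary-trait suites.
#' @param h2_X,h2_Y Heritabilities for `figure3` and the auxiliary-trait
#'   suites.
#' @return Named list of `scenario_config` objects.
#' @export
preset_scenarios <- function(name = c("table1", "table2", "figure2", "figure3",
                                      "single_trait_suite",
                                      "cross_trait_correlated_suite"),
                             n_trios = 40000, P = 0.7,
                             h2_X = 0.5, h2_Y = 0.5) {
  name <- match.arg(name)
  cross_xy <- assortment_spec("cross_trait", "X", "Y")
  out <- switch(name,
    table1 = {
      grid <- expand.grid(P = c(0.2, 0.6, 1.0), h2_Y = c(0.1, 0.5),
                          gi = c(10L, 50L), gy = c(10L, 50L))
      lapply(seq_len(nrow(grid)), function(i)
        scenario_config(n_trios = n_trios, n_snps_X = 50,
                        n_snps_Y = grid$gy[i], h2_X = 0.5, h2_Y = grid$h2_Y[i],
                        beta_XY = 0, P = grid$P[i], assortment = cross_xy,
                        n_instrument_snps = grid$gi[i]))
    },
    table2 = {
      grid <- expand.grid(h2_X = c(0.1, 0.5), h2_Y = c(0.1, 0.5))
      lapply(seq_len(nrow(grid)), function(i)
        scenario_config(n_trios = n_trios, h2_X = grid$h2_X[i],
                        h2_Y = grid$h2_Y[i], beta_XY = 0.05,
                        assortment = assortment_spec("none")))
    },
    figure2 = {
      grid <- expand.grid(P = seq(0.2, 1, 0.2), h2_X = c(0.1, 0.5),
                          h2_Y = c(0.1, 0.5))
      lapply(seq_len(nrow(grid)), function(i)
        scenario_config(n_trios = n_trios, h2_X = grid$h2_X[i],
                        h2_Y = grid$h2_Y[i], beta_XY = 0, P = grid$P[i],
                        assortment = cross_xy))
    },
    figure3 = lapply(1:9, function(g)
      scenario_config(n_trios = n_trios, h2_X = h2_X, h2_Y = h2_Y,
                      beta_XY = 0, P = P, assortment = cross_xy,
                      n_generations = g)),
    single_trait_suite = {
      aux_h <- phenotype_def("C_horiz", c(gscore_X = 1, gscore_Y = 1),
                             noise_sd = 1)
      aux_v <- phenotype_def("C_vert", c(X = 1, Y = 1), noise_sd = 1)
      base <- function(trait, defs = list())
        scenario_config(n_trios = n_trios, h2_X = h2_X, h2_Y = h2_Y,
                        beta_XY = 0, P = P,
                        assortment = assortment_spec("single_trait", trait),
                        phenotype_defs = defs)
      list(on_X = base("X"), on_Y = base("Y"),
           on_horizontal_pleiotropy = base("C_horiz", list(aux_h)),
           on_vertical_pleiotropy = base("C_vert", list(aux_v)))
    },
    cross_trait_correlated_suite = {
      defs_h <- list(
        phenotype_def("A_x", c(gscore_X = 1), noise_sd = sqrt(1 - h2_X)),
        phenotype_def("A_y", c(gscore_Y = 1), noise_sd = sqrt(1 - h2_Y)))
      defs_v <- list(
        phenotype_def("V_x", c(X = 1), noise_sd = 0.7),
        phenotype_def("V_y", c(Y = 1), noise_sd = 0.7))
      base <- function(a, b, defs)
        scenario_config(n_trios = n_trios, h2_X = h2_X, h2_Y = h2_Y,
                        beta_XY = 0, P = P,
                        assortment = assortment_spec("cross_trait", a, b),
                        phenotype_defs = defs)
      list(horizontal = base("A_x", "A_y", defs_h),
           vertical = base("V_x", "V_y", defs_v))
    })
  if (is.null(names(out)))
    names(out) <- vapply(out, scenario_id, character(1))
  out
}

# compact identifier used in output tables
scenario_id <- function(cfg) {
  paste0("P", cfg$P, "_h2X", cfg$h2_X, "_h2Y", cfg$h2_Y,
         "_gi", cfg$n_instrument_snps, "_gy", cfg$n_snps_Y,
         "_gen", cfg$n_generations,
         if (cfg$assortment$pattern == "none") "_none")
}
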