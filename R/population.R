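# Population container: phased haplotypes plus phenotypes for one generation.
# Haplotypes are integer matrices (individuals x SNPs) of 0/1 allele
# indicators; genotype = hap1 + hap2, exposed by pop_genotypes(). Sex is
# 1 = female, 2 = male.

new_population <- function(hap1, hap2, sex, panel,
                           mother = NULL, father = NULL) {
  stopifnot(is.matrix(hap1), is.matrix(hap2),
            all(dim(hap1) == dim(hap2)), nrow(hap1) == length(sex),
            ncol(hap1) == panel$n_snps)
  structure(list(hap1 = hap1, hap2 = hap2, sex = as.integer(sex),
                 panel = panel, phen = NULL,
                 mother = mother, father = father),
            class = "population")
}

pop_size <- function(pop) nrow(pop$hap1)

#' Genotype matrix of a population
#'
#' @param pop A `population`.
#' @return Integer matrix of 0/1/2 effect-allele counts (individuals x SNPs).
#' @export
pop_genotypes <- function(pop) {
  stopifnot(inherits(pop, "population"))
  genotype_rows_cpp(pop$hap1, pop$hap2, seq_len(pop_size(pop)))
}

pop_subset <- function(pop, idx) {
  out <- pop
  out$hap1 <- pop$hap1[idx, , drop = FALSE]
  out$hap2 <- pop$hap2[idx, , drop = FALSE]
  out$sex <- pop$sex[idx]
  if (!is.null(pop$phen)) out$phen <- lapply(pop$phen, `[`, idx)
  if (!is.null(pop$mother)) out$mother <- pop$mother[idx]
  if (!is.null(pop$father)) out$father <- pop$father[idx]
  out
}

#' @export
print.population <- function(x, ...) {
  cat("<population> ", pop_size(x), " individuals (",
      sum(x$sex == 1L), " female, ", sum(x$sex == 2L), " male); ",
      x$panel$n_snps, " SNPs; phenotypes: ",
      if (is.null(x$phen)) "none" else paste(names(x$phen), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Build the scenario's combined panel: GX then GY SNPs.
scenario_panel <- function(cfg) {
  freq <- runif(cfg$n_snps_X + cfg$n_snps_Y, cfg$maf_low, cfg$maf_high)
  new_snp_panel(freq, rep(c("GX", "GY"), c(cfg$n_snps_X, cfg$n_snps_Y)))
}

#' Simulate founder couples
#'
#' Draws `n_couples` females and `n_couples` males with phased genotypes under
#' Hardy-Weinberg and linkage equilibrium: every haplotype allele is an
#' independent Bernoulli draw at the panel frequency.
#'
#' @param panel An `snp_panel`.
#' @param n_couples Number of couples (population is `2 * n_couples`).
#' @param seed Optional integer seed.
#' @return A `population` of founders (no parent links), females first.
#' @export
simulate_founders <- function(panel, n_couples, seed = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  n_couples <- check_count(n_couples, "n_couples")
  with_seed(seed, {
    n <- 2L * n_couples
    hap1 <- draw_haplotypes_cpp(n, panel$freq)
    hap2 <- draw_haplotypes_cpp(n, panel$freq)
    new_population(hap1, hap2, rep(1:2, each = n_couples), panel)
  })
}

# structural effect sizes: delta = sqrt(h2 / var0(Z)), var0 from founder theory
scenario_deltas <- function(cfg, panel) {
  vX <- panel_score_var(panel, "GX")
  vY <- panel_score_var(panel, "GY")
  list(dX = if (cfg$h2_X > 0) sqrt(cfg$h2_X / vX) else 0,
       dY = if (cfg$h2_Y > 0) sqrt(cfg$h2_Y / vY) else 0)
}

#' Attach phenotypes to a population
#'
#' Computes the structural phenotypes X and Y, the shared confounder U, and
#' any auxiliary traits declared in `cfg$phenotype_defs`, in declared order.
#' Genetic scores are unweighted allele-count sums over the GX resp. GY panel
#' sets, scaled by the structural constants \eqn{\delta_X, \delta_Y} derived
#' from the target heritabilities and the theoretical founder score variances
#' (see [scenario_config()]).
#'
#' @param pop A `population` with genotypes.
#' @param cfg A `scenario_config`.
#' @param seed Optional integer seed for the environmental draws.
#' @return The population with `$phen` holding at least
#'   `X`, `Y`, `U`, `gscore_X`, `gscore_Y`.
#' @export
compute_phenotypes <- function(pop, cfg, seed = NULL) {
  stopifnot(inherits(pop, "population"), inherits(cfg, "scenario_config"))
  panel <- pop$panel
  d <- scenario_deltas(cfg, panel)
  n <- pop_size(pop)
  cs <- cfg$confounder_share
  var_eX <- 1 - cfg$h2_X - cs
  var_eY <- 1 - cfg$h2_Y - cs
  with_seed(seed, {
    ZX <- score_sums_cpp(pop$hap1, pop$hap2, panel_set(panel, "GX"))
    ZY <- score_sums_cpp(pop$hap1, pop$hap2, panel_set(panel, "GY"))
    U <- rnorm(n)
    gX <- d$dX * ZX
    gY <- d$dY * ZY
    X <- gX + sqrt(cs) * U + rnorm(n, 0, sqrt(var_eX))
    Y <- cfg$beta_XY * X + gY + sqrt(cs) * U + rnorm(n, 0, sqrt(var_eY))
    phen <- list(X = X, Y = Y, U = U, gscore_X = gX, gscore_Y = gY)
    for (def in cfg$phenotype_defs) {
      val <- rnorm(n, 0, def$noise_sd)
      for (term in names(def$terms)) {
        if (is.null(phen[[term]]))
          stop_invalid("phenotype_def '", def$name,
                       "' references undefined term '", term, "'")
        val <- val + def$terms[[term]] * phen[[term]]
      }
      phen[[def$name]] <- val
    }
    pop$phen <- phen
    pop
  })
}

#' Build a noisy assortment proxy
#'
#' The proxy equals the phenotype plus independent Gaussian noise with
#' variance `var(values) * (1 - P^2) / P^2`, so that `cor(values, proxy) = P`
#' in expectation. The proxy is what partners actually sort on; everything
#' else entering partner choice is absorbed in the noise.
#'
#' @param values Numeric phenotype vector.
#' @param P Assortment strength in `(0, 1]`; `P = 1` returns `values`
#'   unchanged. `P = 0` is not a proxy (use assortment pattern `"none"`).
#' @param seed Optional integer seed.
#' @return Numeric vector of proxy values.
#' @export
make_proxy <- function(values, P, seed = NULL) {
  if (!is.numeric(P) || length(P) != 1L || is.na(P) || P <= 0 || P > 1)
    stop_invalid("P must be in (0, 1]; random mating is expressed as ",
                 "assortment pattern \"none\", not P = 0")
  if (P == 1) return(values)
  with_seed(seed,
            values + rnorm(length(values), 0, sd(values) * sqrt(1 - P^2) / P))
}
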