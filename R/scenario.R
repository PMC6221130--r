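#' Describe an assortment pattern
#'
#' @param pattern One of `"none"` (random mating), `"single_trait"` (both
#'   partners selected on the same trait) or `"cross_trait"` (each partner
#'   selected on a different trait).
#' @param trait_a,trait_b Phenotype names the pairing operates on. For
#'   `single_trait` only `trait_a` is used; for `cross_trait` women carrying
#'   high `trait_a` are matched to men carrying high `trait_b` in one half of
#'   the population and vice versa in the other.
#' @return An `assortment_spec` list.
#' @export
assortment_spec <- function(pattern = c("none", "single_trait", "cross_trait"),
                            trait_a = "X", trait_b = "Y") {
  pattern <- match.arg(pattern)
  structure(list(pattern = pattern,
                 trait_a = as.character(trait_a),
                 trait_b = as.character(trait_b)),
            class = "assortment_spec")
}

#' Define an auxiliary phenotype
#'
#' Auxiliary traits are linear combinations of the structural genetic scores,
#' upstream phenotypes, the confounder and fresh noise. They express
#' pleiotropy in either form: a loading on `"gscore_X"`/`"gscore_Y"` (the
#' scaled genetic scores, i.e. horizontal pleiotropy shared by every variant
#' of the set) or a loading on `"X"`/`"Y"` (vertical pleiotropy, mediated by
#' the phenotype). Definitions are evaluated in declared order, so later
#' traits may reference earlier ones by name.
#'
#' @param name Trait name.
#' @param terms Named numeric vector of loadings; valid names are
#'   `"gscore_X"`, `"gscore_Y"`, `"X"`, `"Y"`, `"U"` and previously defined
#'   auxiliary traits.
#' @param noise_sd Standard deviation of the independent noise term.
#' @return A `phenotype_def` list.
#' @export
phenotype_def <- function(name, terms, noise_sd = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(terms), !is.null(names(terms)), all(nzchar(names(terms))),
            is.numeric(noise_sd), noise_sd >= 0)
  structure(list(name = name, terms = terms, noise_sd = as.numeric(noise_sd)),
            class = "phenotype_def")
}

#' Configure a simulation scenario
#'
#' Bundles every parameter of the data-generating process: panel composition,
#' heritabilities, the causal effect of exposure on outcome, confounding,
#' assortment strength and pattern, and the generation count.
#'
#' The structural model for founders is
#' \deqn{X = \delta_X Z_X + \sqrt{c}\,U + e_X, \qquad
#'       Y = \beta_{XY} X + \delta_Y Z_Y + \sqrt{c}\,U + e_Y,}
#' where \eqn{Z_X} is the unweighted effect-allele count over the GX set,
#' \eqn{\delta_X = \sqrt{h^2_X / \mathrm{var}_0(Z_X)}} with
#' \eqn{\mathrm{var}_0(Z_X) = \sum_k 2p_k(1-p_k)} the theoretical founder
#' variance, \eqn{c} the confounder share and the error variances chosen so
#' founder phenotypic variances are 1. \eqn{\delta_X,\delta_Y} are structural
#' constants: under assortment realized variances (and hence realized
#' heritabilities) drift slightly upward, which is a property of the model,
#' not an artifact.
#'
#' @param n_trios Number of couples per generation (and analyzed trios).
#' @param n_snps_X,n_snps_Y SNPs with direct effects on X resp. Y.
#' @param maf_low,maf_high Allele-frequency bounds for the panel draw.
#' @param h2_X,h2_Y Narrow-sense heritabilities in `[0, 1)`.
#' @param beta_XY Causal effect of X on Y.
#' @param confounder_share Fraction of phenotypic variance from the shared
#'   confounder U; `h2 + confounder_share < 1` must hold for both traits.
#' @param P Assortment strength: the correlation between a phenotype and the
#'   proxy on which partners actually sort, in `(0, 1]`. Ignored when
#'   `assortment$pattern == "none"`.
#' @param assortment An [assortment_spec()].
#' @param n_generations Number of assortative-mating generations (>= 1).
#' @param n_instrument_snps Number of GX SNPs used to build the instrument.
#' @param phenotype_defs Optional list of [phenotype_def()] auxiliary traits.
#' @param seed Master seed for the scenario.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(n_trios = 40000,
                            n_snps_X = 50, n_snps_Y = 50,
                            maf_low = 0.1, maf_high = 0.5,
                            h2_X = 0.5, h2_Y = 0.5,
                            beta_XY = 0,
                            confounder_share = 0.2,
                            P = 1,
                            assortment = assortment_spec("none"),
                            n_generations = 1,
                            n_instrument_snps = n_snps_X,
                            phenotype_defs = list(),
                            seed = NULL) {
  cfg <- list(
    n_trios = check_count(n_trios, "n_trios"),
    n_snps_X = check_count(n_snps_X, "n_snps_X"),
    n_snps_Y = check_count(n_snps_Y, "n_snps_Y"),
    maf_low = check_prob(maf_low, "maf_low", open_lo = TRUE, open_hi = TRUE),
    maf_high = check_prob(maf_high, "maf_high", open_lo = TRUE, open_hi = TRUE),
    h2_X = check_prob(h2_X, "h2_X", open_hi = TRUE),
    h2_Y = check_prob(h2_Y, "h2_Y", open_hi = TRUE),
    beta_XY = as.numeric(beta_XY),
    confounder_share = check_prob(confounder_share, "confounder_share",
                                  open_hi = TRUE),
    P = as.numeric(P),
    assortment = assortment,
    n_generations = check_count(n_generations, "n_generations"),
    n_instrument_snps = check_count(n_instrument_snps, "n_instrument_snps"),
    phenotype_defs = phenotype_defs,
    seed = if (!is.null(seed)) as.integer(seed)
  )
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  if (cfg$maf_low > cfg$maf_high) stop_invalid("maf_low must be <= maf_high")
  if (cfg$h2_X + cfg$confounder_share >= 1)
    stop_invalid("variance budget exceeded: h2_X + confounder_share must be < 1")
  if (cfg$h2_Y + cfg$confounder_share >= 1)
    stop_invalid("variance budget exceeded: h2_Y + confounder_share must be < 1")
  if (cfg$n_instrument_snps > cfg$n_snps_X)
    stop_invalid("n_instrument_snps must be <= n_snps_X")
  if (!inherits(cfg$assortment, "assortment_spec"))
    stop_invalid("assortment must be an assortment_spec()")
  if (cfg$assortment$pattern != "none") {
    if (!is.numeric(cfg$P) || is.na(cfg$P) || cfg$P <= 0 || cfg$P > 1)
      stop_invalid("P must be in (0, 1] when assortment is active; ",
                   "express P = 0 as pattern \"none\"")
    known <- c("X", "Y", vapply(cfg$phenotype_defs, `[[`, "", "name"))
    traits <- cfg$assortment$trait_a
    if (cfg$assortment$pattern == "cross_trait")
      traits <- c(traits, cfg$assortment$trait_b)
    miss <- setdiff(traits, known)
    if (length(miss))
      stop_invalid("assortment trait(s) not defined: ",
                   paste(miss, collapse = ", "))
  }
  if (length(cfg$phenotype_defs) &&
      !all(vapply(cfg$phenotype_defs, inherits, logical(1), "phenotype_def")))
    stop_invalid("phenotype_defs must be a list of phenotype_def() objects")
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n",
      "  trios: ", x$n_trios, "; SNPs: ", x$n_snps_X, " GX + ", x$n_snps_Y,
      " GY (instrument: ", x$n_instrument_snps, ")\n",
      "  h2_X = ", x$h2_X, ", h2_Y = ", x$h2_Y, ", beta_XY = ", x$beta_XY,
      ", confounder share = ", x$confounder_share, "\n",
      "  assortment: ", x$assortment$pattern,
      if (x$assortment$pattern == "single_trait")
        paste0(" on ", x$assortment$trait_a)
      else if (x$assortment$pattern == "cross_trait")
        paste0(" on (", x$assortment$trait_a, ", ", x$assortment$trait_b, ")"),
      if (x$assortment$pattern != "none") paste0(", P = ", x$P),
      "; generations: ", x$n_generations, "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a scenario configuration
#'
#' Configurations round-trip through a flat YAML `key: value` file.
#'
#' @param cfg A `scenario_config`.
#' @param path File path.
#' @return `read_scenario_config` returns a validated `scenario_config`.
#' @export
write_scenario_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  out <- unclass(cfg)
  out$assortment <- unclass(out$assortment)
  out$phenotype_defs <- lapply(out$phenotype_defs, function(d)
    list(name = d$name, terms = as.list(d$terms), noise_sd = d$noise_sd))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop_invalid("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$assortment))
    raw$assortment <- assortment_spec(raw$assortment$pattern,
                                      raw$assortment$trait_a %||% "X",
                                      raw$assortment$trait_b %||% "Y")
  if (!is.null(raw$phenotype_defs))
    raw$phenotype_defs <- lapply(raw$phenotype_defs, function(d)
      phenotype_def(d$name, unlist(d$terms), d$noise_sd %||% 0))
  do.call(scenario_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
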