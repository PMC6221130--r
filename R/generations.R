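#' Run the full multigenerational simulation
#'
#' Simulates founders, then for each generation: computes phenotypes, pairs
#' spouses via the two-set sorting procedure (see [assort_pairs()]), and
#' produces two children per couple (one female, one male) via Mendelian
#' transmission (see [mate()]), keeping population size constant. The
#' children of the final generation, together with their parents, form the
#' study sample. One generation of assortment means founders are paired
#' assortatively and their offspring analyzed. With `n_generations = 1` the
#' result is identical, draw for draw, to the manual pipeline
#' `simulate_founders()` then `compute_phenotypes()`, `assort_pairs()`,
#' `mate()` under the same seed.
#'
#' @param cfg A [scenario_config()].
#' @param seed Optional integer seed; defaults to `cfg$seed`.
#' @return An object of class `trio_sim`: a list with the final-generation
#'   parent population `parents` (phenotypes attached), `couples` (row
#'   indices into `parents`), the phenotyped offspring population
#'   `offspring` (2 children per couple; rows 1..n = daughters, n+1..2n =
#'   sons of couples 1..n; `hap1` = maternal transmitted, `hap2` = paternal
#'   transmitted haplotype), the SNP `panel`, realized between-spouse
#'   phenotype correlations `spouse_cor` (XX, XY, YX, YY), and
#'   per-generation variance bookkeeping `generation_stats`.
#' @export
advance_generations <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  seed <- seed %||% cfg$seed
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_trios
  panel <- scenario_panel(cfg)
  pop <- simulate_founders(panel, n)
  gen_stats <- vector("list", cfg$n_generations)
  parents <- couples <- res <- NULL
  for (g in seq_len(cfg$n_generations)) {
    pop <- compute_phenotypes(pop, cfg)
    gen_stats[[g]] <- data.frame(
      generation = g - 1L,  # 0 = founders
      var_X = var(pop$phen$X), var_Y = var(pop$phen$Y),
      var_gscore_X = var(pop$phen$gscore_X),
      var_gscore_Y = var(pop$phen$gscore_Y))
    f_idx <- which(pop$sex == 1L)
    m_idx <- which(pop$sex == 2L)
    # only the assorted traits are consulted by the pairing
    need <- if (cfg$assortment$pattern == "cross_trait")
      unique(c(cfg$assortment$trait_a, cfg$assortment$trait_b))
    else if (cfg$assortment$pattern == "single_trait") cfg$assortment$trait_a
    else character(0)
    cp <- assort_core(lapply(pop$phen[need], `[`, f_idx),
                      lapply(pop$phen[need], `[`, m_idx),
                      length(f_idx), length(m_idx),
                      cfg$assortment, cfg$P)
    wife <- f_idx[cp$wife]
    hus <- m_idx[cp$husband]
    res <- mate_cpp(pop$hap1, pop$hap2, wife, pop$hap1, pop$hap2, hus, 2L)
    parents <- pop
    couples <- list(wife = wife, husband = hus, set = cp$set)
    pop <- new_population(res$hap1, res$hap2, sex = rep(1:2, each = n),
                          panel = panel,
                          mother = rep(wife, 2L), father = rep(hus, 2L))
  }
  pop <- compute_phenotypes(pop, cfg)
  wx <- parents$phen$X[couples$wife]
  wy <- parents$phen$Y[couples$wife]
  hx <- parents$phen$X[couples$husband]
  hy <- parents$phen$Y[couples$husband]
  structure(list(
    cfg = cfg, panel = panel,
    parents = parents, couples = couples,
    offspring = pop,
    spouse_cor = c(XX = cor(wx, hx), XY = cor(wx, hy),
                   YX = cor(wy, hx), YY = cor(wy, hy)),
    generation_stats = do.call(rbind, gen_stats)),
    class = "trio_sim")
}

#' @export
print.trio_sim <- function(x, ...) {
  cat("<trio_sim> ", x$cfg$n_trios, " couples, ", x$cfg$n_generations,
      " generation(s), assortment ", x$cfg$assortment$pattern, "\n",
      "  spouse correlations: ",
      paste(sprintf("%s = %.3f", names(x$spouse_cor), x$spouse_cor),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Assemble the analyzed trio dataset
#'
#' Selects one analyzed child per final-generation couple at random, collects
#' offspring and parental genotypes, the maternal/paternal transmitted and
#' nontransmitted haplotypes, offspring and parental phenotypes, and assigns
#' random half-split labels A/B (weight-training vs analysis halves).
#'
#' @param sim A `trio_sim` from [advance_generations()].
#' @param seed Optional integer seed for child choice and half split.
#' @param transmitted Materialize the transmitted haplotype matrices `t_m`,
#'   `t_f` (default). They are redundant with `g - nt` and skipping them
#'   saves memory traffic in large replicated runs.
#' @param parents Include parental genotypes, nontransmitted haplotypes and
#'   parental phenotypes (default). Plain offspring-only estimation does not
#'   need them; skipping saves most of the assembly cost.
#' @return An object of class `trio_dataset`: genotype matrices `g_o`, `g_m`,
#'   `g_f` (0/1/2), haplotype matrices `t_m`, `t_f`, `nt_m`, `nt_f` (0/1),
#'   phenotypes `x`, `y`, `x_m`, `x_f`, `y_m`, `y_f`, the `split` factor and
#'   the SNP `panel`.
#' @export
build_trio_dataset <- function(sim, seed = NULL, transmitted = TRUE,
                               parents = TRUE) {
  stopifnot(inherits(sim, "trio_sim"))
  if (is.null(sim$offspring$hap1) || is.null(sim$parents))
    stop("internal consistency error: simulation lacks transmission records")
  n <- sim$cfg$n_trios
  with_seed(seed, {
    slot <- sample(1:2, n, replace = TRUE)
    row_of <- (slot - 1L) * n + seq_len(n)
    wife <- sim$couples$wife
    hus <- sim$couples$husband
    # one fused pass: transmitted = offspring haplotypes, nontransmitted =
    # parent genotype minus transmitted
    tm <- trio_matrices_cpp(sim$offspring$hap1, sim$offspring$hap2,
                            sim$parents$hap1, sim$parents$hap2,
                            row_of, wife, hus, transmitted, parents)
    split <- factor(sample(rep(c("A", "B"), length.out = n)),
                    levels = c("A", "B"))
    new_trio_dataset(
      g_o = tm$g_o, g_m = tm$g_m, g_f = tm$g_f,
      t_m = tm$t_m, t_f = tm$t_f, nt_m = tm$nt_m, nt_f = tm$nt_f,
      x = sim$offspring$phen$X[row_of], y = sim$offspring$phen$Y[row_of],
      x_m = if (parents) sim$parents$phen$X[wife],
      x_f = if (parents) sim$parents$phen$X[hus],
      y_m = if (parents) sim$parents$phen$Y[wife],
      y_f = if (parents) sim$parents$phen$Y[hus],
      split = split, panel = sim$panel)
  })
}

new_trio_dataset <- function(g_o, g_m, g_f, t_m = NULL, t_f = NULL,
                             nt_m = NULL, nt_f = NULL,
                             x, y, x_m = NULL, x_f = NULL,
                             y_m = NULL, y_f = NULL, split, panel = NULL) {
  n <- nrow(g_o)
  stopifnot(length(x) == n, length(y) == n, length(split) == n)
  structure(list(n = n, g_o = g_o, g_m = g_m, g_f = g_f,
                 t_m = t_m, t_f = t_f, nt_m = nt_m, nt_f = nt_f,
                 x = x, y = y, x_m = x_m, x_f = x_f, y_m = y_m, y_f = y_f,
                 split = split, panel = panel),
            class = "trio_dataset")
}

#' @export
print.trio_dataset <- function(x, ...) {
  cat("<trio_dataset> ", x$n, " trios, ", ncol(x$g_o), " SNPs; split A/B = ",
      sum(x$split == "A"), "/", sum(x$split == "B"),
      "; nontransmitted haplotypes: ",
      if (is.null(x$nt_m)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Sample instrument SNPs from the exposure panel
#'
#' @param trios A `trio_dataset` carrying a panel.
#' @param k Number of instrument SNPs.
#' @param seed Optional integer seed.
#' @return Integer vector of SNP column indices (within the GX set).
#' @export
sample_instruments <- function(trios, k, seed = NULL) {
  stopifnot(inherits(trios, "trio_dataset"), !is.null(trios$panel))
  gx <- panel_set(trios$panel, "GX")
  k <- check_count(k, "k")
  if (k > length(gx)) stop_invalid("k exceeds the number of GX SNPs")
  with_seed(seed, sort(sample(gx, k)))
}
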