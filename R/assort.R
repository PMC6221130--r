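#' Pair spouses by bidirectional two-set sorting
#'
#' Implements phenotype-proxy assortment. Couples are first formed at random
#' and split at random into two equal sets (so the procedure is symmetric in
#' the sexes). Under `cross_trait` assortment, in one set men are sorted in
#' ascending order of their `trait_b` proxy and women in ascending order of
#' their `trait_a` proxy; in the other set the roles are swapped. Under
#' `single_trait` both sexes sort on the `trait_a` proxy in both sets. Rank i
#' of the sorted women marries rank i of the sorted men within each set, and
#' the sets are concatenated preserving sorted order. Within a set the
#' Spearman correlation of the paired sorting proxies is therefore exactly 1;
#' the strength of phenotypic assortment is controlled entirely by the
#' proxy-phenotype correlation `P`.
#'
#' @param females,males `population` objects with phenotypes attached (equal
#'   sizes).
#' @param spec An [assortment_spec()].
#' @param P Assortment strength passed to [make_proxy()] (ignored for pattern
#'   `"none"`).
#' @param seed Optional integer seed.
#' @return A list with integer vectors `wife` and `husband` (row indices into
#'   `females` resp. `males`, couple i = (`wife[i]`, `husband[i]`)) and `set`
#'   (1/2 set membership per couple; 0 for pattern `"none"`).
#' @export
assort_pairs <- function(females, males, spec, P = 1, seed = NULL) {
  stopifnot(inherits(females, "population"), inherits(males, "population"))
  with_seed(seed,
            assort_core(females$phen, males$phen, pop_size(females),
                        pop_size(males), spec, P))
}

# core pairing on raw phenotype lists; consumes the ambient RNG stream
assort_core <- function(phen_f, phen_m, n_f, n_m, spec, P) {
  stopifnot(inherits(spec, "assortment_spec"))
  if (n_f != n_m)
    stop_invalid("equal numbers of females and males required (got ",
                 n_f, " vs ", n_m, ")")
  n <- n_f
  if (spec$pattern == "none") {
    return(list(wife = sample.int(n), husband = sample.int(n),
                set = rep(0L, n)))
  }
  need <- function(phen, trait) {
    v <- phen[[trait]]
    if (is.null(v)) stop_invalid("phenotype '", trait, "' not present")
    v
  }
  ta <- spec$trait_a
  tb <- if (spec$pattern == "cross_trait") spec$trait_b else spec$trait_a
  # proxies drawn once per individual per trait actually used
  prox_f_a <- make_proxy(need(phen_f, ta), P)
  prox_m_b <- make_proxy(need(phen_m, tb), P)
  if (spec$pattern == "cross_trait") {
    prox_f_b <- make_proxy(need(phen_f, tb), P)
    prox_m_a <- make_proxy(need(phen_m, ta), P)
  } else {
    prox_f_b <- prox_f_a
    prox_m_a <- prox_m_b
  }
  # random initial pairing, then a random half of the couples to each set
  wife0 <- sample.int(n)
  hus0 <- sample.int(n)
  in_set1 <- sample(rep(c(TRUE, FALSE), length.out = n))
  w1 <- wife0[in_set1]; m1 <- hus0[in_set1]
  w2 <- wife0[!in_set1]; m2 <- hus0[!in_set1]
  # set 1: women ascend on trait_a proxy, men on trait_b proxy
  w1 <- w1[order(prox_f_a[w1])]
  m1 <- m1[order(prox_m_b[m1])]
  # set 2: women ascend on trait_b proxy, men on trait_a proxy
  w2 <- w2[order(prox_f_b[w2])]
  m2 <- m2[order(prox_m_a[m2])]
  list(wife = c(w1, w2), husband = c(m1, m2),
       set = rep(1:2, c(length(w1), length(w2))))
}

#' Mendelian transmission: mate couples
#'
#' Each couple produces `n_offspring` children (default two, forced to one
#' female and one male so population size and sex balance are constant across
#' generations). For every child, parent and SNP, one of the parent's two
#' haplotype alleles is transmitted with probability 1/2; the other allele is
#' recorded as nontransmitted.
#'
#' @param couples Pairing as returned by [assort_pairs()].
#' @param females,males Parent `population` objects the couple indices refer
#'   to.
#' @param n_offspring Children per couple (child slot 1 is female, slot 2
#'   male).
#' @param seed Optional integer seed.
#' @return A list with `offspring` (a `population` of `n_offspring * n`
#'   children; rows `(k-1)*n + i` = child slot k of couple i; `hap1` =
#'   maternal transmitted, `hap2` = paternal transmitted; `mother`/`father`
#'   hold the parent row indices) and matrices `nt_m`, `nt_f` (0/1
#'   nontransmitted haplotypes, rows aligned with `offspring`).
#' @export
mate <- function(couples, females, males, n_offspring = 2, seed = NULL) {
  stopifnot(inherits(females, "population"), inherits(males, "population"))
  n_offspring <- check_count(n_offspring, "n_offspring")
  if (n_offspring > 2L) stop_invalid("n_offspring must be 1 or 2")
  with_seed(seed, {
    n <- length(couples$wife)
    res <- mate_cpp(females$hap1, females$hap2, as.integer(couples$wife),
                    males$hap1, males$hap2, as.integer(couples$husband),
                    as.integer(n_offspring))
    child <- new_population(res$hap1, res$hap2,
                            sex = rep(seq_len(n_offspring), each = n),
                            panel = females$panel,
                            mother = rep(couples$wife, n_offspring),
                            father = rep(couples$husband, n_offspring))
    # nontransmitted = parent genotype - transmitted, replicated per slot
    g_m <- genotype_rows_cpp(females$hap1, females$hap2,
                             as.integer(couples$wife))
    g_f <- genotype_rows_cpp(males$hap1, males$hap2,
                             as.integer(couples$husband))
    reps <- rep(seq_len(n), n_offspring)
    list(offspring = child,
         nt_m = g_m[reps, , drop = FALSE] - res$hap1,
         nt_f = g_f[reps, , drop = FALSE] - res$hap2)
  })
}
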