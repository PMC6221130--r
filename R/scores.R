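#' Estimate per-SNP instrument weights
#'
#' Fits one simple linear regression of offspring exposure on offspring
#' genotype per instrument SNP (with intercept) in the weight-training half,
#' and returns the slopes as allele-score weights. Training in one half and
#' scoring in the other avoids overfitting the instrument to the analysis
#' sample.
#'
#' @param trios A `trio_dataset`.
#' @param instrument_snps Integer vector of SNP column indices (must lie in
#'   the GX set when the dataset carries a panel).
#' @param half Which split half to train in (default `"A"`).
#' @return An object of class `allele_weights`: list with `snps`, `weights`
#'   (exposure units per effect allele) and the training `half`. Monomorphic
#'   SNPs get weight 0 with a warning.
#' @export
estimate_weights <- function(trios, instrument_snps, half = "A") {
  stopifnot(inherits(trios, "trio_dataset"))
  half <- match.arg(half, c("A", "B"))
  if (!is.null(trios$panel)) {
    gx <- panel_set(trios$panel, "GX")
    if (!all(instrument_snps %in% gx))
      stop_invalid("instrument SNPs must belong to the GX set")
  }
  idx <- which(trios$split == half)
  if (!length(idx)) stop_invalid("training half '", half, "' is empty")
  g <- trios$g_o[idx, instrument_snps, drop = FALSE]
  x <- trios$x[idx]
  n <- length(x)
  gs <- colSums(g)
  ss <- colSums(g * g) - gs^2 / n          # centered sum of squares
  mono <- ss <= 0
  cxy <- as.numeric(crossprod(g, x)) - gs * mean(x)
  w <- numeric(ncol(g))
  w[!mono] <- cxy[!mono] / ss[!mono]
  if (any(mono)) {
    warning("monomorphic SNP(s) in training half; weight set to 0: ",
            paste(instrument_snps[mono], collapse = ", "))
  }
  structure(list(snps = as.integer(instrument_snps), weights = w, half = half),
            class = "allele_weights")
}

#' @export
print.allele_weights <- function(x, ...) {
  cat("<allele_weights> ", length(x$snps), " SNPs trained in half ", x$half,
      "; mean |weight| = ", sprintf("%.4f", mean(abs(x$weights))), "\n",
      sep = "")
  invisible(x)
}

#' Build weighted allele scores and nontransmitted scores
#'
#' Computes, per analyzed trio in the analysis half, the offspring score
#' \eqn{S = \sum_k \omega_k g_k}, the parental scores \eqn{S^m, S^f} on the
#' parents' full genotypes, and the nontransmitted scores \eqn{W^m, W^f} on
#' the parents' nontransmitted haplotypes, all with the same weights.
#'
#' @param trios A `trio_dataset`.
#' @param weights An `allele_weights` object, or a bare numeric vector of
#'   external weights (e.g. published GWAS weights), in which case the full
#'   sample is scored and `snps` must be supplied.
#' @param half Which split half to score (default `"B"`, the half opposite to
#'   weight training). Ignored for external weights.
#' @param snps SNP columns for external numeric weights.
#' @param allow_same_half Set `TRUE` to override the overfitting guard that
#'   refuses scoring the half the weights were trained in.
#' @return An object of class `score_set`: list with `idx` (trio rows scored)
#'   and numeric vectors `S`, `S_m`, `S_f`, and `W_m`, `W_f` when the dataset
#'   has nontransmitted haplotypes.
#' @export
build_scores <- function(trios, weights, half = "B", snps = NULL,
                         allow_same_half = FALSE) {
  stopifnot(inherits(trios, "trio_dataset"))
  if (inherits(weights, "allele_weights")) {
    half <- match.arg(half, c("A", "B"))
    if (identical(weights$half, half) && !allow_same_half)
      stop_invalid("weights were trained in half ", weights$half,
                   "; scoring the same half risks overfitting ",
                   "(set allow_same_half = TRUE to override)")
    idx <- which(trios$split == half)
    snps <- weights$snps
    w <- weights$weights
  } else {
    if (is.null(snps)) stop_invalid("snps must be given with external weights")
    if (length(weights) != length(snps))
      stop_invalid("external weights and snps must have equal length")
    idx <- seq_len(trios$n)
    w <- as.numeric(weights)
  }
  sc <- function(m) if (is.null(m)) NULL else
    as.numeric(m[idx, snps, drop = FALSE] %*% w)
  structure(list(idx = idx, snps = snps, weights = w,
                 S = sc(trios$g_o), S_m = sc(trios$g_m), S_f = sc(trios$g_f),
                 W_m = sc(trios$nt_m), W_f = sc(trios$nt_f)),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat("<score_set> ", length(x$idx), " trios scored on ", length(x$snps),
      " SNPs; nontransmitted scores: ",
      if (is.null(x$W_m)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Infer nontransmitted allele counts without phase
#'
#' For user-supplied trio genotype tables lacking transmission records, the
#' nontransmitted allele count of a parent at one SNP is resolved by Mendelian
#' logic: a homozygous parent's transmitted allele is determined; a
#' heterozygous parent is resolved when the offspring is homozygous, or by
#' subtraction when the other parent is homozygous. The remaining case (all
#' three heterozygous) is ambiguous and gets the expected value 1/2 for each
#' parent, with a per-trio ambiguity count reported.
#'
#' @param g_o,g_m,g_f Offspring/mother/father genotype matrices (0/1/2).
#' @return List with numeric matrices `nt_m`, `nt_f` (values 0, 1/2, 1) and
#'   integer vector `n_ambiguous` per trio.
#' @export
infer_nontransmitted <- function(g_o, g_m, g_f) {
  stopifnot(all(dim(g_o) == dim(g_m)), all(dim(g_o) == dim(g_f)))
  # transmitted maternal count t_m in {0, 1}; t_m + t_f = g_o
  t_m <- matrix(NA_real_, nrow(g_o), ncol(g_o))
  t_m[g_m == 0L] <- 0
  t_m[g_m == 2L] <- 1
  het_m <- g_m == 1L
  # other parent homozygous: t_f determined, t_m by subtraction
  fix <- het_m & g_f != 1L
  t_m[fix] <- (g_o - g_f / 2)[fix]
  # offspring homozygous: both transmitted alleles known
  fix <- het_m & g_f == 1L & g_o != 1L
  t_m[fix] <- (g_o / 2)[fix]
  amb <- is.na(t_m)
  t_m[amb] <- 0.5
  t_f <- g_o - t_m
  bad <- t_m < 0 | t_m > 1 | t_f < 0 | t_f > 1
  if (any(bad))
    stop_invalid("Mendelian inconsistency in ", sum(bad), " trio-SNP cell(s)")
  list(nt_m = g_m - t_m, nt_f = g_f - t_f,
       n_ambiguous = as.integer(rowSums(amb)))
}
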