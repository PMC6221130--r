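#' Draw a biallelic SNP panel
#'
#' Creates a panel of unlinked biallelic SNPs with effect-allele frequencies
#' drawn independently and uniformly on `[maf_low, maf_high]`. Each SNP carries
#' a set label partitioning the panel into the genetic influences on the
#' exposure (`"GX"`), on the outcome (`"GY"`), or auxiliary sets.
#'
#' @param n_snps Number of SNPs (>= 1).
#' @param maf_low,maf_high Frequency bounds, `0 < maf_low <= maf_high < 1`.
#' @param set_label Character scalar or vector of length `n_snps` tagging set
#'   membership; defaults to `"GX"`.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   in isolation.
#' @return An object of class `snp_panel`: a list with `n_snps`, `freq`
#'   (effect-allele frequencies) and `set` (labels).
#' @export
#' @examples
#' draw_panel(10, 0.1, 0.5, seed = 1)
draw_panel <- function(n_snps, maf_low, maf_high, set_label = "GX", seed = NULL) {
  n_snps <- check_count(n_snps, "n_snps")
  check_prob(maf_low, "maf_low", open_lo = TRUE, open_hi = TRUE)
  check_prob(maf_high, "maf_high", open_lo = TRUE, open_hi = TRUE)
  if (maf_low > maf_high) stop_invalid("maf_low must be <= maf_high")
  if (!length(set_label) %in% c(1L, n_snps))
    stop_invalid("set_label must have length 1 or n_snps")
  with_seed(seed, {
    freq <- runif(n_snps, maf_low, maf_high)
    new_snp_panel(freq, rep_len(as.character(set_label), n_snps))
  })
}

new_snp_panel <- function(freq, set) {
  stopifnot(length(freq) == length(set), all(freq > 0 & freq < 1))
  structure(list(n_snps = length(freq), freq = as.numeric(freq),
                 set = as.character(set)),
            class = "snp_panel")
}

#' Combine SNP panels
#'
#' @param ... `snp_panel` objects.
#' @return A single `snp_panel` with concatenated frequencies and labels.
#' @export
combine_panels <- function(...) {
  panels <- list(...)
  stopifnot(all(vapply(panels, inherits, logical(1), "snp_panel")))
  new_snp_panel(unlist(lapply(panels, `[[`, "freq")),
                unlist(lapply(panels, `[[`, "set")))
}

# SNP indices belonging to one set label
panel_set <- function(panel, label) which(panel$set == label)

# theoretical founder variance of an unweighted allele-count score over a set:
# sum of 2 p (1 - p) under Hardy-Weinberg and linkage equilibrium
panel_score_var <- function(panel, label) {
  p <- panel$freq[panel_set(panel, label)]
  sum(2 * p * (1 - p))
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel> ", x$n_snps, " SNPs; sets: ",
      paste(sprintf("%s (%d)", names(table(x$set)), table(x$set)),
            collapse = ", "),
      "; freq range [", sprintf("%.3f", min(x$freq)), ", ",
      sprintf("%.3f", max(x$freq)), "]\n", sep = "")
  invisible(x)
}
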