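#' Per-SNP summary association statistics
#'
#' Simple linear regressions of exposure and outcome on genotype, one SNP at
#' a time, in the analysis half. By default both regressions use the same
#' half (one-sample summary statistics); `two_sample = TRUE` estimates the
#' exposure associations in the opposite half so the two sets of statistics
#' come from independent samples.
#'
#' @param trios A `trio_dataset`.
#' @param instrument_snps SNP column indices.
#' @param half Analysis half (default `"B"`).
#' @param two_sample Use independent halves for exposure and outcome.
#' @return An object of class `mr_sumstats`: data frame with columns
#'   `snp_id`, `beta_x`, `se_x`, `beta_y`, `se_y`, `n_x`, `n_y`. Monomorphic
#'   SNPs are excluded with a warning.
#' @export
snp_summary_stats <- function(trios, instrument_snps, half = "B",
                              two_sample = FALSE) {
  stopifnot(inherits(trios, "trio_dataset"))
  half <- match.arg(half, c("A", "B"))
  other <- setdiff(c("A", "B"), half)
  idx_y <- which(trios$split == half)
  idx_x <- if (two_sample) which(trios$split == other) else idx_y
  marg <- function(idx, v) {
    g <- trios$g_o[idx, instrument_snps, drop = FALSE]
    gc <- sweep(g, 2L, colMeans(g))
    ss <- colSums(gc^2)
    b <- se <- rep(NA_real_, length(instrument_snps))
    ok <- ss > 0
    vc <- v[idx] - mean(v[idx])
    b[ok] <- colSums(gc[, ok, drop = FALSE] * vc) / ss[ok]
    n <- length(idx)
    rss <- colSums((vc - sweep(gc[, ok, drop = FALSE], 2L, b[ok], `*`))^2)
    se[ok] <- sqrt(rss / (n - 2) / ss[ok])
    list(b = b, se = se, n = n)
  }
  mx <- marg(idx_x, trios$x)
  my <- marg(idx_y, trios$y)
  keep <- !is.na(mx$b) & !is.na(my$b)
  if (!all(keep))
    warning("excluding ", sum(!keep), " monomorphic SNP(s)")
  structure(data.frame(snp_id = instrument_snps[keep],
                       beta_x = mx$b[keep], se_x = mx$se[keep],
                       beta_y = my$b[keep], se_y = my$se[keep],
                       n_x = mx$n, n_y = my$n),
            class = c("mr_sumstats", "data.frame"))
}

wald_ratios <- function(stats) {
  zero <- stats$beta_x == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " SNP(s) with zero exposure association")
    stats <- stats[!zero, , drop = FALSE]
  }
  ratio <- stats$beta_y / stats$beta_x
  # first-order SE of the ratio; IVW weights are its inverse square
  se_ratio <- stats$se_y / abs(stats$beta_x)
  list(stats = stats, ratio = ratio, se_ratio = se_ratio,
       w = 1 / se_ratio^2)
}

mr_summary_result <- function(method, estimate, se, n_snps, extra = NULL) {
  z <- estimate / se
  structure(c(list(method = method, estimate = estimate, se = se,
                   ci_lower = estimate - qnorm(0.975) * se,
                   ci_upper = estimate + qnorm(0.975) * se,
                   p.value = 2 * pnorm(-abs(z)),
                   aux = NULL, assort_test = NULL, n = n_snps), extra),
            class = "mr_estimate")
}

#' Summary-data MR estimators
#'
#' Pleiotropy-robust (and conventional) estimators operating on per-SNP
#' summary statistics:
#' * `ivw` — fixed-effect inverse-variance-weighted mean of the per-SNP Wald
#'   ratios, weights \eqn{\beta_{Xk}^2 / SE(\beta_{Yk})^2}.
#' * `egger` — weighted linear regression of outcome on exposure
#'   associations with an intercept (weights \eqn{1/SE(\beta_{Yk})^2}); the
#'   slope is the causal estimate, the intercept the directional-pleiotropy
#'   term. Residual dispersion below 1 is floored at 1.
#' * `weighted_median` — weighted median of the ordered Wald ratios by
#'   cumulative-weight interpolation at 50%; parametric-bootstrap SE.
#' * `mbe` — mode of the Gaussian-kernel-smoothed Wald-ratio density,
#'   bandwidth `phi` times the modified Silverman rule
#'   \eqn{0.9\,\min(sd, 1.4826\,mad)\,J^{-1/5}}; parametric-bootstrap SE.
#'
#' @param stats An `mr_sumstats` data frame.
#' @param method One of `"ivw"`, `"egger"`, `"weighted_median"`, `"mbe"`.
#' @param phi Bandwidth multiplier for `mbe`.
#' @param weighted For `mbe`: weight the kernel density by the IVW weights
#'   (default) or use the simple unweighted form.
#' @param n_boot Bootstrap replicates for `weighted_median`/`mbe` SEs.
#' @param seed Optional integer seed for the bootstrap.
#' @return An `mr_estimate`; for `egger` the intercept and its SE/p-value are
#'   attached as `intercept`, `intercept_se`, `intercept_p`.
#' @export
summary_mr <- function(stats,
                       method = c("ivw", "egger", "weighted_median", "mbe"),
                       phi = 1, weighted = TRUE, n_boot = 1000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(stats, "mr_sumstats") || is.data.frame(stats))
  if (nrow(stats) < 2L && method != "ivw")
    stop_invalid("at least 2 SNPs required")
  if (method == "egger" && nrow(stats) < 3L)
    stop_invalid("at least 3 SNPs required for Egger regression")
  wr <- wald_ratios(stats)
  J <- nrow(wr$stats)
  if (method == "ivw") {
    est <- sum(wr$w * wr$ratio) / sum(wr$w)
    se <- sqrt(1 / sum(wr$w))
    return(mr_summary_result("ivw", est, se, J))
  }
  if (method == "egger") {
    s <- wr$stats
    # orient so all exposure associations are positive (InSIDE convention)
    flip <- sign(s$beta_x)
    bx <- s$beta_x * flip; by <- s$beta_y * flip
    if (var(bx) == 0)
      stop_invalid("exposure associations are constant; Egger slope undefined")
    fit <- lm(by ~ bx, weights = 1 / s$se_y^2)
    sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
    infl <- if (sm$sigma > 0) max(1, sm$sigma) / sm$sigma else 1
    cf <- sm$coefficients
    est <- cf["bx", "Estimate"]; se <- cf["bx", "Std. Error"] * infl
    i_est <- cf["(Intercept)", "Estimate"]
    i_se <- cf["(Intercept)", "Std. Error"] * infl
    return(mr_summary_result("egger", est, se, J,
                             extra = list(intercept = i_est,
                                          intercept_se = i_se,
                                          intercept_p = 2 * pnorm(-abs(i_est / i_se)))))
  }
  point <- function(ratio, w) {
    if (method == "weighted_median") weighted_median_point(ratio, w)
    else mbe_point(ratio, if (weighted) w else rep(1, length(w)), phi)
  }
  est <- point(wr$ratio, wr$w)
  se <- with_seed(seed, boot_se_ratio(wr$stats, point, n_boot))
  mr_summary_result(method, est, se, J)
}

# weighted median by cumulative-weight interpolation at 50%
weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]
  p <- cumsum(w[o]) / sum(w) - w[o] / (2 * sum(w))  # midpoint convention
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(p)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

# mode of the kernel-smoothed ratio density
mbe_point <- function(ratio, w, phi = 1) {
  s <- 0.9 * min(sd(ratio), mad(ratio)) * length(ratio)^(-1 / 5)
  if (s <= 0) return(ratio[1])  # all ratios identical
  d <- density(ratio, weights = w / sum(w), bw = phi * s, kernel = "gaussian")
  d$x[which.max(d$y)]
}

# parametric bootstrap over the summary statistics
boot_se_ratio <- function(stats, point_fun, n_boot) {
  ests <- vapply(seq_len(n_boot), function(b) {
    bx <- rnorm(nrow(stats), stats$beta_x, stats$se_x)
    by <- rnorm(nrow(stats), stats$beta_y, stats$se_y)
    keep <- bx != 0
    r <- by[keep] / bx[keep]
    w <- bx[keep]^2 / stats$se_y[keep]^2
    point_fun(r, w)
  }, numeric(1))
  sd(ests)
}

#' Heterogeneity and pleiotropy diagnostics
#'
#' Computes Cochran's Q over the per-SNP Wald ratios against the IVW
#' estimate (chi-square with J - 1 df), the Egger-intercept z-test for
#' directional pleiotropy (when >= 3 SNPs), and optionally the
#' exposure/outcome allele-score correlation test: a nonzero correlation
#' between independent exposure and outcome allele scores indicates
#' cross-trait assortative mating (or population substructure), which the
#' within-instrument heterogeneity statistics cannot see.
#'
#' @param stats An `mr_sumstats` data frame.
#' @param exposure_score,outcome_score Optional individual-level allele-score
#'   vectors for the score-correlation diagnostic.
#' @return List with `Q` (`statistic`, `df`, `p.value`), `egger_intercept`
#'   (or NULL), and `score_correlation` (an `htest`, or NULL).
#' @export
heterogeneity_tests <- function(stats, exposure_score = NULL,
                                outcome_score = NULL) {
  if (nrow(stats) < 2L) stop_invalid("at least 2 SNPs required")
  wr <- wald_ratios(stats)
  ivw <- sum(wr$w * wr$ratio) / sum(wr$w)
  Q <- sum(wr$w * (wr$ratio - ivw)^2)
  J <- length(wr$ratio)
  out <- list(
    Q = list(statistic = Q, df = J - 1L,
             p.value = pchisq(Q, df = J - 1L, lower.tail = FALSE)),
    egger_intercept = NULL, score_correlation = NULL)
  if (J >= 3L) {
    eg <- tryCatch(summary_mr(wr$stats, "egger"), error = function(e) NULL)
    if (!is.null(eg))
      out$egger_intercept <- list(estimate = eg$intercept,
                                  se = eg$intercept_se,
                                  p.value = eg$intercept_p)
  }
  if (!is.null(exposure_score) && !is.null(outcome_score))
    out$score_correlation <- cor.test(exposure_score, outcome_score)
  out
}

#' Exposure/outcome allele-score correlation test
#'
#' @param exposure_score,outcome_score Individual-level allele scores built
#'   from nonoverlapping SNP sets.
#' @return An `htest` from [stats::cor.test()].
#' @export
score_correlation_test <- function(exposure_score, outcome_score) {
  cor.test(exposure_score, outcome_score)
}
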