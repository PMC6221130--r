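new_mr_estimate <- function(method, fit, target, aux_parm = NULL, n = fit$n) {
  est <- coef(fit)[target]
  se <- fit$se[target]
  ci <- c(est - qnorm(0.975) * se, est + qnorm(0.975) * se)
  aux <- assort <- NULL
  if (!is.null(aux_parm)) {
    aux <- data.frame(term = aux_parm,
                      estimate = as.numeric(coef(fit)[aux_parm]),
                      se = as.numeric(fit$se[aux_parm]))
    assort <- wald_joint(fit, aux_parm)
  }
  z <- est / se
  structure(list(method = method,
                 estimate = as.numeric(est), se = as.numeric(se),
                 ci_lower = as.numeric(ci[1]), ci_upper = as.numeric(ci[2]),
                 p.value = 2 * pnorm(-abs(z)),
                 aux = aux, assort_test = assort,
                 n = n, fit = fit),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(x$method, ": estimate = ", format(x$estimate, digits = digits),
      " (SE ", format(x$se, digits = digits),
      "), 95% CI [", format(x$ci_lower, digits = digits), ", ",
      format(x$ci_upper, digits = digits),
      "], p = ", format.pval(x$p.value, digits = digits),
      ", n = ", x$n, "\n", sep = "")
  if (!is.null(x$aux)) {
    for (i in seq_len(nrow(x$aux)))
      cat("  ", x$aux$term[i], " = ", format(x$aux$estimate[i], digits = digits),
          " (SE ", format(x$aux$se[i], digits = digits), ")\n", sep = "")
    cat("  assortment/dynastic joint test: chi2(", x$assort_test$df, ") = ",
        format(x$assort_test$statistic, digits = digits), ", p = ",
        format.pval(x$assort_test$p.value, digits = digits), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) setNames(object$estimate, object$method)

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  matrix(c(object$estimate - z * object$se, object$estimate + z * object$se),
         1, 2, dimnames = list(object$method, c("lower", "upper")))
}

mr_phen <- function(trios, scores, what) {
  v <- trios[[what]]
  if (is.null(v))
    stop_invalid("trio dataset lacks required column '", what, "'")
  v[scores$idx]
}

#' Plain allele-score MR (TSLS with no covariates)
#'
#' Regresses outcome on exposure instrumenting the exposure with the
#' offspring weighted allele score; no covariates. This is the conventional
#' single-sample MR estimator and is biased under cross-trait assortative
#' mating.
#'
#' @param scores A `score_set` from [build_scores()].
#' @param trios The `trio_dataset` the scores index into.
#' @param robust Use heteroskedasticity-robust SEs.
#' @return An `mr_estimate` (method `"tsls1"`).
#' @export
mr_tsls1 <- function(scores, trios, robust = FALSE) {
  stopifnot(inherits(scores, "score_set"))
  fit <- fit_2sls(mr_phen(trios, scores, "y"),
                  endog = mr_phen(trios, scores, "x"),
                  instruments = scores$S, robust = robust,
                  names_endog = "x")
  new_mr_estimate("tsls1", fit, "x")
}

#' Parental-allele-score-adjusted MR
#'
#' TSLS of outcome on exposure with mother's and father's allele scores as
#' exogenous covariates in both stages and the offspring score as instrument.
#' The joint 2-df Wald test of the parental-score coefficients in the outcome
#' equation is a test for the presence and direction of assortative-mating
#' bias; the signed coefficients are reported for direction.
#'
#' @inheritParams mr_tsls1
#' @return An `mr_estimate` (method `"tsls2"`) with `aux` holding the
#'   parental-score coefficients and `assort_test` the joint Wald test.
#' @export
mr_tsls2 <- function(scores, trios, robust = FALSE) {
  stopifnot(inherits(scores, "score_set"))
  if (is.null(scores$S_m) || is.null(scores$S_f))
    stop_invalid("parental allele scores are required for tsls2")
  exog <- cbind(S_m = scores$S_m, S_f = scores$S_f)
  fit <- fit_2sls(mr_phen(trios, scores, "y"),
                  endog = mr_phen(trios, scores, "x"),
                  exog = exog,
                  instruments = scores$S, robust = robust,
                  names_endog = "x", names_exog = c("S_m", "S_f"))
  new_mr_estimate("tsls2", fit, "x", aux_parm = c("S_m", "S_f"))
}

#' Nontransmitted-allele-score MR
#'
#' Jointly estimates the causal effect of the offspring's exposure and the
#' direct (dynastic) effects of the parents' exposure phenotypes on the
#' offspring outcome. Three endogenous regressors (offspring, mother and
#' father exposure) are instrumented by the offspring allele score and the
#' mother's and father's nontransmitted allele scores. The joint 2-df Wald
#' test of the parental-phenotype coefficients detects assortment or dynastic
#' effects.
#'
#' @inheritParams mr_tsls1
#' @return An `mr_estimate` (method `"tsls3"`) with `aux` holding the
#'   parental-exposure coefficients.
#' @export
mr_tsls3 <- function(scores, trios, robust = FALSE) {
  stopifnot(inherits(scores, "score_set"))
  if (is.null(scores$W_m) || is.null(scores$W_f))
    stop_invalid("nontransmitted allele scores are required for tsls3")
  endog <- cbind(x = mr_phen(trios, scores, "x"),
                 x_m = mr_phen(trios, scores, "x_m"),
                 x_f = mr_phen(trios, scores, "x_f"))
  fit <- fit_2sls(mr_phen(trios, scores, "y"),
                  endog = endog,
                  instruments = cbind(scores$S, scores$W_m, scores$W_f),
                  robust = robust,
                  names_endog = c("x", "x_m", "x_f"))
  new_mr_estimate("tsls3", fit, "x", aux_parm = c("x_m", "x_f"))
}
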