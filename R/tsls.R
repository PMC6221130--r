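#' Two-stage least squares
#'
#' Instrumental-variable estimation by two-stage least squares with standard
#' errors that account for first-stage estimation error (IV-consistent, not
#' naive second-stage OLS). Exogenous covariates enter both stages; an
#' intercept is always included. Optionally returns heteroskedasticity-robust
#' (HC1 sandwich) standard errors.
#'
#' @param y Numeric outcome vector.
#' @param endog Matrix (or vector) of endogenous regressors.
#' @param exog Optional matrix (or vector) of exogenous covariates.
#' @param instruments Matrix (or vector) of excluded instruments; the order
#'   condition `ncol(instruments) >= ncol(endog)` must hold.
#' @param robust Use HC1 sandwich standard errors.
#' @param names_endog,names_exog Optional coefficient names.
#' @return An object of class `tsls` with components `coefficients`, `vcov`,
#'   `se`, `sigma2`, `residuals`, `fitted.values`, `n`, `df.residual`,
#'   `robust`, and bookkeeping of which coefficients are endogenous.
#' @export
#' @examples
#' set.seed(1)
#' z <- rnorm(200); x <- z + rnorm(200); y <- 2 * x + rnorm(200)
#' fit <- fit_2sls(y, x, instruments = z)
#' coef(fit)
fit_2sls <- function(y, endog, exog = NULL, instruments, robust = FALSE,
                     names_endog = NULL, names_exog = NULL) {
  y <- as.numeric(y)
  endog <- as.matrix(endog)
  instruments <- as.matrix(instruments)
  if (!is.null(exog)) exog <- as.matrix(exog)
  n <- length(y)
  stopifnot(nrow(endog) == n, nrow(instruments) == n,
            is.null(exog) || nrow(exog) == n)
  if (ncol(instruments) < ncol(endog))
    stop_identification("under-identified: ", ncol(instruments),
                        " instrument(s) for ", ncol(endog),
                        " endogenous regressor(s)")
  if (is.null(names_endog))
    names_endog <- colnames(endog) %||% paste0("endog", seq_len(ncol(endog)))
  if (!is.null(exog) && is.null(names_exog))
    names_exog <- colnames(exog) %||% paste0("exog", seq_len(ncol(exog)))
  W <- cbind(`(Intercept)` = 1, endog, exog)
  colnames(W) <- c("(Intercept)", names_endog, names_exog)
  Z <- cbind(1, instruments, exog)
  k <- ncol(W)
  qz <- qr(Z)
  if (qz$rank < ncol(Z))
    stop_identification("instrument matrix is rank deficient")
  What <- qr.fitted(qz, W)      # projection of regressors on instrument space
  A <- crossprod(What)          # = W' P_Z W by idempotency
  qa <- qr(A)
  if (qa$rank < k)
    stop_identification("projected design is rank deficient; ",
                        "instruments do not identify all coefficients")
  beta <- solve(qa, crossprod(What, y))
  res <- y - as.numeric(W %*% beta)   # structural residuals (actual W)
  df <- n - k
  sigma2 <- sum(res^2) / df
  Ainv <- solve(qa, diag(k))
  if (robust) {
    meat <- crossprod(What * res)
    V <- Ainv %*% meat %*% Ainv * n / df   # HC1
  } else {
    V <- sigma2 * Ainv
  }
  dimnames(V) <- list(colnames(W), colnames(W))
  structure(list(coefficients = setNames(as.numeric(beta), colnames(W)),
                 vcov = V, se = sqrt(diag(V)), sigma2 = sigma2,
                 residuals = res,
                 fitted.values = as.numeric(W %*% beta),
                 n = n, df.residual = df, robust = robust,
                 endog_names = names_endog, exog_names = names_exog,
                 n_instruments = ncol(instruments)),
            class = "tsls")
}

#' @export
coef.tsls <- function(object, ...) object$coefficients

#' @export
vcov.tsls <- function(object, ...) object$vcov

#' @export
residuals.tsls <- function(object, ...) object$residuals

#' @export
fitted.tsls <- function(object, ...) object$fitted.values

#' @export
confint.tsls <- function(object, parm, level = 0.95, ...) {
  cf <- coef(object)
  if (missing(parm)) parm <- names(cf)
  z <- qnorm(1 - (1 - level) / 2)
  out <- cbind(cf[parm] - z * object$se[parm], cf[parm] + z * object$se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
predict.tsls <- function(object, new_endog, new_exog = NULL, ...) {
  W <- cbind(1, as.matrix(new_endog), if (!is.null(new_exog)) as.matrix(new_exog))
  as.numeric(W %*% coef(object))
}

#' @export
print.tsls <- function(x, ...) {
  cat("Two-stage least squares (", x$n_instruments, " instrument(s), n = ",
      x$n, if (x$robust) ", robust SEs", ")\n", sep = "")
  print(round(coef(x), 6))
  invisible(x)
}

#' @export
summary.tsls <- function(object, ...) {
  cf <- coef(object)
  zval <- cf / object$se
  tab <- cbind(Estimate = cf, `Std. Error` = object$se, `z value` = zval,
               `Pr(>|z|)` = 2 * pnorm(-abs(zval)))
  structure(list(coefficients = tab, n = object$n, robust = object$robust,
                 sigma2 = object$sigma2), class = "summary.tsls")
}

#' @export
print.summary.tsls <- function(x, ...) {
  cat("Two-stage least squares, n =", x$n,
      if (x$robust) "(robust SEs)", "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nResidual variance:", format(x$sigma2, digits = 5), "\n")
  invisible(x)
}

# joint Wald chi-square test of a coefficient subset
wald_joint <- function(fit, parm) {
  b <- coef(fit)[parm]
  V <- vcov(fit)[parm, parm, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V, b))
  list(statistic = stat, df = length(parm),
       p.value = pchisq(stat, df = length(parm), lower.tail = FALSE))
}
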