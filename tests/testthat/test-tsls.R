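test_that("fit_2sls matches the textbook projection oracle to 1e-8", {
  for (case in 1:12) {
    set.seed(500 + case)
    n <- sample(20:50, 1)
    k_end <- sample(1:2, 1)
    k_inst <- k_end + sample(0:2, 1)
    k_ex <- sample(0:2, 1)
    endog <- matrix(rnorm(n * k_end), n, k_end)
    inst <- matrix(rnorm(n * k_inst), n, k_inst) + endog[, 1]
    exog <- if (k_ex) matrix(rnorm(n * k_ex), n, k_ex)
    y <- endog %*% rep(1, k_end) + rnorm(n) +
      if (k_ex) exog %*% rep(0.5, k_ex) else 0
    fit <- fit_2sls(y, endog, exog, inst)
    or <- oracle_2sls(y, endog, exog, inst)
    expect_equal(unname(coef(fit)), or$beta, tolerance = 1e-8)
    expect_equal(unname(vcov(fit)), unname(or$vcov), tolerance = 1e-8)
  }
})

test_that("just-identified IV equals the covariance ratio", {
  set.seed(520)
  n <- 200
  z <- rnorm(n); x <- z + rnorm(n); y <- 2 * x + rnorm(n)
  fit <- fit_2sls(y, x, instruments = z)
  expect_equal(unname(coef(fit)[2]), cov(z, y) / cov(z, x), tolerance = 1e-10)
})

test_that("exact linear systems and OLS-equivalence limits behave", {
  z <- c(0, 1, 2, 3)
  fit <- fit_2sls(2 * z, z, instruments = z)
  expect_equal(unname(coef(fit)), c(0, 2), tolerance = 1e-12)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-12)
  # instrumenting x with itself reproduces OLS
  set.seed(521)
  x <- rnorm(100); y <- 1 + 0.3 * x + rnorm(100)
  fit2 <- fit_2sls(y, x, instruments = x)
  ols <- lm(y ~ x)
  expect_equal(unname(coef(fit2)), unname(coef(ols)), tolerance = 1e-10)
})

test_that("identification failures raise identification errors", {
  set.seed(522)
  x <- matrix(rnorm(60), 30, 2)
  z <- rnorm(30)
  expect_error(fit_2sls(rnorm(30), x, instruments = z),
               class = "triomr_identification_error")
  # duplicated instrument columns: rank deficient
  expect_error(fit_2sls(rnorm(30), x, instruments = cbind(z, z)),
               class = "triomr_identification_error")
  # constant exogenous covariate collinear with the intercept
  expect_error(fit_2sls(rnorm(30), x[, 1], exog = rep(1, 30),
                        instruments = cbind(z, rnorm(30))),
               class = "triomr_identification_error")
})

test_that("robust sandwich SEs match an explicit HC1 computation", {
  set.seed(523)
  n <- 300
  z <- rnorm(n); x <- z + rnorm(n)
  y <- x + rnorm(n) * (1 + abs(z))  # heteroskedastic
  fit <- fit_2sls(y, x, instruments = z, robust = TRUE)
  W <- cbind(1, x); Z <- cbind(1, z)
  PW <- Z %*% solve(crossprod(Z), crossprod(Z, W))
  b <- solve(crossprod(PW, W), crossprod(PW, y))
  e <- as.numeric(y - W %*% b)
  A <- solve(crossprod(PW))
  V <- A %*% crossprod(PW * e) %*% A * n / (n - 2)
  expect_equal(unname(vcov(fit)), unname(V), tolerance = 1e-8)
})

test_that("tsls methods expose standard accessors", {
  set.seed(524)
  z <- rnorm(80); x <- z + rnorm(80); y <- x + rnorm(80)
  fit <- fit_2sls(y, x, instruments = z)
  ci <- confint(fit)
  expect_equal(ci[, 1], coef(fit) - qnorm(0.975) * fit$se, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fitted(fit) + residuals(fit), y, tolerance = 1e-12)
  expect_equal(predict(fit, x), fitted(fit), tolerance = 1e-12)
  s <- summary(fit)
  expect_true(all(s$coefficients[, "Pr(>|z|)"] >= 0 &
                  s$coefficients[, "Pr(>|z|)"] <= 1))
  wt <- triomr:::wald_joint(fit, "endog1")
  expect_equal(wt$statistic, (coef(fit)["endog1"] / fit$se["endog1"])^2,
               tolerance = 1e-10, ignore_attr = TRUE)
})
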