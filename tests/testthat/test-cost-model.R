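test_that("the design encodes dummies, covariates and the cheapest reference", {
  # cohort of only reference-category cases: covariates but no dummies
  p_ref <- toy_patients(5, categories = rep("aph", 5))
  c_ref <- costs_from_totals(p_ref, rep(15, 5))
  d_ref <- suppressMessages(build_design(p_ref, c_ref))
  expect_identical(setdiff(d_ref$candidates, c("age", "urban", "anc")),
                   character(0))

  # a full synthetic cohort: 6 dummies + age + urban + anc
  sim <- generate_cohort(cohort_params(), seed = 2)
  costs <- costs_from_totals(sim$patients, sim$latent$cost_mmk,
                             currency = "MMK")
  design <- suppressMessages(build_design(sim$patients, costs))
  n_cats <- length(unique(sim$patients$complication))
  expect_length(design$candidates, (n_cats - 1) + 3)
  expect_length(intersect(design$candidates, complication_levels()),
                n_cats - 1)
  # reference is the category with the lowest observed mean cost
  mean_by_cat <- tapply(costs$total, sim$patients$complication, mean)
  expect_identical(design$reference, names(which.min(mean_by_cat)))
  # zero-cost cases are rejected by name
  c_bad <- costs_from_totals(sim$patients, sim$latent$cost_mmk, "MMK")
  c_bad$total[3] <- 0
  expect_error(build_design(sim$patients, c_bad),
               sim$patients$patient_id[3])
})

test_that("OLS matches a normal-equations oracle on random instances", {
  set.seed(21)
  for (i in 1:10) {
    n <- 40; p <- 4
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    y <- 1 + X %*% runif(p, -2, 2) + rnorm(n, 0, 0.5)
    design <- make_design(X, drop(y))
    fit <- fit_cost_model(design)
    Z <- cbind(1, X)
    beta_oracle <- solve(t(Z) %*% Z, t(Z) %*% y)
    expect_equal(unname(fit$coef), unname(drop(beta_oracle)), tolerance = 1e-8)
    expect_equal(sum(fit$residuals), 0, tolerance = 1e-8 * sd(y) * n)
  }
})

test_that("exact linear data give a perfect fit", {
  X <- matrix(seq_len(20), 20, 1, dimnames = list(NULL, "x1"))
  y <- 2 + 3 * X[, 1]
  fit <- suppressWarnings(fit_cost_model(make_design(X, y)))
  expect_equal(fit$r_squared, 1)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected as singular", {
  X <- cbind(x1 = rnorm(30))
  X <- cbind(X, x2 = X[, 1])
  expect_error(fit_cost_model(make_design(X, rnorm(30))), "singular")
})

test_that("Durbin-Watson matches hand computations and the iid reference", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)
  expect_equal(durbin_watson(rep(0.7, 6)), 0)
  expect_warning(d0 <- durbin_watson(rep(0, 5)), "undefined")
  expect_true(is.nan(d0))
  set.seed(33)
  e <- rnorm(10000)
  expect_equal(durbin_watson(e), 2, tolerance = 0.05 / 2)
  # cross-check against the independent lmtest implementation
  fit <- lm(e ~ 1)
  expect_equal(durbin_watson(residuals(fit)),
               unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-10)
})

test_that("collinearity diagnostics match brute force and car::vif", {
  # orthogonal centered predictors (orthogonal polynomials): VIF exactly 1
  X <- unclass(stats::poly(1:100, 3))
  colnames(X) <- paste0("x", 1:3)
  cd <- collinearity_diagnostics(X)
  expect_equal(unname(cd$vif), rep(1, 3), tolerance = 1e-8)

  # duplicated column: tolerance 0, infinite VIF
  Xd <- cbind(x1 = rnorm(50))
  Xd <- cbind(Xd, x2 = Xd[, 1])
  cdd <- collinearity_diagnostics(Xd)
  expect_equal(unname(cdd$tolerance), c(0, 0), tolerance = 1e-10)
  expect_true(all(is.infinite(cdd$vif) | cdd$vif > 1e10))

  # random instance against brute-force auxiliary regressions and car::vif
  set.seed(44)
  Z <- matrix(rnorm(200 * 4), 200, 4) %*% chol(0.5 + 0.5 * diag(4))
  colnames(Z) <- paste0("x", 1:4)
  cdz <- collinearity_diagnostics(Z)
  for (j in 1:4) {
    r2 <- summary(lm(Z[, j] ~ Z[, -j]))$r.squared
    expect_equal(unname(cdz$tolerance[j]), 1 - r2, tolerance = 1e-8)
  }
  y <- rnorm(200)
  vif_car <- car::vif(lm(y ~ ., data = data.frame(Z)))
  expect_equal(unname(cdz$vif), unname(vif_car), tolerance = 1e-8)
  expect_gte(min(cdz$condition_indices), 1)
  expect_equal(min(cdz$condition_indices), 1)
})

test_that("case diagnostics equal brute-force leave-one-out refits", {
  set.seed(55)
  n <- 25
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 1 + X %*% c(1, -1) + rnorm(n, 0, 0.3)
  design <- make_design(X, drop(y))
  fit <- fit_cost_model(design)
  diag <- case_diagnostics(fit)
  p <- 3  # parameters including intercept
  s2 <- sum(fit$residuals^2) / (n - p)
  for (i in seq_len(n)) {
    loo <- lm(y[-i] ~ X[-i, ])
    pred_i <- sum(c(1, X[i, ]) * coef(loo))
    s_loo <- summary(loo)$sigma
    h_i <- diag$leverage[i]
    # SDR: deleted residual over its standard error
    sdr_oracle <- (y[i] - pred_i) / (s_loo * sqrt(1 + t(c(1, X[i, ])) %*%
      solve(crossprod(cbind(1, X[-i, ]))) %*% c(1, X[i, ])))
    expect_equal(diag$sdr[i], drop(sdr_oracle), tolerance = 1e-8)
    # Cook's D via the shift in fitted values
    fitted_full <- fit$fitted
    fitted_drop <- cbind(1, X) %*% coef(loo)
    cook_oracle <- sum((fitted_full - fitted_drop)^2) / (p * s2)
    expect_equal(diag$cooks[i], drop(cook_oracle), tolerance = 1e-8)
  }
})

test_that("a zero-residual case has zero SDR and Cook's distance", {
  X <- cbind(x1 = c(0, 0, 1, 1, 2, 2))
  y <- c(1, 3, 2, 4, 3, 5)  # symmetric pairs: line passes between each pair
  fit <- fit_cost_model(make_design(X, y))
  # construct one exactly-fitted point
  X2 <- cbind(x1 = c(X[, 1], 3))
  y2 <- c(y, sum(c(1, 3) * fit$coef))
  fit2 <- fit_cost_model(make_design(X2, y2))
  diag2 <- case_diagnostics(fit2)
  expect_equal(diag2$sdr[7], 0, tolerance = 1e-8)
  expect_equal(diag2$cooks[7], 0, tolerance = 1e-12)
})

test_that("a planted gross outlier is flagged with the maximum |SDR|", {
  set.seed(66)
  sim <- generate_cohort(cohort_params(n = 60, sigma = 0.05), seed = 66)
  latent <- sim$latent
  latent$cost_mmk[10] <- latent$cost_mmk[10] * 8  # gross outlier
  costs <- costs_from_totals(sim$patients, latent$cost_mmk, "MMK")
  fit <- stepwise_select(build_design(sim$patients, costs))
  diag <- case_diagnostics(fit)
  expect_identical(which.max(abs(diag$sdr)), 10L)
  expect_gt(abs(diag$sdr[10]), 2)
})

test_that("stepwise limits: everything at p = 1, nothing as p_enter -> 0", {
  set.seed(77)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- 1 + 0.5 * X[, 1] + rnorm(n)
  design <- make_design(X, y)
  full <- stepwise_select(design, cost_model_spec(p_enter = 1, p_remove = 1))
  expect_setequal(full$selected, colnames(X))
  expect_equal(full$coef[colnames(X)],
               fit_cost_model(design)$coef[colnames(X)])
  none <- stepwise_select(design, cost_model_spec(p_enter = 1e-12,
                                                  p_remove = 0.1))
  expect_length(none$selected, 0)
})

test_that("a strong real predictor enters before pure-noise candidates", {
  set.seed(88)
  for (rep in 1:5) {
    n <- 500
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, c(paste0("noise", 1:5), "real")))
    y <- 2 + 5 * X[, "real"] + rnorm(n)
    fit <- stepwise_select(make_design(X, y))
    expect_identical(fit$selected[1], "real")
  }
})

test_that("trimming drops exactly the planted outliers and refits", {
  sim <- generate_cohort(cohort_params(n = 91, sigma = 0.08), seed = 14)
  latent <- sim$latent
  planted <- c(5, 23, 57, 80)
  latent$cost_mmk[planted] <- latent$cost_mmk[planted] *
    c(6, 1 / 6, 7, 1 / 7)
  costs <- costs_from_totals(sim$patients, latent$cost_mmk, "MMK")
  tm <- trim_and_refit(sim$patients, costs)
  expect_setequal(tm$dropped, sim$patients$patient_id[planted])
  expect_equal(tm$initial$n - tm$trimmed$n, length(planted))

  # with no outliers the refit is the original fit
  clean <- costs_from_totals(sim$patients, sim$latent$cost_mmk, "MMK")
  design <- build_design(sim$patients, clean)
  base <- stepwise_select(design)
  if (!any(case_diagnostics(base)$outlier)) {
    tm2 <- trim_and_refit(sim$patients, clean)
    expect_identical(tm2$dropped, character(0))
    expect_equal(tm2$trimmed$coef, tm2$initial$coef)
  }
})

test_that("smearing factor matches hand values and Jensen's bound", {
  expect_equal(smearing_factor(rep(0, 10)), 1)
  expect_equal(smearing_factor(c(log(2), -log(2))), 1.25)
  set.seed(99)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    expect_gte(smearing_factor(residuals(lm(y ~ x))), 1)
  }
})

test_that("intercept-only retransformation is exactly consistent", {
  set.seed(123)
  y <- rnorm(50, 10, 0.3)
  fit <- fit_cost_model(make_design(data.frame(row.names = 1:50), y,
                                    reference = "aph"), character(0))
  expect_equal(exp(unname(fit$coef[1])) * fit$smearing, mean(exp(y)),
               tolerance = 1e-12)
})

test_that("fixed-coefficient prediction reproduces the published worked values", {
  fm <- fixed_cost_model(published_coefficients(), smearing = 1.0024,
                         reference = "aph")
  pred <- predict_category_cost(fm, c("incomplete_abortion", "prolonged_labor",
                                      "pph", "septicemia"), age = 26.75)
  expect_equal(unname(pred), c(35.75, 37.43, 27.79, 16.59))
  # the PIH chain gives 21.815, agreeing with the printed 21.82 to its precision
  pih <- predict_category_cost(fm, "pih", age = 26.75, digits = NULL)
  expect_lt(abs(unname(pih) - 21.82), 0.011)
  # reference category: intercept plus age only, near its observed mean range
  aph <- predict_category_cost(fm, "aph", age = 26.75, digits = NULL)
  expect_gt(unname(aph), 14.0)
  expect_lt(unname(aph), 15.0)
  # unknown category errors
  expect_error(predict_category_cost(fm, "pid", age = 26.75),
               "neither the reference nor in the model")
})
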