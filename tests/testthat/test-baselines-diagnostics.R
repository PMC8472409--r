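test_that("pooled OLS recovers exact linear structure", {
  set.seed(2)
  n <- 30
  rec <- data.frame(id = rep(sprintf("i%02d", 1:n), each = 2),
                    period = rep(1:2, n), bmi = runif(2 * n, 20, 35),
                    x = rnorm(2 * n), gender = "female", skill = "low",
                    employment_status = "employee", pregnant = FALSE,
                    stringsAsFactors = FALSE)
  rec$hours <- 2 * rec$bmi
  fit <- fit_pooled_ols(panel_dataset(rec, "x"))
  expect_equal(unname(fit$coefficients["bmi"]), 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  rec$hours <- 40
  fit0 <- fit_pooled_ols(panel_dataset(rec, "x"))
  expect_equal(unname(fit0$coefficients["bmi"]), 0, tolerance = 1e-10)
  expect_equal(unname(fit0$coefficients["x"]), 0, tolerance = 1e-10)
})

test_that("pooled OLS equals hand-solved normal equations on a toy table", {
  rec <- data.frame(id = rep(c("a", "b", "c"), each = 2),
                    period = rep(1:2, 3),
                    hours = c(30, 34, 42, 40, 25, 28),
                    bmi = c(22, 24, 27, 28, 31, 33),
                    x = c(1, 1, 0, 2, 1, 3),
                    gender = "female", skill = "low",
                    employment_status = "employee", pregnant = FALSE,
                    stringsAsFactors = FALSE)
  fit <- fit_pooled_ols(panel_dataset(rec, "x"))
  X <- cbind(1, rec$x, rec$bmi)
  beta_hand <- solve(t(X) %*% X, t(X) %*% rec$hours)  # normal equations
  expect_equal(unname(fit$coefficients), as.numeric(beta_hand),
               tolerance = 1e-10)
  res <- rec$hours - X %*% beta_hand
  sigma2 <- sum(res^2) / (6 - 3)
  se_hand <- sqrt(diag(solve(t(X) %*% X)) * sigma2)
  expect_equal(unname(fit$se), se_hand, tolerance = 1e-10)
})

test_that("collinear pooled design errors, naming the dependent column", {
  rec <- toy_panel()$records
  rec$copy <- rec$x
  expect_error(fit_pooled_ols(panel_dataset(rec, c("x", "copy"))),
               "copy")
})

test_that("fixed effects ignore pure individual heterogeneity", {
  set.seed(5)
  n <- 50
  omega <- rnorm(n, 0, 6)
  rec <- data.frame(id = rep(sprintf("i%02d", 1:n), each = 2),
                    period = rep(1:2, n), bmi = runif(2 * n, 20, 35),
                    x = rnorm(2 * n), gender = "female", skill = "low",
                    employment_status = "employee", pregnant = FALSE,
                    stringsAsFactors = FALSE)
  rec$hours <- rep(30 + omega, each = 2)  # hours depend only on the effect
  fit <- fit_fixed_effects(panel_dataset(rec, "x"))
  expect_equal(unname(fit$coefficients["bmi"]), 0, tolerance = 1e-10)
})

test_that("FE slopes equal a hand-computed demeaned regression", {
  rec <- data.frame(id = rep(c("a", "b", "c", "d"), each = 2),
                    period = rep(1:2, 4),
                    hours = c(30, 36, 40, 38, 25, 29, 33, 30),
                    bmi = c(22, 25, 27, 28, 31, 34, 24, 23),
                    gender = "female", skill = "low",
                    employment_status = "employee", pregnant = FALSE,
                    stringsAsFactors = FALSE)
  fit <- fit_fixed_effects(panel_dataset(rec, character(0)))
  ym <- ave(rec$hours, rec$id); xm <- ave(rec$bmi, rec$id)
  slope_hand <- sum((rec$bmi - xm) * (rec$hours - ym)) /
    sum((rec$bmi - xm)^2)
  expect_equal(unname(fit$coefficients["bmi"]), slope_hand,
               tolerance = 1e-12)
})

test_that("with two periods FE coincides with first-difference least squares", {
  for (s in 1:6) {
    data <- random_panel(n = 35, k = 2, seed = 50 + s)
    fe <- suppressMessages(fit_fixed_effects(data))
    rows <- first_difference(data)
    Xd <- as.matrix(rows[, c("d_x1", "d_x2", "d_bmi")])
    fd <- qr.coef(qr(Xd), rows$d_hours)  # no intercept: demeaning identity
    expect_equal(unname(fe$coefficients[c("x1", "x2", "bmi")]),
                 unname(fd), tolerance = 1e-10)
  }
})

test_that("FE drops time-invariant regressors and errors when none remain", {
  rec <- toy_panel()$records
  rec$constant_cov <- rep(c(5, 3, 7), each = 2)
  expect_message(
    fit_fixed_effects(panel_dataset(rec, c("x", "constant_cov"))),
    "constant_cov")
  rec2 <- rec
  rec2$bmi <- rep(c(25, 27, 30), each = 2)
  rec2$x <- rep(c(1, 2, 0), each = 2)
  expect_error(
    suppressMessages(fit_fixed_effects(panel_dataset(rec2, "x"))),
    "no regressor")
})

test_that("pooled OLS agrees with FE when effects are absent and BMI exogenous", {
  cfg <- default_bcs_config("female", n = 5000, seed = 61,
                            sigma_omega = 1e-6, lambda_endog = 0)
  cfg$truth$delta <- 0  # keep the pooled and within estimands identical
  sim <- simulate_panel(cfg)
  ols <- fit_pooled_ols(sim$data)
  fe <- suppressMessages(fit_fixed_effects(sim$data))
  diff <- abs(unname(ols$coefficients["bmi"]) -
                unname(fe$coefficients["bmi"]))
  tol <- 3 * sqrt(ols$se["bmi"]^2 + fe$se["bmi"]^2)
  expect_lt(diff, tol)
})

test_that("Cragg-Donald equals the first-stage F with one endogenous, one instrument", {
  for (s in 1:5) {
    set.seed(200 + s)
    n <- 150
    exog <- cbind(rnorm(n), rnorm(n))
    z <- rnorm(n)
    endog <- 0.5 * z + exog %*% c(1, -1) + rnorm(n)
    cd <- cragg_donald(endog, z, exog)
    # independent first-stage F: nested-model comparison
    X0 <- cbind(1, exog); X1 <- cbind(X0, z)
    rss0 <- sum(qr.resid(qr(X0), endog)^2)
    rss1 <- sum(qr.resid(qr(X1), endog)^2)
    f_hand <- ((rss0 - rss1) / 1) / (rss1 / (n - ncol(X1)))
    expect_equal(cd, f_hand, tolerance = 1e-8)
  }
})

test_that("Cragg-Donald: null behaviour, perfect relevance and identification errors", {
  set.seed(9)
  n <- 2000
  endog <- rnorm(n)
  znoise <- matrix(rnorm(n * 4), n)
  cd_null <- cragg_donald(endog, znoise)
  expect_lt(cd_null, 5)       # near its null expectation of ~1
  expect_lt(cd_null, 16.85)   # far below the weak-instrument critical value
  expect_gt(cd_null, 0)

  expect_equal(cragg_donald(endog, endog), Inf)
  expect_error(cragg_donald(cbind(endog, rnorm(n)), znoise[, 1]),
               "under-identified")
})

test_that("Sargan test is undefined for just-identified systems", {
  set.seed(10)
  n <- 50
  Z <- cbind(1, rnorm(n))
  expect_error(sargan_test(rnorm(n), system = list(Z = Z), n_params = 2),
               "df = 0")
})

test_that("Sargan test rejects an invalid instrument", {
  reject <- vapply(1:40, function(i) {
    cfg <- default_bcs_config("female", n = 3200, seed = 4000 + i)
    cfg$truth$delta <- 0
    sim <- simulate_panel(cfg)
    rec <- sim$data$records
    zi <- as.data.frame(sim$instruments)
    mb <- zi$mother_bmi[match(rec$id, zi$id)]
    # violate exclusion: mother's BMI enters period-2 hours directly
    rec$hours <- rec$hours + 0.3 * mb * (rec$period == 2)
    data <- panel_dataset(rec, sim$data$covariates)
    rows <- suppressMessages(first_difference(data))
    iv <- fit_fd_iv(rows, sim$instruments)
    sargan_test(iv)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.5)
})

test_that("Stock-Yogo lookup returns tabulated constants and errors on unknown keys", {
  expect_identical(stock_yogo_lookup(1, 4, "bias_5"), 16.85)
  expect_identical(stock_yogo_lookup(1, 1, "size_10"), 16.38)
  expect_identical(stock_yogo_lookup(2, 2, "size_10"), 7.03)
  expect_error(stock_yogo_lookup(3, 4, "bias_5"), "available keys")
  expect_error(stock_yogo_lookup(1, 2, "bias_5"), "available keys")
})

test_that("instrument diagnostics report a coherent summary on simulated data", {
  sim <- simulate_panel(default_bcs_config("female", n = 828, seed = 3))
  d <- instrument_diagnostics(sim$data, sim$instruments)
  expect_gt(d$first_stage_r2, 0.10)
  expect_lt(d$first_stage_r2, 0.30)
  expect_gt(d$cragg_donald_F, 0)
  expect_equal(d$stock_yogo_critical, 16.85)
  expect_equal(d$sargan_df, 3L)
  expect_true(d$sargan_p >= 0 && d$sargan_p <= 1)
})
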