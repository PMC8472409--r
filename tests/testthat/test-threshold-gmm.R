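test_that("moment system matches hand construction on the toy panel", {
  rows <- first_difference(toy_panel())
  sys <- build_moment_system(rows, toy_instruments(), gamma = 30)
  rows <- rows[order(rows$id), ]
  ord <- order(sys$ids)
  # hand: dkink = kink(q2,30) - kink(q1,30) = (2, 0, 0) for A, B, C
  expect_equal(unname(sys$X[ord, "kink"]), c(2, 0, 0))
  expect_equal(unname(sys$X[ord, "d_bmi"]), c(4, 1, -1))
  expect_equal(unname(sys$X[ord, "d_x"]), c(2, 0, 1))
  expect_equal(unname(sys$X[, "(Intercept)"]), rep(1, 3))
  expect_equal(unname(sys$Z[ord, "mother_bmi"]), c(23, 24, 22))
  expect_equal(sys$y[ord], c(4, -2, 4))
  expect_equal(dim(sys$Z), c(3, 6))

  # equal BMI in both periods: zero difference and zero kink at every gamma
  rec <- toy_panel()$records
  rec$bmi <- 24
  rows2 <- suppressMessages(first_difference(panel_dataset(rec, "x")))
  for (g in c(20, 24, 28)) {
    s2 <- build_moment_system(rows2, toy_instruments(), g)
    expect_equal(unname(s2$X[, "d_bmi"]), rep(0, 3))
    expect_equal(unname(s2$X[, "kink"]), rep(0, 3))
  }

  # missing instrument row is a join error naming the id
  inst <- as.data.frame(toy_instruments())
  expect_error(build_moment_system(rows, instrument_table(inst[-2, ]), 30),
               "B")
})

random_system <- function(n = 30, p = 3, m = 5, seed = 1) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  colnames(X) <- c("c", paste0("x", seq_len(p - 1)))
  Z <- cbind(X[, 1:2], matrix(rnorm(n * (m - 2)), n))
  colnames(Z) <- c("c", "x1", paste0("z", seq_len(m - 2)))
  y <- as.numeric(X %*% rnorm(p)) + rnorm(n)
  list(y = y, X = X, Z = Z, n = n)
}

test_that("self-instrumented GMM collapses to least squares", {
  set.seed(3)
  n <- 40
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("c", "x1", "x2")
  y <- 1 + 2 * X[, 2] - X[, 3] + rnorm(n)
  sys <- list(y = y, X = X, Z = X, n = n)
  # arbitrary SPD weight
  A <- matrix(rnorm(9), 3); W <- crossprod(A) + diag(3)
  fit <- gmm_linear_at_gamma(sys, W)
  ols <- qr.coef(qr(X), y)
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-10)
  expect_lt(fit$objective, 1e-16)
})

test_that("closed-form GMM equals brute-force minimization of the criterion", {
  for (s in 1:5) {
    sys <- random_system(seed = s)
    W <- diag(ncol(sys$Z))
    fit <- gmm_linear_at_gamma(sys, W)
    crit <- function(theta) {
      g <- crossprod(sys$Z, sys$y - sys$X %*% theta) / sys$n
      sys$n * sum(g * (W %*% g))
    }
    bf <- optim(rep(0, ncol(sys$X)), crit, method = "BFGS",
                control = list(reltol = 1e-15, maxit = 2000))
    expect_equal(unname(fit$coefficients), bf$par, tolerance = 1e-6)
    expect_lt(abs(fit$objective - bf$value), 1e-6)
  }
})

test_that("GMM with first-step weight equals textbook 2SLS", {
  for (s in 1:10) {
    sys <- random_system(n = 60, seed = 100 + s)
    W <- solve(crossprod(sys$Z) / sys$n)
    fit <- gmm_linear_at_gamma(sys, W)
    # independent matrix-algebra 2SLS
    P <- sys$Z %*% solve(crossprod(sys$Z), t(sys$Z))
    b2sls <- solve(t(sys$X) %*% P %*% sys$X, t(sys$X) %*% P %*% sys$y)
    expect_equal(unname(fit$coefficients), as.numeric(b2sls),
                 tolerance = 1e-8)
  }
})

test_that("trimmed grid spans the configured pooled quantiles", {
  sim <- simulate_panel(noise_free_config(n = 400, seed = 6))
  rows <- suppressMessages(first_difference(sim$data))
  prof <- suppressMessages(profile_gamma(rows, sim$instruments,
                                         gmm_spec(trim_rate = 0.30)))
  qp <- c(rows$bmi_1, rows$bmi_2)
  expect_equal(min(prof$gamma), quantile(qp, 0.15, names = FALSE))
  expect_equal(max(prof$gamma), quantile(qp, 0.85, names = FALSE))
})

test_that("noise-free data: profile minimized at the true threshold with zero objective", {
  cfg <- noise_free_config(n = 400, seed = 14, gamma = 26,
                           alpha = 2, delta = -5)
  sim <- simulate_panel(cfg)
  rows <- suppressMessages(first_difference(sim$data))
  sp <- gmm_spec(gamma_grid = sort(c(seq(22, 30, length.out = 100), 26)))
  prof <- suppressMessages(profile_gamma(rows, sim$instruments, sp))
  j <- which.min(prof$objective)
  expect_equal(prof$gamma[j], 26)
  expect_lt(prof$objective[j], 1e-14)
  # off-threshold candidates fit strictly worse
  expect_gt(min(prof$objective[prof$gamma != 26], na.rm = TRUE), 1e-10)
})

test_that("no kink (delta = 0) and no noise: profile identically zero", {
  cfg <- noise_free_config(n = 300, seed = 15, delta = 0)
  sim <- simulate_panel(cfg)
  rows <- suppressMessages(first_difference(sim$data))
  prof <- suppressMessages(profile_gamma(rows, sim$instruments))
  expect_true(all(prof$objective[!prof$skipped] < 1e-14))
})

test_that("exact fit: noise-free threshold fit recovers all parameters", {
  cfg <- noise_free_config(n = 500, seed = 16, gamma = 27,
                           alpha = 2, delta = -5)
  sim <- simulate_panel(cfg)
  tp <- sim$truth
  sp <- gmm_spec(gamma_grid = sort(c(seq(23, 31, length.out = 150), 27)))
  fit <- suppressMessages(fit_panel_threshold(sim$data, sim$instruments, sp))
  expect_equal(fit$gamma, 27)
  expect_equal(fit$alpha, 2, tolerance = 1e-8)
  expect_equal(fit$delta, -5, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["d_degree"]),
               unname(tp$beta["degree"]), tolerance = 1e-8)
  # exact fit: the step-1 criterion vanishes at the truth (the two-step
  # J is numerically unstable here because the moment covariance is zero)
  p1 <- fit$step1_profile
  expect_lt(min(p1$objective[!p1$skipped], na.rm = TRUE), 1e-12)
  # with the default even grid gamma lands on the nearest grid point
  fit2 <- suppressMessages(fit_panel_threshold(sim$data, sim$instruments,
                                               gmm_spec()))
  step <- diff(fit2$objective_profile$gamma[1:2])
  expect_lt(abs(fit2$gamma - 27), step)
})

test_that("threshold fit is scale-equivariant in the outcome", {
  cfg <- default_bcs_config("female", n = 400, seed = 31)
  sim <- simulate_panel(cfg)
  fit1 <- suppressMessages(fit_panel_threshold(sim$data, sim$instruments))
  cc <- 3.7
  rec <- sim$data$records
  rec$hours <- rec$hours * cc
  scaled <- panel_dataset(rec, sim$data$covariates)
  fit2 <- suppressMessages(fit_panel_threshold(scaled, sim$instruments))
  expect_equal(fit2$gamma, fit1$gamma)
  expect_equal(fit2$alpha, cc * fit1$alpha, tolerance = 1e-7)
  expect_equal(fit2$delta, cc * fit1$delta, tolerance = 1e-7)
  expect_equal(unname(fit2$se[["d_bmi"]]), cc * unname(fit1$se[["d_bmi"]]),
               tolerance = 1e-6)
  expect_equal(unname(fit2$se[["kink"]]), cc * unname(fit1$se[["kink"]]),
               tolerance = 1e-6)
})

test_that("regime slopes implement alpha and alpha + delta", {
  tp <- threshold_params(0, c(x = 0), 4.656, -7.088, 30.021)
  rs <- regime_slopes(tp)
  expect_equal(unname(rs["below"]), 4.656)
  expect_equal(unname(rs["above"]), -2.432, tolerance = 1e-12)
  expect_equal(unname(regime_slopes(threshold_params(0, c(x = 0), 0, 0, 25))),
               c(0, 0))
  expect_equal(unname(regime_slopes(
    threshold_params(0, c(x = 0), 1, -1, 25))["above"]), 0)
})

test_that("J-statistic has the stated degrees of freedom and scale", {
  sim <- simulate_panel(default_bcs_config("female", n = 400, seed = 19))
  fit <- suppressMessages(fit_panel_threshold(sim$data, sim$instruments))
  # 9 moments (intercept + 4 differenced covariates + 4 instruments),
  # 8 parameters (7 linear + the threshold)
  expect_equal(fit$j_df, 1L)
  expect_gte(fit$j_statistic, 0)
  expect_true(fit$gamma %in% fit$objective_profile$gamma)
  pr <- fit$objective_profile
  expect_equal(fit$gamma,
               pr$gamma[!pr$skipped][which.min(pr$objective[!pr$skipped])])
})

test_that("profile objective is smooth in gamma at the grid-step scale", {
  sim <- simulate_panel(default_bcs_config("female", n = 400, seed = 23))
  rows <- suppressMessages(first_difference(sim$data))
  coarse <- suppressMessages(profile_gamma(rows, sim$instruments,
                                           gmm_spec(grid_points = 200)))
  fine <- suppressMessages(profile_gamma(rows, sim$instruments,
                                         gmm_spec(grid_points = 800)))
  dmax <- function(p) max(abs(diff(p$objective[!p$skipped])), na.rm = TRUE)
  # halving the step about halves adjacent changes; allow generous slack
  expect_lt(dmax(fine), dmax(coarse))
  expect_lt(dmax(coarse), 8 * dmax(fine))
})

test_that("degenerate threshold variable is a configuration error", {
  rec <- toy_panel()$records
  rec$bmi <- 25
  rows <- suppressMessages(first_difference(panel_dataset(rec, "x")))
  expect_error(
    suppressWarnings(suppressMessages(profile_gamma(rows, toy_instruments()))),
    "grid")
})

test_that("estimation error shrinks with sample size (stochastic, fixed seeds)", {
  ns <- c(200, 800, 3200)
  reps <- 30
  rmse <- sapply(ns, function(N) {
    est <- t(vapply(seq_len(reps), function(i) {
      sim <- simulate_panel(default_bcs_config("female", n = N,
                                               seed = 7000 + 17 * i + N))
      fit <- suppressMessages(fit_panel_threshold(sim$data, sim$instruments))
      c(fit$alpha, fit$delta)
    }, numeric(2)))
    sqrt(colMeans(sweep(est, 2, c(4.656, -7.088))^2))
  })
  # delta is the well-identified parameter: strictly shrinking RMSE
  expect_lt(rmse[2, 3], rmse[2, 1])
  expect_lt(rmse[2, 2], 1.2 * rmse[2, 1])
  # alpha inherits threshold noise: require no blow-up and eventual decrease
  expect_lt(rmse[1, 3], 1.2 * rmse[1, 1])
})

test_that("J-statistic is calibrated under correct specification", {
  j <- vapply(1:300, function(i) {
    sim <- simulate_panel(default_bcs_config("female", n = 800,
                                             seed = 30000 + i))
    fit <- suppressMessages(fit_panel_threshold(sim$data, sim$instruments))
    fit$j_statistic
  }, numeric(1))
  rej <- mean(j > qchisq(0.95, 1))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
})

test_that("pairs bootstrap standard errors are finite and positive", {
  sim <- simulate_panel(default_bcs_config("female", n = 200, seed = 77))
  sp <- gmm_spec(se_method = "pairs_bootstrap", bootstrap_reps = 30,
                 grid_points = 60)
  set.seed(1)
  fit <- suppressMessages(fit_panel_threshold(sim$data, sim$instruments, sp))
  expect_true(all(is.finite(fit$se)))
  expect_true(all(fit$se > 0))
})
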