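#' Parameters of the kink-threshold outcome equation
#'
#' The estimand of the model
#' `y_it = beta0 + x_it' beta + alpha * q_it + delta * (q_it - gamma)_+ +
#' omega_i + eps_it`: BMI raises (or lowers) weekly hours with slope `alpha`
#' below the threshold `gamma` and slope `alpha + delta` above it, with no
#' jump at the threshold.
#'
#' @param beta0 intercept (hours)
#' @param beta named numeric vector of covariate coefficients
#' @param alpha below-threshold BMI slope (hours per kg/m^2)
#' @param delta slope change at the threshold
#' @param gamma threshold (kg/m^2)
#' @return object of class `threshold_params`
#' @export
threshold_params <- function(beta0, beta, alpha, delta, gamma) {
  stopifnot(is.finite(beta0), is.finite(alpha), is.finite(delta),
            is.finite(gamma), all(is.finite(beta)))
  structure(list(beta0 = beta0, beta = beta, alpha = alpha,
                 delta = delta, gamma = gamma),
            class = "threshold_params")
}

#' @export
print.threshold_params <- function(x, ...) {
  cat("Kink-threshold parameters:\n")
  cat("  alpha (below-threshold slope):", format(x$alpha), "\n")
  cat("  delta (slope change):         ", format(x$delta), "\n")
  cat("  gamma (threshold):            ", format(x$gamma), "\n")
  cat("  regime slopes: below =", format(x$alpha),
      " above =", format(x$alpha + x$delta), "\n")
  invisible(x)
}

# Shifted-lognormal sampler matched to a target mean, SD and skewness.
# skew = 0 falls back to the normal. Used for the childhood BMI instruments,
# whose real distributions are right-skewed; with jointly Gaussian
# instruments the threshold is unidentified in the differenced moment
# system (the instrument moments of any function of the two BMI indices
# collapse onto a two-dimensional subspace), so the skewness is what lets
# the moments trace the kink.
rskewed <- function(n, mean, sd, skew) {
  if (skew == 0) return(stats::rnorm(n, mean, sd))
  flip <- sign(skew)
  skew <- abs(skew)
  # lognormal skewness (w + 2) * sqrt(w - 1) = skew, w = exp(sigma^2)
  w <- stats::uniroot(function(w) (w + 2) * sqrt(w - 1) - skew,
                      c(1 + 1e-10, 50))$root
  sigma <- sqrt(log(w))
  scale <- sd / sqrt(w * (w - 1))          # e^{mu + sigma^2/2}
  x <- scale * exp(sigma * stats::rnorm(n))
  mean + flip * (x - scale * sqrt(w))      # center the exp part on zero
}

default_covariate_scheme <- function(degree_p = c(0.197, 0.287),
                                     famsize_mean = c(3.388, 3.496),
                                     famsize_sd = c(1.006, 1.026),
                                     skill_p = c(0.469, 0.551),
                                     england_p = 0.843,
                                     england_switch_down = 0.02,
                                     ages = c(34, 42)) {
  list(degree_p = degree_p, famsize_mean = famsize_mean,
       famsize_sd = famsize_sd, skill_p = skill_p, england_p = england_p,
       england_switch_down = england_switch_down, ages = ages)
}

#' Simulation configuration for the synthetic two-period cohort
#'
#' Describes the data-generating process: four time-invariant childhood
#' instruments `z_i` (birth weight and own/mother's/father's BMI at age 10),
#' an individual effect `omega_i` shared by the hours equation and (through
#' `lambda_endog`) the BMI equation, period-specific BMI built from an
#' instrument index plus idiosyncratic shocks, and hours following the kink
#' equation of [threshold_params()].
#'
#' BMI is generated as
#' `q_it = bmi_mean1 + bmi_drift*1{t=2} + c_t' s_i + lambda_endog*omega_i + u_it`
#' where `s_i` are the standardized instruments. The index loadings `c_t`
#' are scaled so the instruments account for `instrument_share` of the BMI
#' variance in each period; `pi_stability` is the correlation between the
#' period-1 and period-2 indices. Values below 1 let the instruments retain
#' power for BMI *changes* (a time-invariant instrument with fixed loadings
#' would difference out entirely, leaving the below-threshold slope
#' unidentified in the first-differenced moment system).
#'
#' @param n number of individuals (>= 2)
#' @param truth a [threshold_params()] object; `beta` must be named
#'   `degree, famsize, skill, england, age`
#' @param instrument_means,instrument_sds length-4 numeric (birth weight,
#'   own BMI at 10, mother's BMI, father's BMI)
#' @param instrument_cov optional 4x4 covariance for the instruments
#'   (default: independent with `instrument_sds`); providing it switches the
#'   instruments to jointly Gaussian draws
#' @param instrument_skew length-4 skewness of the instrument marginals
#'   (default 0 for birth weight, 1 for the three right-skewed childhood
#'   BMI variables); ignored when `instrument_cov` is given. Non-zero
#'   skewness is what identifies the threshold in the differenced moment
#'   system — see the methods vignette
#' @param bmi_mean1 period-1 mean BMI
#' @param bmi_drift mean BMI increase period 1 -> 2
#' @param bmi_sd length-2 target BMI standard deviations by period
#' @param instrument_share share of per-period BMI variance explained by the
#'   instruments (default 0.20)
#' @param pi_stability correlation of the instrument index across periods
#' @param sigma_omega SD of the individual effect (hours)
#' @param lambda_endog loading of `omega_i` in the BMI equation
#'   (`cov(q_it, omega_i + eps_it) = lambda_endog * sigma_omega^2`)
#' @param sigma_eps SD of the transitory hours shock
#' @param rho_u_eps correlation between contemporaneous BMI and hours shocks
#'   (0 = all endogeneity through the fixed effect)
#' @param bmi_measurement_sd optional additive noise on *recorded* BMI
#'   (self-report error; hours are generated from true BMI)
#' @param covariate_scheme list as produced by the internal default scheme
#' @param gender "female" or "male" label stamped on all records
#' @param frac_self_employed_p1,frac_not_working,frac_pregnant fractions of
#'   individuals marked for the sample filters (defaults 0: the generator
#'   emulates the final analysis sample)
#' @param seed integer seed; identical seeds give byte-identical output
#' @return object of class `sim_config`
#' @export
sim_config <- function(n,
                       truth,
                       instrument_means = c(3.267, 16.848, 23.248, 24.489),
                       instrument_sds = c(0.506, 2.160, 3.629, 2.924),
                       instrument_cov = NULL,
                       instrument_skew = c(0, 1, 1, 1),
                       bmi_mean1 = 24.919,
                       bmi_drift = 0.97,
                       bmi_sd = c(4.615, 4.870),
                       instrument_share = 0.20,
                       pi_stability = 0.625,
                       sigma_omega = 8,
                       lambda_endog = 0.173,
                       sigma_eps = 6,
                       rho_u_eps = 0,
                       bmi_measurement_sd = 0,
                       covariate_scheme = default_covariate_scheme(),
                       gender = "female",
                       frac_self_employed_p1 = 0,
                       frac_not_working = 0,
                       frac_pregnant = 0,
                       seed = 1L) {
  stopifnot(inherits(truth, "threshold_params"))
  if (n < 2) stop("n_individuals must be >= 2", call. = FALSE)
  if (sigma_omega < 0 || sigma_eps < 0 || any(bmi_sd <= 0) ||
      any(instrument_sds <= 0)) {
    stop("standard deviations must be non-negative (BMI and instrument ",
         "SDs strictly positive)", call. = FALSE)
  }
  if (instrument_share < 0 || instrument_share >= 1) {
    stop("instrument_share must lie in [0, 1)", call. = FALSE)
  }
  if (abs(pi_stability) > 1) stop("pi_stability must lie in [-1, 1]",
                                  call. = FALSE)
  if (abs(rho_u_eps) >= 1) stop("rho_u_eps must lie in (-1, 1)",
                                call. = FALSE)
  # idiosyncratic BMI variance left after the instrument index and omega
  sigma_u2 <- bmi_sd^2 * (1 - instrument_share) -
    lambda_endog^2 * sigma_omega^2
  if (any(sigma_u2 < 0)) {
    stop("config leaves non-positive idiosyncratic BMI variance; ",
         "reduce lambda_endog or instrument_share", call. = FALSE)
  }
  structure(list(
    n = as.integer(n), truth = truth,
    instrument_means = instrument_means, instrument_sds = instrument_sds,
    instrument_cov = instrument_cov, instrument_skew = instrument_skew,
    bmi_mean1 = bmi_mean1, bmi_drift = bmi_drift, bmi_sd = bmi_sd,
    instrument_share = instrument_share, pi_stability = pi_stability,
    sigma_omega = sigma_omega, lambda_endog = lambda_endog,
    sigma_eps = sigma_eps, rho_u_eps = rho_u_eps,
    bmi_measurement_sd = bmi_measurement_sd,
    covariate_scheme = covariate_scheme, gender = gender,
    frac_self_employed_p1 = frac_self_employed_p1,
    frac_not_working = frac_not_working, frac_pregnant = frac_pregnant,
    seed = as.integer(seed)), class = "sim_config")
}

#' Mean of the kink transform under a normal threshold variable
#'
#' Closed form for `E[(Q - gamma)_+]` with `Q ~ N(m, s^2)`; used to center
#' the simulated hours on a target mean.
#' @param m,s mean and SD of the threshold variable
#' @param gamma threshold
#' @return expected positive part
#' @export
expected_kink_normal <- function(m, s, gamma) {
  d <- (m - gamma) / s
  s * stats::dnorm(d) + (m - gamma) * stats::pnorm(d)
}

#' Cohort-calibrated default configuration
#'
#' Returns a [sim_config()] whose marginal moments for BMI, hours and the
#' childhood instruments match the study cohort's summary statistics for the
#' requested arm, and whose truth slopes/threshold are the published
#' panel-threshold estimates for that arm: female
#' `(alpha, delta, gamma) = (4.656, -7.088, 30.021)`, male
#' `(-3.021, 3.439, 25.658)`. The intercept is computed in closed form so
#' the period-1 mean of simulated hours equals the cohort mean (31.343
#' female, 45.285 male).
#'
#' @param arm "female" or "male"
#' @param n number of individuals; default is the arm's analysis sample size
#'   (828 women, 775 men)
#' @param seed integer seed
#' @param ... overrides passed on to [sim_config()]
#' @return a `sim_config`
#' @export
default_bcs_config <- function(arm = c("female", "male"), n = NULL,
                               seed = 1L, ...) {
  arm <- match.arg(arm)
  beta <- c(degree = 2.0, famsize = -0.8, skill = 1.5,
            england = 0.5, age = 0.15)
  if (arm == "female") {
    base <- list(n = 828, hours_mean1 = 31.343,
                 alpha = 4.656, delta = -7.088, gamma = 30.021,
                 instrument_means = c(3.267, 16.848, 23.248, 24.489),
                 instrument_sds = c(0.506, 2.160, 3.629, 2.924),
                 bmi_mean1 = 24.919, bmi_drift = 0.972,
                 bmi_sd = c(4.615, 4.870),
                 sigma_omega = 8, sigma_eps = 6,
                 scheme = default_covariate_scheme())
  } else {
    base <- list(n = 775, hours_mean1 = 45.285,
                 alpha = -3.021, delta = 3.439, gamma = 25.658,
                 instrument_means = c(3.401, 16.738, 23.338, 24.340),
                 instrument_sds = c(0.521, 1.872, 3.784, 2.710),
                 bmi_mean1 = 26.579, bmi_drift = 0.755,
                 bmi_sd = c(4.140, 4.359),
                 sigma_omega = 5.5, sigma_eps = 5.6,
                 scheme = default_covariate_scheme(
                   degree_p = c(0.222, 0.308),
                   famsize_mean = c(3.151, 3.485),
                   famsize_sd = c(1.039, 1.140),
                   skill_p = c(0.533, 0.578),
                   england_p = 0.834))
  }
  # endogeneity calibrated to corr(q, omega) ~= 0.3 in period 1
  lambda <- 0.3 * base$bmi_sd[1L] / base$sigma_omega
  sch <- base$scheme
  ex1 <- c(degree = sch$degree_p[1L], famsize = sch$famsize_mean[1L],
           skill = sch$skill_p[1L], england = sch$england_p,
           age = sch$ages[1L])
  ek1 <- expected_kink_normal(base$bmi_mean1, base$bmi_sd[1L], base$gamma)
  beta0 <- base$hours_mean1 - sum(ex1 * beta) -
    base$alpha * base$bmi_mean1 - base$delta * ek1
  truth <- threshold_params(beta0 = beta0, beta = beta,
                            alpha = base$alpha, delta = base$delta,
                            gamma = base$gamma)
  args <- list(n = if (is.null(n)) base$n else n, truth = truth,
               instrument_means = base$instrument_means,
               instrument_sds = base$instrument_sds,
               bmi_mean1 = base$bmi_mean1, bmi_drift = base$bmi_drift,
               bmi_sd = base$bmi_sd, sigma_omega = base$sigma_omega,
               lambda_endog = lambda, sigma_eps = base$sigma_eps,
               covariate_scheme = sch, gender = arm, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Simulate a two-period panel with endogenous BMI
#'
#' Draws instruments, individual effects, BMI and covariates per the
#' configured process and evaluates the kink outcome equation exactly.
#' When all noise SDs are zero-limit (set `sigma_eps` tiny and
#' `lambda_endog = 0`) hours reproduce the deterministic equation row by
#' row. Random draws occur in a fixed block order (instruments, individual
#' effects, BMI shocks, hours shocks, then covariates and labels) so
#' changing the covariate scheme never perturbs the BMI draws.
#'
#' @param config a [sim_config()]
#' @return list with `data` (a [panel_dataset()]), `instruments`
#'   (an [instrument_table()]) and `truth` (the generating
#'   [threshold_params()])
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(config$seed)
  n <- config$n
  mu <- config$instrument_means
  sd_z <- config$instrument_sds

  # block 1: instruments
  if (is.null(config$instrument_cov)) {
    z <- vapply(1:4, function(j)
      rskewed(n, mu[j], sd_z[j], config$instrument_skew[j]),
      numeric(n))
  } else {
    ch <- chol(config$instrument_cov)
    z <- matrix(stats::rnorm(n * 4L), n, 4L) %*% ch
    z <- sweep(z, 2L, mu, "+")
    sd_z <- sqrt(diag(config$instrument_cov))
  }
  z <- pmax(z, 0.1)  # instruments are physical quantities (> 0)
  s <- sweep(sweep(z, 2L, mu, "-"), 2L, sd_z, "/")
  # orthonormal instrument indices (under independent instruments)
  s1 <- rowSums(s) / 2
  s2 <- (s[, 1L] + s[, 2L] - s[, 3L] - s[, 4L]) / 2

  # block 2: individual effect
  omega <- stats::rnorm(n, 0, config$sigma_omega)

  # block 3: BMI shocks and recorded-BMI noise
  a <- matrix(stats::rnorm(n * 2L), n, 2L)     # BMI shock base
  b <- matrix(stats::rnorm(n * 2L), n, 2L)     # hours shock base
  me <- matrix(stats::rnorm(n * 2L), n, 2L)    # measurement noise base

  var_pi <- config$instrument_share * config$bmi_sd^2
  rho <- config$pi_stability
  idx1 <- sqrt(var_pi[1L]) * s1
  idx2 <- sqrt(var_pi[2L]) * (rho * s1 + sqrt(1 - rho^2) * s2)
  sigma_u <- sqrt(config$bmi_sd^2 * (1 - config$instrument_share) -
                    config$lambda_endog^2 * config$sigma_omega^2)
  u1 <- sigma_u[1L] * a[, 1L]
  u2 <- sigma_u[2L] * a[, 2L]
  q1 <- config$bmi_mean1 + idx1 + config$lambda_endog * omega + u1
  q2 <- config$bmi_mean1 + config$bmi_drift + idx2 +
    config$lambda_endog * omega + u2
  q1 <- pmax(q1, 1e-3)
  q2 <- pmax(q2, 1e-3)

  r_ue <- config$rho_u_eps
  eps1 <- config$sigma_eps * (r_ue * a[, 1L] + sqrt(1 - r_ue^2) * b[, 1L])
  eps2 <- config$sigma_eps * (r_ue * a[, 2L] + sqrt(1 - r_ue^2) * b[, 2L])

  # block 4: covariates and labels
  sch <- config$covariate_scheme
  upgrade_p <- function(p) (p[2L] - p[1L]) / (1 - p[1L])
  degree1 <- stats::rbinom(n, 1L, sch$degree_p[1L])
  degree2 <- pmax(degree1,
                  stats::rbinom(n, 1L, upgrade_p(sch$degree_p)))
  skill1 <- stats::rbinom(n, 1L, sch$skill_p[1L])
  skill2 <- pmax(skill1, stats::rbinom(n, 1L, upgrade_p(sch$skill_p)))
  fam1 <- pmax(1, round(stats::rnorm(n, sch$famsize_mean[1L],
                                     sch$famsize_sd[1L])))
  fam2 <- pmax(1, round(stats::rnorm(n, sch$famsize_mean[2L],
                                     sch$famsize_sd[2L])))
  eng1 <- stats::rbinom(n, 1L, sch$england_p)
  s_down <- sch$england_switch_down
  s_up <- min(1, sch$england_p / (1 - sch$england_p) * s_down)
  flip <- stats::runif(n)
  eng2 <- ifelse(eng1 == 1L, ifelse(flip < s_down, 0L, 1L),
                 ifelse(flip < s_up, 1L, 0L))
  age1 <- sch$ages[1L]; age2 <- sch$ages[2L]

  status1 <- rep("employee", n)
  status2 <- rep("employee", n)
  if (config$frac_self_employed_p1 > 0) {
    status1[stats::runif(n) < config$frac_self_employed_p1] <- "self_employed"
  }
  if (config$frac_not_working > 0) {
    status2[stats::runif(n) < config$frac_not_working] <- "not_working"
  }
  pregnant1 <- rep(FALSE, n); pregnant2 <- rep(FALSE, n)
  if (config$frac_pregnant > 0 && config$gender == "female") {
    pregnant2 <- stats::runif(n) < config$frac_pregnant
  }

  tp <- config$truth
  xb <- function(degree, fam, skill, eng, age) {
    tp$beta["degree"] * degree + tp$beta["famsize"] * fam +
      tp$beta["skill"] * skill + tp$beta["england"] * eng +
      tp$beta["age"] * age
  }
  y1 <- tp$beta0 + xb(degree1, fam1, skill1, eng1, age1) +
    tp$alpha * q1 + tp$delta * kink_transform(q1, tp$gamma) + omega + eps1
  y2 <- tp$beta0 + xb(degree2, fam2, skill2, eng2, age2) +
    tp$alpha * q2 + tp$delta * kink_transform(q2, tp$gamma) + omega + eps2

  q1_rec <- q1; q2_rec <- q2
  if (config$bmi_measurement_sd > 0) {
    q1_rec <- pmax(q1 + config$bmi_measurement_sd * me[, 1L], 1e-3)
    q2_rec <- pmax(q2 + config$bmi_measurement_sd * me[, 2L], 1e-3)
  }

  ids <- sprintf("ind%06d", seq_len(n))
  rec <- data.frame(
    id = rep(ids, 2L),
    period = rep(c(1L, 2L), each = n),
    hours = c(y1, y2),
    bmi = c(q1_rec, q2_rec),
    degree = c(degree1, degree2),
    famsize = c(fam1, fam2),
    skill = c(skill1, skill2),
    england = c(eng1, eng2),
    age = rep(c(age1, age2), each = n),
    gender = config$gender,
    stringsAsFactors = FALSE)
  rec$skill_label <- ifelse(rec$skill == 1L, "high", "low")
  rec$employment_status <- c(status1, status2)
  rec$pregnant <- c(pregnant1, pregnant2)
  # panel_dataset() uses `skill` as the label column name; the numeric
  # indicator stays a covariate, so rename on assembly
  names(rec)[names(rec) == "skill"] <- "skill_ind"
  names(rec)[names(rec) == "skill_label"] <- "skill"
  covs <- c("degree", "famsize", "skill_ind", "england", "age")
  data <- panel_dataset(rec, covariates = covs)

  inst <- instrument_table(data.frame(
    id = ids, birth_weight = z[, 1L], bmi_age10 = z[, 2L],
    mother_bmi = z[, 3L], father_bmi = z[, 4L], stringsAsFactors = FALSE))
  list(data = data, instruments = inst, truth = tp)
}
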