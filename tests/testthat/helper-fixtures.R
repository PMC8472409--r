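# Small hand-written fixtures shared across test files.

# Three-individual toy panel; differences computed by hand:
#   d_hours: A 4, B -2, C 4 ; d_bmi: A 4, B 1, C -1 ; d_x: A 2, B 0, C 1
toy_panel <- function() {
  rec <- data.frame(
    id = rep(c("A", "B", "C"), each = 2),
    period = rep(1:2, 3),
    hours = c(31, 35, 40, 38, 20, 24),
    bmi = c(28, 32, 25, 26, 22, 21),
    x = c(1, 3, 2, 2, 0, 1),
    gender = "female", skill = "low",
    employment_status = "employee", pregnant = FALSE,
    stringsAsFactors = FALSE)
  panel_dataset(rec, covariates = "x")
}

toy_instruments <- function() {
  instrument_table(data.frame(
    id = c("A", "B", "C"),
    birth_weight = c(3.1, 3.5, 2.9),
    bmi_age10 = c(17, 16, 18),
    mother_bmi = c(23, 24, 22),
    father_bmi = c(25, 24, 26),
    stringsAsFactors = FALSE))
}

# random two-period panel with k covariates, no special structure
random_panel <- function(n = 40, k = 2, seed = 1) {
  set.seed(seed)
  ids <- sprintf("r%03d", seq_len(n))
  rec <- data.frame(
    id = rep(ids, each = 2), period = rep(1:2, n),
    hours = rnorm(2 * n, 35, 8),
    bmi = rnorm(2 * n, 26, 4),
    stringsAsFactors = FALSE)
  for (j in seq_len(k)) rec[[paste0("x", j)]] <- rnorm(2 * n)
  rec$gender <- "female"; rec$skill <- "low"
  rec$employment_status <- "employee"; rec$pregnant <- FALSE
  panel_dataset(rec, covariates = paste0("x", seq_len(k)))
}

random_instruments <- function(data, seed = 2) {
  set.seed(seed)
  ids <- unique(data$records$id)
  n <- length(ids)
  instrument_table(data.frame(
    id = ids,
    birth_weight = rlnorm(n, log(3.2), 0.15),
    bmi_age10 = 16 + rlnorm(n, 0, 0.4),
    mother_bmi = 20 + rlnorm(n, 1, 0.4),
    father_bmi = 21 + rlnorm(n, 1, 0.3),
    stringsAsFactors = FALSE))
}

# noise-free kinked world: outcome follows the kink equation exactly
# (sigma_eps = 0); BMI keeps idiosyncratic variation so the design has rank
noise_free_config <- function(n = 300, seed = 4, gamma = 27,
                              alpha = 2, delta = -5, ...) {
  sim_config(
    n = n,
    truth = threshold_params(
      beta0 = 10,
      beta = c(degree = 2, famsize = -0.8, skill = 1.5,
               england = 0.5, age = 0.15),
      alpha = alpha, delta = delta, gamma = gamma),
    sigma_omega = 4, lambda_endog = 0, sigma_eps = 0,
    bmi_mean1 = 25, bmi_drift = 1, bmi_sd = c(4.5, 4.7),
    seed = seed, ...)
}
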