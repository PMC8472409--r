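#' Estimation settings for the first-difference GMM threshold fit
#'
#' @param trim_rate total fraction of the pooled BMI distribution excluded
#'   from the threshold grid, half from each tail. The default 0.3 matches
#'   the study's headline specification (15 percent per side).
#' @param grid_points number of evenly spaced candidate thresholds
#' @param grid_type "even" (quantile-bounded even grid) or "sample" (the
#'   unique pooled BMI values inside the trimmed support)
#' @param gamma_grid optional explicit numeric grid overriding the above
#' @param weighting "two_step" (efficient weight re-profiled once) or
#'   "identity"-style first step only (weight `(Z'Z/n)^-1`, i.e. 2SLS)
#' @param se_method "analytic_sandwich" or "pairs_bootstrap"
#' @param bootstrap_reps bootstrap replications when
#'   `se_method = "pairs_bootstrap"`
#' @param min_regime_fraction candidate thresholds leaving less than this
#'   fraction of pooled observations in either regime are skipped
#' @return object of class `gmm_spec`
#' @export
gmm_spec <- function(trim_rate = 0.3, grid_points = 400L,
                     grid_type = c("even", "sample"), gamma_grid = NULL,
                     weighting = c("two_step", "identity"),
                     se_method = c("analytic_sandwich", "pairs_bootstrap"),
                     bootstrap_reps = 500L, min_regime_fraction = 0.05) {
  grid_type <- match.arg(grid_type)
  weighting <- match.arg(weighting)
  se_method <- match.arg(se_method)
  if (trim_rate <= 0 || trim_rate >= 1) {
    stop("trim_rate must lie in (0, 1)", call. = FALSE)
  }
  if (min_regime_fraction < 0 || min_regime_fraction >= 0.5) {
    stop("min_regime_fraction must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(trim_rate = trim_rate,
                 grid_points = as.integer(grid_points),
                 grid_type = grid_type, gamma_grid = gamma_grid,
                 weighting = weighting, se_method = se_method,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 min_regime_fraction = min_regime_fraction),
            class = "gmm_spec")
}

# Differenced design shared by every candidate threshold: response, the
# gamma-independent regressors, the instrument block, and the BMI levels.
fd_design <- function(rows, instruments, quiet = FALSE) {
  stopifnot(is.data.frame(rows), inherits(instruments, "instrument_table"))
  covs <- attr(rows, "covariates")
  if (is.null(covs)) {
    covs <- sub("^d_", "", grep("^d_(?!hours$|bmi$)", names(rows),
                                perl = TRUE, value = TRUE))
  }
  miss <- setdiff(rows$id, instruments$id)
  if (length(miss) > 0L) {
    stop("individual(s) missing from the instrument table: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  zi <- instruments[match(rows$id, instruments$id), , drop = FALSE]
  zmat <- as.matrix(zi[, c("birth_weight", "bmi_age10", "mother_bmi",
                           "father_bmi")])
  dcols <- paste0("d_", covs)
  dx <- as.matrix(rows[, dcols, drop = FALSE])
  keep <- apply(dx, 2L, function(v) stats::var(v) > 0)
  if (any(!keep) && !quiet) {
    message("fd_design: dropping period-collinear differenced covariate(s): ",
            paste(dcols[!keep], collapse = ", "),
            " (constant difference, absorbed by the intercept)")
  }
  dx <- dx[, keep, drop = FALSE]
  X0 <- cbind(`(Intercept)` = 1, dx)
  Z <- cbind(X0, zmat)
  list(y = rows$d_hours, X0 = X0, dq = rows$d_bmi, Z = Z,
       q1 = rows$bmi_1, q2 = rows$bmi_2, ids = rows$id,
       dropped = dcols[!keep], n = nrow(rows))
}

#' Assemble the linear GMM moment system at a fixed threshold
#'
#' For each first-differenced individual the regressor vector is
#' (intercept, differenced covariates, differenced BMI, differenced kink
#' term at `gamma`) and the instrument vector is (intercept, differenced
#' covariates, the four childhood instruments). The period-collinear age
#' difference (and any other constant difference) is dropped with a message;
#' the intercept absorbs the common time trend.
#'
#' @param rows output of [first_difference()]
#' @param instruments an [instrument_table()]
#' @param gamma candidate threshold
#' @return list with `y`, regressor matrix `X`, instrument matrix `Z`, BMI
#'   levels `q1`, `q2`, ids and `n`
#' @export
build_moment_system <- function(rows, instruments, gamma) {
  d <- fd_design(rows, instruments)
  dk <- kink_transform(d$q2, gamma) - kink_transform(d$q1, gamma)
  X <- cbind(d$X0, d_bmi = d$dq, kink = dk)
  list(y = d$y, X = X, Z = d$Z, q1 = d$q1, q2 = d$q2,
       ids = d$ids, n = d$n, gamma = gamma)
}

#' Closed-form linear GMM at a fixed threshold
#'
#' Minimizes `n * gbar(theta)' W gbar(theta)` with
#' `gbar = Z'(y - X theta)/n` over the linear coefficients; the model is
#' linear once the threshold is fixed, so the minimizer has the standard
#' GMM closed form.
#'
#' @param system output of [build_moment_system()]
#' @param W symmetric positive-definite weight matrix
#'   (default `(Z'Z/n)^{-1}`, i.e. the 2SLS weight)
#' @return list with `coefficients` (named) and `objective` (the minimized
#'   criterion, already scaled by n)
#' @export
gmm_linear_at_gamma <- function(system, W = NULL) {
  Z <- system$Z; X <- system$X; y <- system$y; n <- system$n
  if (ncol(Z) < ncol(X)) {
    stop("under-identified system: fewer instruments than regressors",
         call. = FALSE)
  }
  if (is.null(W)) W <- solve_spd(crossprod(Z) / n, "Z'Z/n")
  A <- crossprod(Z, X) / n
  b <- crossprod(Z, y) / n
  M <- crossprod(A, W %*% A)
  if (rcond(M) < 1e-12) {
    qrA <- qr(A)
    bad <- colnames(X)[qrA$pivot[-seq_len(qrA$rank)]]
    stop("rank-deficient instrument cross-product; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  theta <- solve(M, crossprod(A, W %*% b))
  gbar <- b - A %*% theta
  obj <- as.numeric(n * crossprod(gbar, W %*% gbar))
  coefs <- as.numeric(theta)
  names(coefs) <- colnames(X)
  list(coefficients = coefs, objective = obj)
}

# symmetric-positive-definite solve with ridge fallback
solve_spd <- function(M, label, quiet = FALSE) {
  M <- (M + t(M)) / 2
  out <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(out) || rcond(M) < 1e-13) {
    ridge <- diag(mean(diag(M)) * 1e-8 + 1e-12, nrow(M))
    if (!quiet) {
      warning("near-singular ", label,
              "; using ridge-regularized inverse", call. = FALSE)
    }
    out <- solve(M + ridge)
  }
  (out + t(out)) / 2
}

trimmed_grid <- function(q_pooled, spec) {
  if (!is.null(spec$gamma_grid)) return(sort(unique(spec$gamma_grid)))
  lo <- stats::quantile(q_pooled, spec$trim_rate / 2, names = FALSE)
  hi <- stats::quantile(q_pooled, 1 - spec$trim_rate / 2, names = FALSE)
  if (!(hi > lo)) stop("empty threshold grid after trimming", call. = FALSE)
  if (spec$grid_type == "sample") {
    g <- sort(unique(q_pooled))
    g[g >= lo & g <= hi]
  } else {
    seq(lo, hi, length.out = spec$grid_points)
  }
}

profile_gamma_design <- function(d, spec, W) {
  q_pooled <- c(d$q1, d$q2)
  grid <- trimmed_grid(q_pooled, spec)
  if (length(grid) == 0L) {
    stop("empty threshold grid after trimming", call. = FALSE)
  }
  n2 <- length(q_pooled)
  frac_above <- vapply(grid, function(g) mean(q_pooled >= g), numeric(1))
  skipped <- frac_above < spec$min_regime_fraction |
    frac_above > 1 - spec$min_regime_fraction
  obj <- rep(NA_real_, length(grid))
  Zt <- t(d$Z)
  n <- d$n
  A0 <- Zt %*% cbind(d$X0, d_bmi = d$dq) / n
  b <- Zt %*% d$y / n
  for (j in which(!skipped)) {
    dk <- kink_transform(d$q2, grid[j]) - kink_transform(d$q1, grid[j])
    A <- cbind(A0, kink = Zt %*% dk / n)
    M <- crossprod(A, W %*% A)
    if (rcond(M) < 1e-12) { skipped[j] <- TRUE; next }
    theta <- solve(M, crossprod(A, W %*% b))
    gbar <- b - A %*% theta
    obj[j] <- as.numeric(n * crossprod(gbar, W %*% gbar))
  }
  out <- data.frame(gamma = grid, objective = obj, skipped = skipped)
  class(out) <- c("gamma_profile", "data.frame")
  out
}

#' Profile the GMM objective over the trimmed threshold grid
#'
#' Evaluates the minimized linear-GMM criterion at every candidate
#' threshold on an evenly spaced (or sample-value) grid between the
#' `trim_rate/2` and `1 - trim_rate/2` quantiles of the pooled BMI
#' distribution. Candidates leaving fewer than `min_regime_fraction` of the
#' pooled observations in either regime are skipped and flagged.
#'
#' @inheritParams build_moment_system
#' @param spec a [gmm_spec()]
#' @param W weight matrix; default `(Z'Z/n)^{-1}`
#' @return data.frame with columns `gamma`, `objective`, `skipped`
#' @export
profile_gamma <- function(rows, instruments, spec = gmm_spec(), W = NULL) {
  d <- fd_design(rows, instruments)
  if (is.null(W)) W <- solve_spd(crossprod(d$Z) / d$n, "Z'Z/n")
  profile_gamma_design(d, spec, W)
}

profile_minimum <- function(profile) {
  ok <- which(!profile$skipped & is.finite(profile$objective))
  if (length(ok) == 0L) {
    stop("all threshold candidates degenerate: both regimes empty or ",
         "rank-deficient at every grid point", call. = FALSE)
  }
  # ties broken toward the smaller gamma: grid is ascending, which.min
  # returns the first minimizer
  ok[which.min(profile$objective[ok])]
}

moment_pieces <- function(d, theta, gamma) {
  dk <- kink_transform(d$q2, gamma) - kink_transform(d$q1, gamma)
  X <- cbind(d$X0, d_bmi = d$dq, kink = dk)
  r <- d$y - as.numeric(X %*% theta)
  gi <- d$Z * r
  list(X = X, r = r, gi = gi, dk = dk)
}

fit_at <- function(d, spec, W) {
  prof <- profile_gamma_design(d, spec, W)
  j <- profile_minimum(prof)
  gamma_hat <- prof$gamma[j]
  dk <- kink_transform(d$q2, gamma_hat) - kink_transform(d$q1, gamma_hat)
  X <- cbind(d$X0, d_bmi = d$dq, kink = dk)
  sys <- list(y = d$y, X = X, Z = d$Z, q1 = d$q1, q2 = d$q2,
              ids = d$ids, n = d$n, gamma = gamma_hat)
  sol <- gmm_linear_at_gamma(sys, W)
  list(profile = prof, gamma = gamma_hat, theta = sol$coefficients,
       objective = sol$objective, system = sys)
}

sandwich_se <- function(d, theta, gamma, W) {
  n <- d$n
  mp <- moment_pieces(d, theta, gamma)
  S <- crossprod(sweep(mp$gi, 2L, colMeans(mp$gi), "-")) / n
  dr_dg <- theta[["kink"]] *
    (as.numeric(d$q2 >= gamma) - as.numeric(d$q1 >= gamma))
  G <- cbind(-crossprod(d$Z, mp$X) / n, gamma = crossprod(d$Z, dr_dg) / n)
  GWG <- crossprod(G, W %*% G)
  p <- ncol(G)
  if (rcond(GWG) < 1e-12) {
    # gamma direction unidentified (delta ~ 0): report slope SEs only
    Gs <- G[, -p, drop = FALSE]
    GWGs <- crossprod(Gs, W %*% Gs)
    mid <- crossprod(Gs, W %*% S %*% W %*% Gs)
    V <- solve(GWGs, t(solve(GWGs, t(mid)))) / n
    se <- c(sqrt(pmax(diag(V), 0)), NA_real_)
  } else {
    mid <- crossprod(G, W %*% S %*% W %*% G)
    V <- solve(GWG, t(solve(GWG, t(mid)))) / n
    se <- sqrt(pmax(diag(V), 0))
  }
  names(se) <- c(colnames(mp$X), "gamma")
  se
}

#' Fit the panel kink-threshold model by first-difference GMM
#'
#' Two-step procedure: step 1 profiles the threshold over the trimmed grid
#' with the 2SLS weight `(Z'Z/n)^{-1}`; step 2 (default) rebuilds the
#' weight from the sample covariance of the step-1 moment contributions and
#' re-profiles the threshold. Ties at the grid minimum resolve toward the
#' smaller threshold. The J-statistic is `n` times the minimized two-step
#' criterion with `#moments - #parameters` (threshold included) degrees of
#' freedom.
#'
#' @param data a [panel_dataset()] (balanced internally) or the output of
#'   [first_difference()]
#' @param instruments an [instrument_table()]
#' @param spec a [gmm_spec()]
#' @return object of class `threshold_fit`: coefficient and SE vectors
#'   (slopes plus `gamma`), the objective profile, J-statistic, regime
#'   slopes and bookkeeping fields
#' @export
fit_panel_threshold <- function(data, instruments, spec = gmm_spec()) {
  rows <- if (inherits(data, "panel_dataset")) first_difference(data)
          else data
  d <- fd_design(rows, instruments)
  n <- d$n
  converged <- TRUE
  W1 <- withCallingHandlers(
    solve_spd(crossprod(d$Z) / n, "Z'Z/n"),
    warning = function(w) converged <<- FALSE)
  step1 <- fit_at(d, spec, W1)

  if (spec$weighting == "two_step") {
    mp <- moment_pieces(d, step1$theta, step1$gamma)
    S <- crossprod(sweep(mp$gi, 2L, colMeans(mp$gi), "-")) / n
    W2 <- withCallingHandlers(
      solve_spd(S, "moment covariance"),
      warning = function(w) converged <<- FALSE)
    final <- fit_at(d, spec, W2)
    W <- W2
  } else {
    final <- step1
    W <- W1
  }

  theta <- final$theta
  gamma_hat <- final$gamma
  n_moments <- ncol(d$Z)
  n_params <- length(theta) + 1L  # threshold counts as estimated
  j_df <- n_moments - n_params
  j_stat <- final$objective
  j_p <- if (spec$weighting == "two_step" && j_df >= 1L) {
    stats::pchisq(j_stat, j_df, lower.tail = FALSE)
  } else NA_real_

  se <- if (spec$se_method == "analytic_sandwich") {
    sandwich_se(d, theta, gamma_hat, W)
  } else {
    bootstrap_se(rows, instruments, spec)
  }

  alpha <- theta[["d_bmi"]]
  delta <- theta[["kink"]]
  fit <- structure(list(
    coefficients = theta, gamma = gamma_hat, se = se,
    alpha = alpha, delta = delta,
    regime_slopes = c(below = alpha, above = alpha + delta),
    objective_profile = final$profile,
    step1_profile = step1$profile, step1_gamma = step1$gamma,
    j_statistic = j_stat, j_df = j_df, j_pvalue = j_p,
    n_used = n, converged = converged,
    dropped_covariates = d$dropped, weighting = spec$weighting,
    spec = spec, system = final$system, weight_matrix = W),
    class = "threshold_fit")
  fit
}

bootstrap_se <- function(rows, instruments, spec) {
  B <- spec$bootstrap_reps
  n <- nrow(rows)
  spec_bs <- spec
  spec_bs$se_method <- "analytic_sandwich"  # avoid recursion
  est <- matrix(NA_real_, B, 0L)
  draws <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rb <- rows[idx, , drop = FALSE]
    rb$id <- sprintf("bs%06d", seq_len(n))  # resampled pairs get fresh ids
    attr(rb, "covariates") <- attr(rows, "covariates")
    ib <- instruments[match(rows$id[idx], instruments$id), , drop = FALSE]
    ib$id <- rb$id
    class(ib) <- class(instruments)
    fb <- tryCatch(
      suppressMessages(suppressWarnings(
        fit_panel_threshold_core(rb, ib, spec_bs))),
      error = function(e) NULL)
    if (!is.null(fb)) draws[[b]] <- c(fb$theta, gamma = fb$gamma)
  }
  draws <- do.call(rbind, draws)
  if (is.null(draws) || nrow(draws) < 10L) {
    stop("pairs bootstrap failed in almost all replicates", call. = FALSE)
  }
  apply(draws, 2L, stats::sd)
}

# point estimation only (used by the bootstrap)
fit_panel_threshold_core <- function(rows, instruments, spec) {
  d <- fd_design(rows, instruments, quiet = TRUE)
  W1 <- solve_spd(crossprod(d$Z) / d$n, "Z'Z/n", quiet = TRUE)
  step1 <- fit_at(d, spec, W1)
  if (spec$weighting == "two_step") {
    mp <- moment_pieces(d, step1$theta, step1$gamma)
    S <- crossprod(sweep(mp$gi, 2L, colMeans(mp$gi), "-")) / d$n
    W2 <- solve_spd(S, "moment covariance", quiet = TRUE)
    final <- fit_at(d, spec, W2)
  } else final <- step1
  list(theta = final$theta, gamma = final$gamma)
}

#' Regime slopes of a kink-threshold model
#'
#' Below the threshold the BMI slope is `alpha`; above it the slope is
#' `alpha + delta`, the total above-threshold effect.
#'
#' @param x a [threshold_params()] or `threshold_fit`
#' @return named numeric vector `c(below, above)`
#' @export
regime_slopes <- function(x) UseMethod("regime_slopes")

#' @export
regime_slopes.threshold_params <- function(x) {
  c(below = x$alpha, above = x$alpha + x$delta)
}

#' @export
regime_slopes.threshold_fit <- function(x) x$regime_slopes

#' @export
print.threshold_fit <- function(x, ...) {
  cat("Panel kink-threshold model (first-difference GMM, ",
      x$weighting, ")\n", sep = "")
  est <- c(x$coefficients, gamma = x$gamma)
  tab <- data.frame(estimate = est, se = x$se[names(est)])
  print(round(tab, 4))
  cat("Regime slopes: below =", format(round(x$regime_slopes[1L], 3)),
      " above =", format(round(x$regime_slopes[2L], 3)), "\n")
  cat("J-statistic:", format(round(x$j_statistic, 3)), "on", x$j_df,
      "df", if (is.finite(x$j_pvalue))
        paste0("(p = ", format(round(x$j_pvalue, 3)), ")"), "\n")
  cat("n =", x$n_used, "individuals; converged:", x$converged, "\n")
  invisible(x)
}
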