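#' Cragg-Donald weak-instrument statistic
#'
#' Minimum-eigenvalue statistic of the first-stage concentration matrix
#' after partialling the included exogenous regressors out of both the
#' endogenous block and the excluded instruments, expressed on the F scale.
#' With a single endogenous regressor and a single instrument it equals the
#' first-stage F statistic. Compare against [stock_yogo_lookup()] critical
#' values.
#'
#' @param endog numeric matrix (or vector) of endogenous regressors
#' @param instruments numeric matrix of excluded instruments
#' @param exog numeric matrix of included exogenous regressors; an intercept
#'   column is always added
#' @return the Cragg-Donald F statistic (`Inf` when the first-stage
#'   residual covariance is singular, e.g. an instrument equal to the
#'   endogenous column)
#' @export
cragg_donald <- function(endog, instruments, exog = NULL) {
  endog <- as.matrix(endog)
  Zx <- as.matrix(instruments)
  n <- nrow(endog)
  if (ncol(Zx) < ncol(endog)) {
    stop("under-identified: fewer instruments (", ncol(Zx),
         ") than endogenous regressors (", ncol(endog), ")", call. = FALSE)
  }
  X <- cbind(rep(1, n), if (!is.null(exog)) as.matrix(exog))
  qx <- qr(X)
  Vt <- qr.resid(qx, endog)
  Zt <- qr.resid(qx, Zx)
  kz <- qr(Zt)$rank
  kx <- qx$rank
  qz <- qr(Zt)
  PV <- qr.fitted(qz, Vt)
  Svv <- crossprod(Vt - PV) / (n - kx - kz)
  ev <- eigen(Svv, symmetric = TRUE)
  if (min(ev$values) < 1e-10 * max(ev$values, 1)) return(Inf)
  Sinv_half <- ev$vectors %*% diag(1 / sqrt(ev$values),
                                   ncol(Svv)) %*% t(ev$vectors)
  Gmat <- Sinv_half %*% (crossprod(Vt, PV) / kz) %*% Sinv_half
  min(eigen((Gmat + t(Gmat)) / 2, symmetric = TRUE,
            only.values = TRUE)$values)
}

#' Sargan test of overidentifying restrictions
#'
#' Classical (homoskedastic) Sargan statistic
#' `n * u' P_Z u / (u'u)` computed from the residuals of an instrumental
#' variable fit, asymptotically chi-squared with
#' `#moments - #parameters` degrees of freedom under joint instrument
#' validity. A just-identified system has no testable restrictions and is
#' an error, not a silent zero.
#'
#' @param object a `threshold_fit`, an `fd_iv_fit`, or a numeric residual
#'   vector
#' @param system for a residual vector: list with the instrument matrix `Z`
#' @param n_params for a residual vector: number of estimated parameters
#' @return list with `statistic`, `df`, `p_value` (class `sargan_test`)
#' @export
sargan_test <- function(object, system = NULL, n_params = NULL) {
  if (inherits(object, "threshold_fit")) {
    system <- object$system
    u <- system$y - as.numeric(system$X %*% object$coefficients)
    n_params <- ncol(system$X) + 1L  # the threshold is estimated too
  } else if (inherits(object, "fd_iv_fit")) {
    system <- object$system
    u <- object$residuals
    n_params <- ncol(system$X)
  } else {
    u <- as.numeric(object)
    if (is.null(system) || is.null(n_params)) {
      stop("residual-vector input needs `system` (with Z) and `n_params`",
           call. = FALSE)
    }
  }
  Z <- system$Z
  df <- ncol(Z) - n_params
  if (df < 1L) {
    stop("just-identified system: df = 0, Sargan test undefined",
         call. = FALSE)
  }
  n <- length(u)
  Pu <- qr.fitted(qr(Z), u)
  stat <- n * sum(u * Pu) / sum(u^2)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "sargan_test")
}

#' @export
print.sargan_test <- function(x, ...) {
  cat("Sargan overidentification test: stat =",
      format(round(x$statistic, 3)), "on", x$df, "df, p =",
      format(round(x$p_value, 4)), "\n")
  invisible(x)
}

#' Linear first-differenced 2SLS fit
#'
#' The linear (no-kink) instrumental-variable benchmark on the differenced
#' system: regressors (intercept, differenced covariates, differenced BMI),
#' instruments (intercept, differenced covariates, the four childhood
#' variables). Used by the instrument diagnostics and as the host model for
#' the Sargan test.
#'
#' @param rows output of [first_difference()]
#' @param instruments an [instrument_table()]
#' @return object of class `fd_iv_fit` with coefficients, homoskedastic
#'   2SLS standard errors, residuals and the moment system
#' @export
fit_fd_iv <- function(rows, instruments) {
  d <- fd_design(rows, instruments, quiet = TRUE)
  X <- cbind(d$X0, d_bmi = d$dq)
  Z <- d$Z
  n <- d$n
  qz <- qr(Z)
  Xhat <- qr.fitted(qz, X)
  qxh <- qr(Xhat)
  beta <- qr.coef(qxh, d$y)
  res <- d$y - as.numeric(X %*% beta)
  sigma2 <- sum(res^2) / (n - ncol(X))
  V <- chol2inv(qr.R(qxh)) * sigma2
  se <- sqrt(diag(V))
  names(se) <- names(beta) <- colnames(X)
  structure(list(coefficients = beta, se = se, residuals = res,
                 system = list(y = d$y, X = X, Z = Z, n = n),
                 n_obs = n),
            class = "fd_iv_fit")
}

stock_yogo_env <- new.env(parent = emptyenv())

load_stock_yogo <- function() {
  if (is.null(stock_yogo_env$tab)) {
    path <- system.file("extdata", "stock_yogo.tsv", package = "panelkink")
    stock_yogo_env$tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  stock_yogo_env$tab
}

#' Stock-Yogo weak-instrument critical values
#'
#' Looks up the tabulated 2SLS critical value for the Cragg-Donald F
#' statistic from the bundled constants table, keyed by the number of
#' endogenous regressors, the number of excluded instruments and the test
#' criterion ("bias_5" = 5 percent maximal relative bias, ...,
#' "size_10" = 10 percent maximal size, ...). The value 16.85 quoted for
#' the cohort analysis corresponds to one endogenous regressor, four
#' instruments and the 5 percent maximal-relative-bias criterion.
#'
#' @param n_endog number of endogenous regressors (1 or 2)
#' @param n_instruments number of excluded instruments (1-8)
#' @param criterion one of `bias_5, bias_10, bias_20, bias_30, size_10,
#'   size_15, size_20, size_25`
#' @return the tabulated critical value
#' @export
stock_yogo_lookup <- function(n_endog, n_instruments,
                              criterion = "bias_5") {
  tab <- load_stock_yogo()
  hit <- tab$n_endog == n_endog & tab$n_instruments == n_instruments &
    tab$criterion == criterion
  if (!any(hit)) {
    avail <- unique(paste0("(n_endog=", tab$n_endog, ", n_instruments=",
                           tab$n_instruments, ", ", tab$criterion, ")"))
    stop("no Stock-Yogo critical value for (n_endog=", n_endog,
         ", n_instruments=", n_instruments, ", ", criterion,
         "); available keys:\n", paste(avail, collapse = " "),
         call. = FALSE)
  }
  tab$critical_value[hit][1L]
}

#' Instrument diagnostics for the differenced IV system
#'
#' Reports the pooled first-stage R-squared of adult BMI on the four
#' childhood instruments, the Cragg-Donald F of the differenced first stage
#' (endogenous: differenced BMI; instruments: the childhood variables;
#' included exogenous: intercept and differenced covariates), the matching
#' Stock-Yogo critical value, and the Sargan test from the linear
#' first-differenced 2SLS fit.
#'
#' @param data a [panel_dataset()]
#' @param instruments an [instrument_table()]
#' @param sy_criterion criterion passed to [stock_yogo_lookup()]
#' @return object of class `instrument_diagnostics`
#' @export
instrument_diagnostics <- function(data, instruments,
                                   sy_criterion = "bias_5") {
  stopifnot(inherits(data, "panel_dataset"))
  data <- balance_panel(data)
  r <- data$records
  zi <- instruments[match(r$id, instruments$id), , drop = FALSE]
  zmat <- as.matrix(zi[, c("birth_weight", "bmi_age10", "mother_bmi",
                           "father_bmi")])
  fs <- stats::lm.fit(cbind(1, zmat), r$bmi)
  first_stage_r2 <- 1 - sum(fs$residuals^2) /
    sum((r$bmi - mean(r$bmi))^2)

  rows <- first_difference(data)
  d <- fd_design(rows, instruments, quiet = TRUE)
  zfd <- instruments[match(rows$id, instruments$id), , drop = FALSE]
  zmat_fd <- as.matrix(zfd[, c("birth_weight", "bmi_age10", "mother_bmi",
                               "father_bmi")])
  cd <- cragg_donald(d$dq, zmat_fd, exog = d$X0[, -1L, drop = FALSE])
  sy <- stock_yogo_lookup(1L, ncol(zmat_fd), sy_criterion)
  iv <- fit_fd_iv(rows, instruments)
  sg <- sargan_test(iv)
  structure(list(first_stage_r2 = first_stage_r2,
                 cragg_donald_F = cd, stock_yogo_critical = sy,
                 sy_criterion = sy_criterion,
                 sargan_stat = sg$statistic, sargan_df = sg$df,
                 sargan_p = sg$p_value, n_individuals = nrow(rows)),
            class = "instrument_diagnostics")
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat("Instrument diagnostics (n =", x$n_individuals, "individuals)\n")
  cat("  first-stage R^2 (BMI levels on childhood instruments):",
      format(round(x$first_stage_r2, 4)), "\n")
  cat("  Cragg-Donald F (differenced first stage):",
      format(round(x$cragg_donald_F, 2)), " vs Stock-Yogo",
      x$sy_criterion, "critical value", format(x$stock_yogo_critical), "\n")
  cat("  Sargan: stat =", format(round(x$sargan_stat, 3)), "on",
      x$sargan_df, "df, p =", format(round(x$sargan_p, 4)), "\n")
  invisible(x)
}
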