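#' Pooled OLS benchmark
#'
#' Least-squares fit of weekly hours on an intercept, the covariates and
#' BMI over all records pooled, i.e. the linear model with the slope-change
#' restriction `delta = 0`. Conventional homoskedastic standard errors by
#' default; `cluster = TRUE` switches to cluster-robust (by individual)
#' standard errors, off by default to mirror the usual pooled presentation.
#'
#' @param data a [panel_dataset()]
#' @param cluster cluster SEs by individual?
#' @return object of class `linear_fit`
#' @export
fit_pooled_ols <- function(data, cluster = FALSE) {
  stopifnot(inherits(data, "panel_dataset"))
  r <- data$records
  X <- cbind(`(Intercept)` = 1,
             as.matrix(r[, data$covariates, drop = FALSE]),
             bmi = r$bmi)
  y <- r$hours
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2L) stop("need at least two more records than parameters",
                       call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("collinear design; dependent column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  res <- y - as.numeric(X %*% beta)
  XtXinv <- chol2inv(qr.R(qx))
  if (cluster) {
    ids <- r$id
    meat <- matrix(0, p, p)
    Xu <- X * res
    for (g in split(seq_len(n), ids)) {
      sg <- colSums(Xu[g, , drop = FALSE])
      meat <- meat + tcrossprod(sg)
    }
    G <- length(unique(ids))
    V <- XtXinv %*% meat %*% XtXinv * (G / (G - 1)) * ((n - 1) / (n - p))
  } else {
    sigma2 <- sum(res^2) / (n - p)
    V <- XtXinv * sigma2
  }
  se <- sqrt(diag(V))
  names(se) <- names(beta) <- colnames(X)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(coefficients = beta, se = se, r_squared = r2,
                 estimator = "pooled_ols", n_obs = n,
                 residuals = res, clustered = cluster),
            class = "linear_fit")
}

#' Fixed-effects (within) benchmark
#'
#' Individual-demeaned least squares on the balanced two-period panel. With
#' two periods the slope estimates coincide exactly with least squares on
#' first differences. Regressors with no within-individual variation (age,
#' or a time-constant residence indicator) are dropped with a message; the
#' reported R-squared is the within R-squared. The error variance uses the
#' within degrees of freedom `n_obs - N - k`.
#'
#' @param data a [panel_dataset()]
#' @return object of class `linear_fit`
#' @export
fit_fixed_effects <- function(data) {
  stopifnot(inherits(data, "panel_dataset"))
  data <- balance_panel(data)
  r <- data$records
  r <- r[order(r$id, r$period), , drop = FALSE]
  vars <- c("hours", data$covariates, "bmi")
  demean <- function(v) v - stats::ave(v, r$id)
  dm <- as.data.frame(lapply(r[, vars, drop = FALSE], demean))
  regs <- c(data$covariates, "bmi")
  within_var <- vapply(dm[, regs, drop = FALSE], stats::var, numeric(1))
  keep <- within_var > 1e-12
  if (any(!keep)) {
    message("fit_fixed_effects: dropping time-invariant regressor(s): ",
            paste(regs[!keep], collapse = ", "))
  }
  regs <- regs[keep]
  if (length(regs) == 0L) {
    stop("no regressor varies within individuals", call. = FALSE)
  }
  X <- as.matrix(dm[, regs, drop = FALSE])
  y <- dm$hours
  n <- nrow(X); N <- length(unique(r$id)); k <- ncol(X)
  qx <- qr(X)
  if (qx$rank < k) {
    bad <- regs[qx$pivot[-seq_len(qx$rank)]]
    stop("collinear within-transformed design; dependent column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  res <- y - as.numeric(X %*% beta)
  sigma2 <- sum(res^2) / (n - N - k)
  V <- chol2inv(qr.R(qx)) * sigma2
  se <- sqrt(diag(V))
  names(se) <- names(beta) <- regs
  r2 <- 1 - sum(res^2) / sum(y^2)  # y already demeaned
  structure(list(coefficients = beta, se = se, r_squared = r2,
                 estimator = "fixed_effects", n_obs = n,
                 n_individuals = N, residuals = res,
                 dropped = setdiff(c(data$covariates, "bmi"), regs)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear benchmark (", x$estimator, ")\n", sep = "")
  print(round(data.frame(estimate = x$coefficients, se = x$se), 4))
  cat("R-squared", if (x$estimator == "fixed_effects") " (within)",
      ": ", format(round(x$r_squared, 4)), "; n = ", x$n_obs, "\n", sep = "")
  invisible(x)
}
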