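#' Effect size in standard-deviation units
#'
#' Expresses a total effect on weekly hours as a percentage of the outcome
#' standard deviation; e.g. an above-threshold total BMI effect of -2.432
#' against an hours SD of 11.684 is about -21 percent of a standard
#' deviation.
#'
#' @param total_effect effect in outcome units (hours)
#' @param outcome_sd standard deviation of the outcome (> 0)
#' @return the effect as a percent of one SD
#' @export
effect_size_sd <- function(total_effect, outcome_sd) {
  if (!is.numeric(outcome_sd) || any(outcome_sd <= 0)) {
    stop("outcome_sd must be positive", call. = FALSE)
  }
  100 * total_effect / outcome_sd
}

#' Significance stars
#'
#' `***` p < 0.001, `**` p < 0.05, `*` p < 0.1 (the thresholds used in the
#' study's tables).
#' @param p numeric vector of p-values
#' @return character vector of stars
#' @export
significance_stars <- function(p) {
  out <- ifelse(is.na(p), "",
                ifelse(p < 0.001, "***",
                       ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", ""))))
  out
}

two_sided_p <- function(est, se) {
  ifelse(is.na(se) | se <= 0, NA_real_, 2 * stats::pnorm(-abs(est / se)))
}

#' Summary statistics by gender and period
#'
#' Mean and SD of hours, BMI and each covariate per gender x period, plus
#' the time-invariant childhood instruments per gender. Groups with a
#' single record report SD as NA (undefined), not zero.
#'
#' @param data a [panel_dataset()]
#' @param instruments optional [instrument_table()] for the childhood block
#' @return data.frame with columns `gender, period, variable, mean, sd, n`
#' @export
summary_statistics <- function(data, instruments = NULL) {
  stopifnot(inherits(data, "panel_dataset"))
  r <- data$records
  vars <- c("hours", "bmi", data$covariates)
  out <- list()
  for (g in sort(unique(r$gender))) {
    for (p in sort(unique(r$period))) {
      sub <- r[r$gender == g & r$period == p, , drop = FALSE]
      if (nrow(sub) == 0L) next
      for (v in vars) {
        x <- sub[[v]]
        out[[length(out) + 1L]] <- data.frame(
          gender = g, period = p, variable = v, mean = mean(x),
          sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
          n = length(x))
      }
    }
    if (!is.null(instruments)) {
      ids_g <- unique(r$id[r$gender == g])
      zi <- instruments[instruments$id %in% ids_g, , drop = FALSE]
      for (v in c("birth_weight", "bmi_age10", "mother_bmi", "father_bmi")) {
        x <- zi[[v]]
        out[[length(out) + 1L]] <- data.frame(
          gender = g, period = NA_integer_, variable = v, mean = mean(x),
          sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
          n = length(x))
      }
    }
  }
  do.call(rbind, out)
}

threshold_row <- function(fit, label, n_label = NULL) {
  p_alpha <- two_sided_p(fit$alpha, fit$se[["d_bmi"]])
  p_delta <- two_sided_p(fit$delta, fit$se[["kink"]])
  p_gamma <- two_sided_p(fit$gamma, fit$se[["gamma"]])
  data.frame(
    group = label,
    alpha = fit$alpha, alpha_se = fit$se[["d_bmi"]],
    alpha_stars = significance_stars(p_alpha),
    delta = fit$delta, delta_se = fit$se[["kink"]],
    delta_stars = significance_stars(p_delta),
    gamma = fit$gamma, gamma_se = fit$se[["gamma"]],
    gamma_stars = significance_stars(p_gamma),
    n = if (is.null(n_label)) fit$n_used else n_label,
    status = "ok", stringsAsFactors = FALSE)
}

failed_row <- function(label, reason) {
  data.frame(group = label, alpha = NA_real_, alpha_se = NA_real_,
             alpha_stars = "", delta = NA_real_, delta_se = NA_real_,
             delta_stars = "", gamma = NA_real_, gamma_se = NA_real_,
             gamma_stars = "", n = NA_integer_, status = reason,
             stringsAsFactors = FALSE)
}

#' Threshold estimates across trim rates
#'
#' Refits the kink-threshold model with each requested total trim fraction
#' and arranges the results as a sensitivity panel (one column per rate). A
#' rate whose trimmed grid is empty or degenerate is reported as failed
#' with its reason rather than aborting the panel.
#'
#' @param data a [panel_dataset()] or [first_difference()] rows
#' @param instruments an [instrument_table()]
#' @param rates numeric vector of total trim fractions (default 0.2/0.3/0.4)
#' @param spec base [gmm_spec()]; its `trim_rate` is overridden per column
#' @return list with `table` (data.frame, one row per rate) and `fits`
#' @export
trim_sensitivity <- function(data, instruments, rates = c(0.2, 0.3, 0.4),
                             spec = gmm_spec()) {
  rows <- if (inherits(data, "panel_dataset")) first_difference(data)
          else data
  fits <- list()
  tab <- list()
  for (rate in rates) {
    sp <- spec
    sp$trim_rate <- rate
    res <- tryCatch(
      suppressMessages(fit_panel_threshold(rows, instruments, sp)),
      error = function(e) e)
    lab <- paste0("trim_", format(rate))
    if (inherits(res, "error")) {
      tab[[lab]] <- failed_row(lab, conditionMessage(res))
    } else {
      fits[[lab]] <- res
      tab[[lab]] <- threshold_row(res, lab)
    }
  }
  tab <- do.call(rbind, tab)
  tab$trim_rate <- rates
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Subgroup threshold analysis
#'
#' Refits the full threshold estimator within each level of a
#' period-agnostic grouping label (skill or gender), plus the pooled group.
#' Skill membership is taken from the period-1 (age 34) label by default.
#' Subgroups too small to estimate are skipped with a warning.
#'
#' @param data a [panel_dataset()]
#' @param instruments an [instrument_table()]
#' @param split "skill" or "gender"
#' @param spec a [gmm_spec()]
#' @param period_rule which period defines a time-varying label:
#'   "period1" (default), "period2" or "either" (high if high in either)
#' @return list with `table` (pooled + one row per level) and `fits`
#' @export
subgroup_analysis <- function(data, instruments,
                              split = c("skill", "gender"),
                              spec = gmm_spec(),
                              period_rule = c("period1", "period2",
                                              "either")) {
  split <- match.arg(split)
  period_rule <- match.arg(period_rule)
  stopifnot(inherits(data, "panel_dataset"))
  data <- balance_panel(data)
  r <- data$records
  lab <- r[[split]]
  base_period <- switch(period_rule, period1 = 1L, period2 = 2L, NA_integer_)
  if (split == "skill" && period_rule == "either") {
    high <- tapply(lab == "high", r$id, any)
    membership <- ifelse(high[unique(r$id)], "high", "low")
    names(membership) <- unique(r$id)
  } else if (split == "skill") {
    sel <- r$period == base_period
    membership <- stats::setNames(lab[sel], r$id[sel])
  } else {
    sel <- r$period == 1L
    membership <- stats::setNames(lab[sel], r$id[sel])
  }
  levels_ <- sort(unique(membership))
  groups <- c(list(all = unique(r$id)),
              stats::setNames(lapply(levels_, function(l)
                names(membership)[membership == l]), levels_))
  fits <- list()
  tab <- list()
  min_n <- ncol_needed <- length(data$covariates) + 7L
  for (gname in names(groups)) {
    ids <- groups[[gname]]
    if (length(ids) < min_n) {
      warning("subgroup '", gname, "' skipped: ", length(ids),
              " individuals < ", min_n, " required", call. = FALSE)
      tab[[gname]] <- failed_row(gname, "skipped: too few individuals")
      next
    }
    sub <- panel_dataset(r[r$id %in% ids, , drop = FALSE], data$covariates)
    res <- tryCatch(
      suppressMessages(fit_panel_threshold(sub, instruments, spec)),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("subgroup '", gname, "' failed: ", conditionMessage(res),
              call. = FALSE)
      tab[[gname]] <- failed_row(gname, conditionMessage(res))
    } else {
      fits[[gname]] <- res
      tab[[gname]] <- threshold_row(res, gname)
    }
  }
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL
  list(table = tab, fits = fits, split = split, period_rule = period_rule)
}

#' Analysis configuration
#'
#' One object naming the data source (CSV paths or simulation configs), the
#' estimator settings and the report plan for [run_analysis()].
#'
#' @param panel_path,instruments_path CSV inputs (see [read_panel_csv()])
#' @param covariates covariate column names for the CSV reader
#' @param sim named list of [sim_config()]s (one per arm) used when no CSV
#'   paths are given
#' @param trim_rates trim fractions for the sensitivity panel
#' @param spec a [gmm_spec()]
#' @param skill_split run the skill subgroup panel?
#' @param period_rule subgroup membership rule (see [subgroup_analysis()])
#' @param output_dir optional directory for JSON/text reports
#' @param seed integer seed governing every random element of the run
#' @return list of class `analysis_config`
#' @export
analysis_config <- function(panel_path = NULL, instruments_path = NULL,
                            covariates = c("degree", "famsize", "skill_ind",
                                           "england", "age"),
                            sim = NULL, trim_rates = c(0.2, 0.3, 0.4),
                            spec = gmm_spec(), skill_split = TRUE,
                            period_rule = "period1",
                            output_dir = NULL, seed = 1L) {
  if (is.null(sim) && (is.null(panel_path) || is.null(instruments_path))) {
    stop("need either CSV paths or simulation config(s)", call. = FALSE)
  }
  if (any(trim_rates <= 0 | trim_rates >= 1)) {
    stop("trim rates must lie in (0, 1)", call. = FALSE)
  }
  structure(list(panel_path = panel_path,
                 instruments_path = instruments_path,
                 covariates = covariates, sim = sim,
                 trim_rates = trim_rates, spec = spec,
                 skill_split = skill_split, period_rule = period_rule,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

load_or_simulate <- function(config) {
  if (!is.null(config$panel_path)) {
    data <- read_panel_csv(config$panel_path, config$covariates)
    inst <- read_instruments_csv(config$instruments_path)
    return(list(data = data, instruments = inst, truth = NULL))
  }
  sims <- config$sim
  if (inherits(sims, "sim_config")) sims <- list(arm = sims)
  parts <- lapply(names(sims), function(nm) {
    out <- simulate_panel(sims[[nm]])
    out$data$records$id <- paste0(nm, "_", out$data$records$id)
    out$instruments$id <- paste0(nm, "_", out$instruments$id)
    out
  })
  rec <- do.call(rbind, lapply(parts, function(p) p$data$records))
  inst <- do.call(rbind, lapply(parts, function(p)
    as.data.frame(p$instruments)))
  covs <- parts[[1L]]$data$covariates
  list(data = panel_dataset(rec, covs), instruments = instrument_table(inst),
       truth = lapply(parts, function(p) p$truth))
}

#' Run the full desk-scale analysis
#'
#' Orchestrates the study pipeline: sample filters, summary statistics, the
#' three-estimator comparison (pooled OLS, fixed effects, panel threshold)
#' per gender, instrument diagnostics, trim-rate sensitivity, optional
#' skill subgroups, and SD-standardized effect sizes. Deterministic given
#' the config and seed; when `output_dir` is set, JSON and text reports plus
#' a manifest are written there.
#'
#' @param config an [analysis_config()]
#' @return a `report_bundle` list
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  set.seed(config$seed)
  src <- load_or_simulate(config)
  filt <- apply_sample_filters(src$data)
  data <- filt$data
  inst <- src$instruments
  summary_table <- summary_statistics(data, inst)

  genders <- sort(unique(data$records$gender))
  estimators <- list(); diagnostics <- list(); sensitivity <- list()
  subgroups <- list(); effects <- list(); fits <- list()
  for (g in genders) {
    ids_g <- unique(data$records$id[data$records$gender == g])
    sub <- panel_dataset(
      data$records[data$records$id %in% ids_g, , drop = FALSE],
      data$covariates)
    n_par <- length(data$covariates) + 7L
    if (length(ids_g) < n_par) {
      warning("gender group '", g, "' skipped: too few individuals",
              call. = FALSE)
      next
    }
    ols <- suppressMessages(fit_pooled_ols(sub))
    fe <- suppressMessages(fit_fixed_effects(sub))
    thr <- suppressMessages(fit_panel_threshold(sub, inst, config$spec))
    fits[[g]] <- list(pooled_ols = ols, fixed_effects = fe, threshold = thr)
    lin_row <- function(fit, label) {
      p <- two_sided_p(fit$coefficients[["bmi"]], fit$se[["bmi"]])
      data.frame(gender = g, estimator = label,
                 alpha = fit$coefficients[["bmi"]],
                 alpha_se = fit$se[["bmi"]],
                 alpha_stars = significance_stars(p),
                 delta = NA_real_, delta_se = NA_real_, delta_stars = "",
                 gamma = NA_real_, gamma_se = NA_real_, gamma_stars = "",
                 r_squared = fit$r_squared, n = fit$n_obs,
                 stringsAsFactors = FALSE)
    }
    thr_row <- threshold_row(thr, "panel_threshold", n_label = 2L * thr$n_used)
    thr_row <- data.frame(gender = g, estimator = "panel_threshold",
                          thr_row[, c("alpha", "alpha_se", "alpha_stars",
                                      "delta", "delta_se", "delta_stars",
                                      "gamma", "gamma_se", "gamma_stars")],
                          r_squared = NA_real_, n = thr_row$n,
                          stringsAsFactors = FALSE)
    estimators[[g]] <- rbind(lin_row(ols, "pooled_ols"),
                             lin_row(fe, "fixed_effects"), thr_row)
    diagnostics[[g]] <- instrument_diagnostics(sub, inst)
    sens <- trim_sensitivity(sub, inst, config$trim_rates, config$spec)
    sens$table <- cbind(gender = g, sens$table)
    sensitivity[[g]] <- sens
    if (isTRUE(config$skill_split)) {
      sg <- suppressWarnings(subgroup_analysis(
        sub, inst, split = "skill", spec = config$spec,
        period_rule = config$period_rule))
      sg$table <- cbind(gender = g, sg$table)
      subgroups[[g]] <- sg
    }
    sd_hours <- stats::sd(sub$records$hours)
    total_above <- thr$regime_slopes[["above"]]
    effects[[g]] <- data.frame(
      gender = g, slope_below = thr$regime_slopes[["below"]],
      slope_above = total_above, hours_sd = sd_hours,
      effect_pct_sd = effect_size_sd(total_above, sd_hours),
      stringsAsFactors = FALSE)
  }
  bundle <- structure(list(
    summary_table = summary_table,
    estimator_table = do.call(rbind, estimators),
    sensitivity = lapply(sensitivity, `[[`, "table"),
    subgroups = lapply(subgroups, `[[`, "table"),
    effect_sizes = do.call(rbind, effects),
    diagnostics = diagnostics,
    filter_audit = filt$audit,
    fits = fits, truth = src$truth, config = config),
    class = "report_bundle")
  if (!is.null(config$output_dir)) write_report_bundle(bundle, config)
  bundle
}

report_json <- function(x) {
  jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE, digits = NA,
                   na = "null", pretty = TRUE, force = TRUE)
}

format_text_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 4))
  paste(utils::capture.output(print.data.frame(df, row.names = FALSE)),
        collapse = "\n")
}

#' Write the report bundle to disk
#'
#' Emits `summary`, `estimators`, `sensitivity`, `subgroups`,
#' `effect_sizes` and `diagnostics` as both JSON and plain-text tables,
#' plus `manifest.json` recording the package version, seed, filter audit
#' and subgroup conventions. Output is byte-identical across reruns with
#' the same config and seed.
#'
#' @param bundle a `report_bundle`
#' @param config the [analysis_config()] that produced it
#' @return the output directory, invisibly
#' @export
write_report_bundle <- function(bundle, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  emit <- function(obj, name) {
    writeLines(report_json(obj), out(paste0(name, ".json")))
    txt <- if (is.data.frame(obj)) format_text_table(obj)
           else paste(vapply(names(obj), function(nm)
             paste0("## ", nm, "\n",
                    format_text_table(as.data.frame(obj[[nm]]))),
             character(1)), collapse = "\n\n")
    writeLines(txt, out(paste0(name, ".txt")))
  }
  emit(bundle$summary_table, "summary")
  emit(bundle$estimator_table, "estimators")
  emit(do.call(rbind, unname(bundle$sensitivity)), "sensitivity")
  if (length(bundle$subgroups) > 0L) {
    emit(do.call(rbind, unname(bundle$subgroups)), "subgroups")
  }
  emit(bundle$effect_sizes, "effect_sizes")
  diag_df <- do.call(rbind, lapply(names(bundle$diagnostics), function(g) {
    d <- bundle$diagnostics[[g]]
    data.frame(gender = g, first_stage_r2 = d$first_stage_r2,
               cragg_donald_F = d$cragg_donald_F,
               stock_yogo_critical = d$stock_yogo_critical,
               sargan_stat = d$sargan_stat, sargan_df = d$sargan_df,
               sargan_p = d$sargan_p, stringsAsFactors = FALSE)
  }))
  emit(diag_df, "diagnostics")
  manifest <- list(
    package = "panelkink",
    version = as.character(utils::packageVersion("panelkink")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    trim_rates = config$trim_rates,
    subgroup_period_rule = config$period_rule,
    weighting = config$spec$weighting,
    se_method = config$spec$se_method,
    filter_audit = as.data.frame(bundle$filter_audit))
  writeLines(report_json(manifest), out("manifest.json"))
  invisible(config$output_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Analysis report bundle\n")
  print(x$filter_audit)
  cat("\nEstimator comparison:\n")
  print(round_df(x$estimator_table))
  cat("\nEffect sizes (percent of an hours SD):\n")
  print(round_df(x$effect_sizes))
  invisible(x)
}

round_df <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}
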