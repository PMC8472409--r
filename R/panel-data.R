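#' Two-period panel dataset
#'
#' Container for a long-format two-period panel: one record per individual
#' per period, with weekly work hours as the outcome, BMI (kg/m^2) as the
#' threshold variable, a fixed set of time-varying covariates, and the
#' grouping labels used by the sample filters and subgroup analyses.
#'
#' @param records data.frame with columns `id`, `period` (1 or 2), `hours`,
#'   `bmi`, one column per entry of `covariates`, and the label columns
#'   `gender` ("female"/"male"), `skill` ("high"/"low"), `employment_status`
#'   ("employee"/"self_employed"/"not_working") and `pregnant` (logical).
#'   Missing label columns are filled with neutral defaults (all-employee,
#'   not pregnant) with a message.
#' @param covariates character vector naming the covariate columns, in order.
#'
#' @return An object of class `panel_dataset`: a list with elements
#'   `records` (the validated data.frame) and `covariates`.
#'
#' @details Invariants enforced: each individual appears at most once per
#'   period; `period` takes only the values 1 and 2; `bmi` is finite and
#'   positive; `hours` is finite. Non-negativity of hours is checked where
#'   observed data enter ([read_panel_csv()]); the constructor accepts any
#'   finite value so that unbounded synthetic draws remain representable,
#'   and the sample filters enforce the 10-70 analysis window.
#' @export
panel_dataset <- function(records, covariates = character(0)) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records)
  needed <- c("id", "period", "hours", "bmi", covariates)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("panel records are missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  defaults <- list(gender = "female", skill = "low",
                   employment_status = "employee", pregnant = FALSE)
  filled <- setdiff(names(defaults), names(records))
  if (length(filled) > 0L) {
    message("panel_dataset: filling absent label column(s) with defaults: ",
            paste(filled, collapse = ", "))
    for (nm in filled) records[[nm]] <- defaults[[nm]]
  }
  if (!all(records$period %in% c(1L, 2L))) {
    stop("period must take only the values 1 and 2", call. = FALSE)
  }
  records$period <- as.integer(records$period)
  if (anyDuplicated(records[, c("id", "period")])) {
    dup <- records$id[duplicated(records[, c("id", "period")])]
    stop("duplicated (id, period) pair(s), e.g. id ", dup[1L], call. = FALSE)
  }
  num_cols <- c("hours", "bmi", covariates)
  for (nm in num_cols) {
    if (!is.numeric(records[[nm]])) {
      stop("column '", nm, "' must be numeric", call. = FALSE)
    }
  }
  if (!all(is.finite(records$bmi)) || any(records$bmi <= 0)) {
    stop("bmi must be finite and positive for every record", call. = FALSE)
  }
  if (!all(is.finite(records$hours))) {
    stop("hours must be finite for every record", call. = FALSE)
  }
  records$pregnant <- as.logical(records$pregnant)
  structure(list(records = records, covariates = covariates),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  r <- x$records
  cat("Two-period panel: ", length(unique(r$id)), " individuals, ",
      nrow(r), " records\n", sep = "")
  cat("Covariates: ", paste(x$covariates, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Identifiers of individuals observed in both periods
#' @param data a `panel_dataset`
#' @return vector of ids present in period 1 and period 2
#' @export
balanced_ids <- function(data) {
  r <- data$records
  intersect(unique(r$id[r$period == 1L]), unique(r$id[r$period == 2L]))
}

#' Restrict a panel to its balanced view
#'
#' Keeps only individuals observed in both periods; all estimators operate
#' on this view.
#' @param data a `panel_dataset`
#' @return a `panel_dataset` containing only balanced individuals
#' @export
balance_panel <- function(data) {
  keep <- data$records$id %in% balanced_ids(data)
  panel_dataset(data$records[keep, , drop = FALSE], data$covariates)
}

#' Kink (continuous-threshold) transform
#'
#' Computes `(q - gamma) * 1{q >= gamma}`, the excess of the threshold
#' variable over the threshold. The transform is continuous and piecewise
#' linear in both arguments, so the regression function changes slope at
#' `gamma` without a jump.
#'
#' @param q numeric vector, threshold-variable values (BMI).
#' @param gamma numeric scalar or vector (recycled), the threshold.
#' @return `pmax(q - gamma, 0)`, non-negative.
#' @examples
#' kink_transform(32, 30)  # 2
#' kink_transform(28, 30)  # 0
#' @export
kink_transform <- function(q, gamma) {
  if (!is.numeric(q) || !is.numeric(gamma) ||
      !all(is.finite(q)) || !all(is.finite(gamma))) {
    stop("kink_transform: q and gamma must be finite numeric", call. = FALSE)
  }
  pmax(q - gamma, 0)
}

#' First-difference a two-period panel
#'
#' Transforms the balanced panel into one row per individual holding the
#' period-2 minus period-1 differences of the outcome, the threshold
#' variable and the covariates. The period BMI levels are carried through
#' because the differenced kink term must be re-evaluated at every candidate
#' threshold. First differencing removes the individual fixed effect.
#'
#' @param data a `panel_dataset` (unbalanced individuals are dropped with a
#'   message).
#' @return data.frame with columns `id`, `d_hours`, `d_bmi`,
#'   `d_<covariate>` for each covariate, `bmi_1`, `bmi_2`, plus the
#'   period-1 labels `gender` and `skill`; attribute `covariates` names the
#'   differenced covariate columns.
#' @export
first_difference <- function(data) {
  stopifnot(inherits(data, "panel_dataset"))
  r <- data$records
  ids <- balanced_ids(data)
  n_drop <- length(unique(r$id)) - length(ids)
  if (n_drop > 0L) {
    message("first_difference: dropping ", n_drop,
            " individual(s) not observed in both periods")
  }
  r <- r[r$id %in% ids, , drop = FALSE]
  p1 <- r[r$period == 1L, , drop = FALSE]
  p2 <- r[r$period == 2L, , drop = FALSE]
  p1 <- p1[order(p1$id), , drop = FALSE]
  p2 <- p2[order(p2$id), , drop = FALSE]
  stopifnot(identical(p1$id, p2$id))
  out <- data.frame(id = p1$id,
                    d_hours = p2$hours - p1$hours,
                    d_bmi = p2$bmi - p1$bmi,
                    stringsAsFactors = FALSE)
  for (nm in data$covariates) {
    out[[paste0("d_", nm)]] <- p2[[nm]] - p1[[nm]]
  }
  out$bmi_1 <- p1$bmi
  out$bmi_2 <- p2$bmi
  out$gender <- p1$gender
  out$skill <- p1$skill
  attr(out, "covariates") <- data$covariates
  out
}

#' Apply the study's sample-selection rules
#'
#' Applies, in order: (0) keep individuals observed in both periods with
#' complete numeric fields; (1) keep individuals working in both periods and
#' not self-employed in period 1; (2) drop women pregnant in either period;
#' (3) keep individuals whose weekly hours lie in \[10, 70\] (inclusive) in
#' both periods. All rules operate per individual so the panel stays
#' balanced: one offending period removes both records.
#'
#' @param data a `panel_dataset`
#' @return list with elements `data` (the filtered `panel_dataset`) and
#'   `audit` (a `filter_audit` data.frame with columns `rule`, `n_before`,
#'   `n_excluded`, `n_after`, counted in individuals).
#' @export
apply_sample_filters <- function(data) {
  stopifnot(inherits(data, "panel_dataset"))
  r <- data$records
  audit <- list()
  n_ind <- function(recs) length(unique(recs$id))

  # step 0: balanced with complete numeric fields
  n0 <- n_ind(r)
  num_cols <- c("hours", "bmi", data$covariates)
  complete <- stats::complete.cases(r[, num_cols, drop = FALSE])
  bad_ids <- unique(r$id[!complete])
  r <- r[!(r$id %in% bad_ids), , drop = FALSE]
  bal <- intersect(unique(r$id[r$period == 1L]), unique(r$id[r$period == 2L]))
  r <- r[r$id %in% bal, , drop = FALSE]
  audit[[1L]] <- data.frame(rule = "complete_balanced", n_before = n0,
                            n_excluded = n0 - n_ind(r), n_after = n_ind(r))

  # step 1: working both periods, not self-employed in period 1
  n1 <- n_ind(r)
  working <- r$employment_status %in% c("employee", "self_employed")
  work_ok <- tapply(working, r$id, all)
  se_p1 <- tapply(r$employment_status == "self_employed" & r$period == 1L,
                  r$id, any)
  keep_ids <- names(work_ok)[work_ok & !se_p1]
  r <- r[r$id %in% keep_ids, , drop = FALSE]
  audit[[2L]] <- data.frame(rule = "working_both_periods_not_self_employed",
                            n_before = n1, n_excluded = n1 - n_ind(r),
                            n_after = n_ind(r))

  # step 2: women pregnant in either survey year
  n2 <- n_ind(r)
  preg <- tapply(r$gender == "female" & r$pregnant, r$id, any)
  keep_ids <- names(preg)[!preg]
  r <- r[r$id %in% keep_ids, , drop = FALSE]
  audit[[3L]] <- data.frame(rule = "pregnancy_exclusion", n_before = n2,
                            n_excluded = n2 - n_ind(r), n_after = n_ind(r))

  # step 3: 10 <= hours <= 70 in both periods (inclusive bounds)
  n3 <- n_ind(r)
  in_range <- r$hours >= 10 & r$hours <= 70
  range_ok <- tapply(in_range, r$id, all)
  keep_ids <- names(range_ok)[range_ok]
  r <- r[r$id %in% keep_ids, , drop = FALSE]
  audit[[4L]] <- data.frame(rule = "hours_10_to_70", n_before = n3,
                            n_excluded = n3 - n_ind(r), n_after = n_ind(r))

  audit <- do.call(rbind, audit)
  class(audit) <- c("filter_audit", "data.frame")
  list(data = panel_dataset(r, data$covariates), audit = audit)
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("Sample-selection audit (individuals):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# ---- CSV input/output -------------------------------------------------------

parse_numeric_col <- function(x, name) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L) {
    stop("non-numeric value '", x[bad[1L]], "' in column '", name,
         "' at data row ", bad[1L], call. = FALSE)
  }
  out
}

parse_logical_col <- function(x, name) {
  x <- toupper(trimws(x))
  x[x == ""] <- NA_character_
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1")] <- TRUE
  out[x %in% c("FALSE", "F", "0")] <- FALSE
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L) {
    stop("non-logical value in column '", name, "' at data row ", bad[1L],
         call. = FALSE)
  }
  out
}

#' Read a panel CSV
#'
#' Expects columns `id, period, hours, bmi`, the covariate columns named in
#' `covariates`, and `gender, skill, employment_status, pregnant`. Columns
#' not in that set are ignored with a warning; to treat an extra column as a
#' covariate, list it in `covariates`. Rows with missing numeric fields are
#' kept (the filters drop incomplete individuals with an audited count).
#'
#' @param path file path
#' @param covariates character vector of covariate column names
#' @return a `panel_dataset`
#' @export
read_panel_csv <- function(path, covariates = character(0)) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  needed <- c("id", "period", "hours", "bmi", covariates,
              "gender", "skill", "employment_status", "pregnant")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("panel CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), needed)
  if (length(extra) > 0L) {
    warning("ignoring unmapped column(s): ", paste(extra, collapse = ", "),
            "; list them in `covariates` to keep them", call. = FALSE)
  }
  rec <- data.frame(id = raw$id,
                    period = as.integer(parse_numeric_col(raw$period, "period")),
                    hours = parse_numeric_col(raw$hours, "hours"),
                    bmi = parse_numeric_col(raw$bmi, "bmi"),
                    stringsAsFactors = FALSE)
  for (nm in covariates) rec[[nm]] <- parse_numeric_col(raw[[nm]], nm)
  rec$gender <- raw$gender
  rec$skill <- raw$skill
  rec$employment_status <- raw$employment_status
  rec$pregnant <- parse_logical_col(raw$pregnant, "pregnant")
  if (any(rec$hours < 0, na.rm = TRUE)) {
    warning("panel CSV contains negative hours", call. = FALSE)
  }
  panel_dataset(rec, covariates)
}

#' Write a panel CSV
#' @param data a `panel_dataset`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_panel_csv <- function(data, path) {
  stopifnot(inherits(data, "panel_dataset"))
  cols <- c("id", "period", "hours", "bmi", data$covariates,
            "gender", "skill", "employment_status", "pregnant")
  r <- data$records[order(data$records$id, data$records$period),
                    cols, drop = FALSE]
  utils::write.csv(r, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Time-invariant childhood instrument table
#'
#' One row per individual: birth weight (kg) and the BMI (kg/m^2) of the
#' individual, mother and father measured when the respondent was ten years
#' old. These serve as excluded instruments for adult BMI.
#'
#' @param df data.frame with columns `id, birth_weight, bmi_age10,
#'   mother_bmi, father_bmi`
#' @return validated data.frame of class `instrument_table`
#' @export
instrument_table <- function(df) {
  needed <- c("id", "birth_weight", "bmi_age10", "mother_bmi", "father_bmi")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("instrument table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("instrument table must have one row per individual", call. = FALSE)
  }
  vals <- as.matrix(df[, needed[-1L], drop = FALSE])
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("instrument values must be finite and positive", call. = FALSE)
  }
  df <- as.data.frame(df[, needed, drop = FALSE])
  class(df) <- c("instrument_table", "data.frame")
  df
}

#' Read / write the instrument CSV
#' @param path file path
#' @return `read_instruments_csv`: an `instrument_table`.
#' @export
read_instruments_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  needed <- c("id", "birth_weight", "bmi_age10", "mother_bmi", "father_bmi")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("instrument CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(id = raw$id, stringsAsFactors = FALSE)
  for (nm in needed[-1L]) df[[nm]] <- parse_numeric_col(raw[[nm]], nm)
  instrument_table(df)
}

#' @rdname read_instruments_csv
#' @param tab an `instrument_table`
#' @export
write_instruments_csv <- function(tab, path) {
  stopifnot(inherits(tab, "instrument_table"))
  utils::write.csv(as.data.frame(tab)[order(tab$id), , drop = FALSE],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
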