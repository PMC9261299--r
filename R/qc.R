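.datatable.aware <- TRUE

#' Canonical feature-column names
#'
#' The fixed, documented order of the 336 features: all hourly-maximum
#' columns `max_d{day}_h{hour}` for day 1-7 and hour 0-23 (day-major), then
#' all hourly-variance columns `var_d{day}_h{hour}` in the same order. Units
#' are device counts and counts squared, respectively.
#'
#' @return Character vector of length 336.
#' @export
feature_names <- function() {
  grid <- expand.grid(hour = 0:23, day = 1:7)
  c(sprintf("max_d%d_h%d", grid$day, grid$hour),
    sprintf("var_d%d_h%d", grid$day, grid$hour))
}

#' Apply the cohort inclusion filters to activity weeks
#'
#' Retains a participant's week only if (a) the device was calibrated for
#' every record, (b) all 7 days are complete (1440 distinct minutes each),
#' (c) every day has at least 10% of minutes (>= 144 of 1440) with intensity
#' strictly greater than zero, and (d) the participant is aged 18 or older.
#' The 10% rule is evaluated per day; all seven days must pass. Weeks are
#' dropped, never repaired; an exclusion log records every rule each dropped
#' week violated.
#'
#' @param activity Long canonical activity tibble (see [read_activity()]).
#' @param demographics Tibble with `participant_id` and `age_years`. Every
#'   week must have a matching participant, otherwise a validation error is
#'   raised.
#' @return The retained activity tibble, with the exclusion log — a tibble of
#'   (`participant_id`, `rule`), `rule` one of `"not_calibrated"`,
#'   `"incomplete_week"`, `"low_activity_day"`, `"under_age"` — attached as
#'   attribute `"exclusions"` (see [qc_exclusions()]). Idempotent.
#' @export
qc_filter <- function(activity, demographics) {
  ids <- unique(activity$participant_id)
  missing <- setdiff(ids, demographics$participant_id)
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "activity weeks without matching participant: %s",
      paste(utils::head(missing, 5), collapse = ", ")))
  }

  dt <- data.table::as.data.table(activity)
  per_day <- dt[, list(n_min = data.table::uniqueN(minute),
                       n_rows = .N,
                       nonzero = sum(intensity > 0),
                       cal = all(calibrated)),
                by = c("participant_id", "day")]
  per_week <- per_day[, list(
    calibrated = all(cal),
    complete = .N == 7L && all(n_min == 1440L) && all(n_rows == 1440L),
    active = all(nonzero >= 144L)),
    by = "participant_id"]

  age <- demographics$age_years[match(per_week$participant_id,
                                      demographics$participant_id)]
  rules <- list(
    not_calibrated = !per_week$calibrated,
    incomplete_week = !per_week$complete,
    low_activity_day = per_week$complete & !per_week$active,
    under_age = age < 18
  )
  excl <- dplyr::bind_rows(lapply(names(rules), function(r) {
    tibble::tibble(participant_id = per_week$participant_id[rules[[r]]], rule = r)
  }))
  excl <- dplyr::arrange(excl, .data$participant_id, .data$rule)

  keep <- per_week$participant_id[!Reduce(`|`, rules)]
  out <- activity[activity$participant_id %in% keep, , drop = FALSE]
  attr(out, "exclusions") <- excl
  out
}

#' Exclusion log of a QC-filtered activity table
#'
#' @param activity The result of [qc_filter()].
#' @return Tibble with columns `participant_id` and `rule`.
#' @export
qc_exclusions <- function(activity) {
  excl <- attr(activity, "exclusions")
  if (is.null(excl)) tibble::tibble(participant_id = integer(0), rule = character(0))
  else excl
}

#' Reduce activity weeks to the 336 hourly max/variance features
#'
#' For each of the 168 (day, hour) cells of a complete 7 x 1440 week, emits
#' the maximum and the sample variance (denominator n - 1) of that hour's 60
#' minute-level intensity counts. Column order follows [feature_names()]:
#' maxima first, then variances, day-major and hour-minor. The feature vector
#' is invariant to permuting minutes within an hour; scaling all counts by c
#' scales max features by c and variance features by c squared.
#'
#' @param activity QC-passed long activity tibble; every participant must
#'   have a complete grid (a contract violation error is raised otherwise).
#' @return Tibble: `participant_id` plus the 336 named feature columns.
#' @export
summarize_weeks <- function(activity) {
  dt <- data.table::as.data.table(
    activity[, c("participant_id", "day", "minute", "intensity")])
  sizes <- dt[, list(n = .N, n_cells = data.table::uniqueN(1440L * day + minute)),
              by = "participant_id"]
  if (any(sizes$n != 10080L | sizes$n_cells != 10080L)) {
    abort_validation("summarize_weeks: incomplete activity grid; run qc_filter first")
  }

  dt[, "hour" := minute %/% 60L]
  agg <- dt[, list(mx = as.numeric(max(intensity)),
                   vr = stats::var(as.numeric(intensity))),
            by = c("participant_id", "day", "hour")]
  agg[, "fmax" := sprintf("max_d%d_h%d", day, hour)]
  agg[, "fvar" := sprintf("var_d%d_h%d", day, hour)]

  wide_max <- data.table::dcast(agg, participant_id ~ fmax, value.var = "mx")
  wide_var <- data.table::dcast(agg, participant_id ~ fvar, value.var = "vr")
  out <- merge(wide_max, wide_var, by = "participant_id")
  out <- tibble::as_tibble(out)
  out[, c("participant_id", feature_names())]
}
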