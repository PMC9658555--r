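#' Construct a subject series
#'
#' A `subject_series` is the normalized record model used throughout the
#' pipeline: one row per CGM registration in chronological order, holding
#' blood glucose in mg/dL, an optional integer heart rate in bpm, and the
#' binary exercise label, together with the subject id and the separately
#' handled body weight.
#'
#' @param subject_id subject identifier (character).
#' @param weight body weight in kg (a required feature downstream).
#' @param records `data.frame` with columns `time` (POSIXct), `bg_mgdl`,
#'   `hr_bpm` (may be `NA`), `exercise` (0/1).
#' @param nominal_interval nominal CGM sampling interval in minutes.
#' @param unit_system `"mg/dL"` for natively mg/dL sources, or
#'   `"converted_mmol/L"` where concentrations were converted at ingest.
#' @return object of class `subject_series`.
#' @export
subject_series <- function(subject_id, weight, records,
                           nominal_interval = 5,
                           unit_system = "mg/dL") {
  stopifnot(is.character(subject_id), length(subject_id) == 1)
  if (!is.numeric(weight) || length(weight) != 1 || !is.finite(weight) ||
    weight <= 0) {
    stop("subject weight must be a single positive number (kg)",
      call. = FALSE
    )
  }
  needed <- c("time", "bg_mgdl", "hr_bpm", "exercise")
  if (!all(needed %in% names(records))) {
    stop(
      "records must have columns: ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(records) > 1 && any(diff(as.numeric(records$time)) <= 0)) {
    stop("records must be strictly increasing in time", call. = FALSE)
  }
  if (any(records$bg_mgdl <= 0, na.rm = TRUE)) {
    stop("blood glucose must be positive", call. = FALSE)
  }
  if (!all(records$exercise %in% c(0, 1))) {
    stop("exercise labels must be 0/1", call. = FALSE)
  }
  structure(
    list(
      subject_id = subject_id,
      weight = weight,
      records = records[, needed],
      nominal_interval = nominal_interval,
      unit_system = unit_system
    ),
    class = "subject_series"
  )
}

#' @export
print.subject_series <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "<subject_series> %s: %d records, weight %.1f kg, %s\n",
    x$subject_id, nrow(r), x$weight, x$unit_system
  ))
  if (nrow(r) > 0) {
    cat(sprintf(
      "  %s .. %s; %d exercise-positive; HR present at %d records\n",
      format(min(r$time), tz = "UTC"), format(max(r$time), tz = "UTC"),
      sum(r$exercise), sum(!is.na(r$hr_bpm))
    ))
  }
  invisible(x)
}

# Minutes since the first midnight of the series' calendar.
series_minutes <- function(times) {
  as.numeric(times, tz = "UTC") / 60
}
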