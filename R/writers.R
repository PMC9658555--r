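# Writers that serialize a simulated subject into the two field dialects,
# so ingest is exercised end-to-end on generated fixtures.

fmt_ohio_ts <- function(time) {
  format(time, "%d-%m-%Y %H:%M:%S", tz = "UTC")
}

#' Write a subject bundle as an Ohio-style XML archive
#'
#' Emits one `<patient>` document with `glucose_level`, `exercise` and
#' `basis_heart_rate` event sections and a `weight` attribute, mirroring the
#' structure the Ohio T1DM extraction relies on. Only *reported* episodes are
#' written to the `exercise` section (self-report emulation); glucose is in
#' mg/dL, heart rate in integer bpm, timestamps in the
#' `DD-MM-YYYY HH:MM:SS` dialect.
#'
#' @param bundle a subject bundle from [generate_subject()].
#' @param path output XML file path.
#' @return `path`, invisibly.
#' @export
write_ohio_xml <- function(bundle, path) {
  series <- bundle$series
  rec <- series$records

  glucose <- sprintf(
    '    <event ts="%s" value="%.1f"/>',
    fmt_ohio_ts(rec$time), rec$bg_mgdl
  )
  truth <- bundle$truth[bundle$truth$reported, , drop = FALSE]
  exercise <- sprintf(
    paste0(
      '    <event ts="%s" intensity="%d" type="aerobic" ',
      'duration="%.2f" competitive="No"/>'
    ),
    fmt_ohio_ts(truth$start_time), as.integer(truth$intensity),
    truth$duration
  )
  has_hr <- !is.na(rec$hr_bpm)
  heart <- sprintf(
    '    <event ts="%s" value="%d"/>',
    fmt_ohio_ts(rec$time[has_hr]), rec$hr_bpm[has_hr]
  )

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(
      '<patient id="%s" weight="%.1f" insulin_type="synthetic">',
      series$subject_id, series$weight
    ),
    "  <glucose_level>", glucose, "  </glucose_level>",
    "  <exercise>", exercise, "  </exercise>",
    "  <basis_heart_rate>", heart, "  </basis_heart_rate>",
    "</patient>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a subject bundle as a D1namo-style CSV folder
#'
#' Creates `glucose.csv` with `[date, time, glucose, type]` rows (glucose in
#' mmol/L, rounded to one decimal as the sensor reports it, type `"cgm"`) and
#' `sensor.csv` with the 1 Hz `[datetime, hr, activity]` wearable summary.
#' The activity channel, not self-report, carries the exercise information in
#' this dialect. A small `subject.csv` holds the subject id and body weight.
#'
#' @param bundle a subject bundle from [generate_subject()]; must include the
#'   high-rate stream (`highrate = TRUE` at generation).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_d1namo_csv <- function(bundle, dir) {
  if (is.null(bundle$highrate)) {
    stop("bundle lacks the 1 Hz stream; regenerate with highrate = TRUE",
      call. = FALSE
    )
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- bundle$series$records
  glucose <- data.frame(
    date = format(rec$time, "%Y-%m-%d", tz = "UTC"),
    time = format(rec$time, "%H:%M:%S", tz = "UTC"),
    glucose = sprintf("%.1f", rec$bg_mgdl / 18.0182),
    type = "cgm"
  )
  utils::write.csv(glucose, file.path(dir, "glucose.csv"),
    row.names = FALSE, quote = FALSE
  )

  hrs <- bundle$highrate
  sensor <- data.frame(
    datetime = format(hrs$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    hr = hrs$hr_bpm,
    activity = sprintf("%.4f", hrs$activity)
  )
  utils::write.csv(sensor, file.path(dir, "sensor.csv"),
    row.names = FALSE, quote = FALSE
  )

  meta <- data.frame(
    subject_id = bundle$series$subject_id,
    weight_kg = sprintf("%.1f", bundle$series$weight)
  )
  utils::write.csv(meta, file.path(dir, "subject.csv"),
    row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}
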