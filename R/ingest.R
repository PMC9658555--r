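# Readers for the two source dialects and the cleaned interchange format.

# Timestamp parser accepting both "DD-MM-YYYY HH:MM:SS" and
# "YYYY-MM-DD HH:MM:SS" (auto-detected per vector); locale-independent.
parse_timestamps <- function(x) {
  x <- trimws(x)
  iso <- grepl("^\\d{4}-", x[1])
  fmt <- if (iso) "%Y-%m-%d %H:%M:%S" else "%d-%m-%Y %H:%M:%S"
  out <- as.POSIXct(x, format = fmt, tz = "UTC")
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("unparseable timestamp '%s' (entry %d)", x[bad], bad),
      call. = FALSE
    )
  }
  out
}

#' Read an Ohio-style subject XML archive
#'
#' Parses the `glucose_level`, `exercise` and `basis_heart_rate` event
#' sections of one `<patient>` document into raw event tables. Missing
#' sections yield empty tables; a missing `weight` attribute is an error
#' because body weight is a required downstream feature.
#'
#' @param path XML file path.
#' @return list of class `raw_subject_data` with `subject_id`, `weight`,
#'   `glucose_events`, `exercise_events`, `hr_events` (all sorted by
#'   timestamp), `highrate_stream = NULL`, and `source = "ohio"`.
#' @export
read_ohio_subject <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop(sprintf("malformed XML in %s: %s", path, conditionMessage(e)),
        call. = FALSE
      )
    }
  )
  root <- xml2::xml_find_first(doc, "//patient")
  if (inherits(root, "xml_missing")) root <- xml2::xml_root(doc)

  weight_attr <- xml2::xml_attr(root, "weight")
  if (is.na(weight_attr) || !is.finite(suppressWarnings(
    as.numeric(weight_attr)
  ))) {
    stop(sprintf("weight unavailable in %s", path), call. = FALSE)
  }

  read_events <- function(section, fields) {
    nodes <- xml2::xml_find_all(root, sprintf("./%s/event", section))
    out <- lapply(fields, function(f) xml2::xml_attr(nodes, f))
    names(out) <- fields
    as.data.frame(out, stringsAsFactors = FALSE)
  }

  gl <- read_events("glucose_level", c("ts", "value"))
  glucose_events <- data.frame(
    time = if (nrow(gl)) parse_timestamps(gl$ts) else
      as.POSIXct(character(0), tz = "UTC"),
    value = as.numeric(gl$value),
    unit = rep("mg/dL", nrow(gl))
  )
  glucose_events <- glucose_events[order(glucose_events$time), , drop = FALSE]

  ex <- read_events(
    "exercise",
    c("ts", "intensity", "duration", "type", "competitive")
  )
  exercise_events <- data.frame(
    time = if (nrow(ex)) parse_timestamps(ex$ts) else
      as.POSIXct(character(0), tz = "UTC"),
    intensity = as.numeric(ex$intensity),
    duration = as.numeric(ex$duration),
    type = ex$type,
    competitive = ex$competitive
  )
  exercise_events <- exercise_events[
    order(exercise_events$time), ,
    drop = FALSE
  ]

  hr <- read_events("basis_heart_rate", c("ts", "value"))
  hr_events <- data.frame(
    time = if (nrow(hr)) parse_timestamps(hr$ts) else
      as.POSIXct(character(0), tz = "UTC"),
    value = as.numeric(hr$value)
  )
  hr_events <- hr_events[order(hr_events$time), , drop = FALSE]

  structure(
    list(
      subject_id = xml2::xml_attr(root, "id"),
      weight = as.numeric(weight_attr),
      glucose_events = glucose_events,
      exercise_events = exercise_events,
      hr_events = hr_events,
      highrate_stream = NULL,
      source = "ohio"
    ),
    class = "raw_subject_data"
  )
}

#' Read a D1namo-style subject folder
#'
#' Expects `glucose.csv` with columns `date, time, glucose, type` (glucose in
#' mmol/L; `type` is `cgm` or `manual`) and `sensor.csv` with the 1 Hz
#' `datetime, hr, activity` wearable summary. Manual finger-stick rows are
#' retained but tagged. Rows that fail to parse are skipped with a message
#' reporting the count. An optional `subject.csv` supplies id and weight.
#'
#' @param path directory path.
#' @return list of class `raw_subject_data`; glucose values carry the
#'   `"mmol/L"` unit tag and `highrate_stream` holds the wearable samples.
#' @export
read_d1namo_subject <- function(path) {
  gfile <- file.path(path, "glucose.csv")
  sfile <- file.path(path, "sensor.csv")
  if (!file.exists(gfile)) {
    stop(sprintf("glucose CSV not found in %s", path), call. = FALSE)
  }
  if (!file.exists(sfile)) {
    stop(sprintf("sensor CSV not found in %s", path), call. = FALSE)
  }

  g <- utils::read.csv(gfile, stringsAsFactors = FALSE,
    colClasses = "character"
  )
  for (col in c("date", "time", "glucose", "type")) {
    if (!col %in% names(g)) {
      stop(sprintf("glucose.csv lacks required column '%s'", col),
        call. = FALSE
      )
    }
  }
  conc <- suppressWarnings(as.numeric(g$glucose))
  ts <- suppressWarnings(
    as.POSIXct(paste(g$date, g$time),
      format = "%Y-%m-%d %H:%M:%S",
      tz = "UTC"
    )
  )
  ok <- !is.na(conc) & !is.na(ts)
  if (any(!ok)) {
    message(sprintf("glucose.csv: skipped %d unparseable row(s)", sum(!ok)))
  }
  glucose_events <- data.frame(
    time = ts[ok], value = conc[ok],
    unit = rep("mmol/L", sum(ok)),
    type = g$type[ok]
  )
  glucose_events <- glucose_events[order(glucose_events$time), , drop = FALSE]

  s <- utils::read.csv(sfile, stringsAsFactors = FALSE,
    colClasses = "character"
  )
  if (nrow(s) > 0) {
    for (col in c("datetime", "hr", "activity")) {
      if (!col %in% names(s)) {
        stop(sprintf("sensor.csv lacks required column '%s'", col),
          call. = FALSE
        )
      }
    }
    sts <- suppressWarnings(
      as.POSIXct(s$datetime, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
    )
    shr <- suppressWarnings(as.numeric(s$hr))
    sact <- suppressWarnings(as.numeric(s$activity))
    sok <- !is.na(sts) & !is.na(shr) & !is.na(sact)
    if (any(!sok)) {
      message(sprintf("sensor.csv: skipped %d unparseable row(s)", sum(!sok)))
    }
    highrate <- data.frame(
      time = sts[sok], hr_bpm = shr[sok],
      activity = sact[sok]
    )
    highrate <- highrate[order(highrate$time), , drop = FALSE]
  } else {
    highrate <- data.frame(
      time = as.POSIXct(character(0), tz = "UTC"),
      hr_bpm = numeric(0), activity = numeric(0)
    )
  }

  subject_id <- basename(normalizePath(path, mustWork = FALSE))
  weight <- NA_real_
  mfile <- file.path(path, "subject.csv")
  if (file.exists(mfile)) {
    m <- utils::read.csv(mfile, stringsAsFactors = FALSE)
    if ("subject_id" %in% names(m)) subject_id <- as.character(m$subject_id[1])
    if ("weight_kg" %in% names(m)) weight <- as.numeric(m$weight_kg[1])
  }

  structure(
    list(
      subject_id = subject_id,
      weight = weight,
      glucose_events = glucose_events,
      exercise_events = data.frame(
        time = as.POSIXct(character(0), tz = "UTC"),
        intensity = numeric(0), duration = numeric(0),
        type = character(0), competitive = character(0)
      ),
      hr_events = data.frame(
        time = as.POSIXct(character(0), tz = "UTC"),
        value = numeric(0)
      ),
      highrate_stream = highrate,
      source = "d1namo"
    ),
    class = "raw_subject_data"
  )
}

# --- cleaned interchange format --------------------------------------------

#' Write / read the cleaned interchange format
#'
#' One headered CSV per subject, columns
#' `[date, time, bg_mgdl, hr_bpm, exercise]` (HR blank where absent), with a
#' leading comment line carrying subject id, body weight, nominal interval
#' and unit system. `read_cleaned(write_cleaned(s))` is the identity.
#'
#' @param series a [subject_series()].
#' @param path CSV file path.
#' @return `write_cleaned` returns `path` invisibly; `read_cleaned` returns
#'   the [subject_series()].
#' @export
write_cleaned <- function(series, path) {
  stopifnot(inherits(series, "subject_series"))
  rec <- series$records
  header <- sprintf(
    "#exdetect subject_id=%s weight=%.17g nominal_interval=%g unit_system=%s",
    series$subject_id, series$weight, series$nominal_interval,
    series$unit_system
  )
  body <- data.frame(
    date = format(rec$time, "%Y-%m-%d", tz = "UTC"),
    time = format(rec$time, "%H:%M:%S", tz = "UTC"),
    bg_mgdl = sprintf("%.17g", rec$bg_mgdl),
    hr_bpm = ifelse(is.na(rec$hr_bpm), "", as.character(rec$hr_bpm)),
    exercise = rec$exercise
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(body, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cleaned
#' @export
read_cleaned <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, n = 1)
  if (!startsWith(lines[1], "#exdetect")) {
    stop(sprintf("%s is not a cleaned interchange file", path), call. = FALSE)
  }
  kv <- strsplit(sub("^#exdetect ", "", lines[1]), " ")[[1]]
  meta <- list()
  for (pair in kv) {
    parts <- strsplit(pair, "=", fixed = TRUE)[[1]]
    meta[[parts[1]]] <- parts[2]
  }
  body <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE,
    colClasses = c(
      date = "character", time = "character",
      bg_mgdl = "numeric", hr_bpm = "integer",
      exercise = "integer"
    )
  )
  records <- data.frame(
    time = as.POSIXct(paste(body$date, body$time),
      format = "%Y-%m-%d %H:%M:%S", tz = "UTC"
    ),
    bg_mgdl = body$bg_mgdl,
    hr_bpm = body$hr_bpm,
    exercise = body$exercise
  )
  subject_series(
    subject_id = meta$subject_id,
    weight = as.numeric(meta$weight),
    records = records,
    nominal_interval = as.numeric(meta$nominal_interval),
    unit_system = meta$unit_system
  )
}
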