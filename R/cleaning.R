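# Cleaning rules: exercise labeling, 24 h day-block extraction, and
# aggregation of the 1 Hz wearable stream onto the CGM grid.

#' Cleaning configuration
#'
#' @param min_intensity self-reported episodes below this intensity are
#'   labeled 0 (default 2: "mild" reports are not treated as exercise).
#' @param activity_threshold wearable activity level above which (strictly)
#'   an aggregated registration is labeled as exercise; 0.2 is the
#'   mild-activity bar of the Zephyr activity channel.
#' @param max_gap largest tolerated spacing between consecutive CGM
#'   registrations within a retained day, minutes (default 1.5 x the nominal
#'   5-minute interval).
#' @param min_day_coverage minimum fraction of the day's nominal grid that
#'   must be present for the day to be retained.
#' @param require_hr if `TRUE`, retained day blocks must have a heart-rate
#'   value at every registration.
#' @return object of class `cleaning_config`.
#' @export
cleaning_config <- function(min_intensity = 2,
                            activity_threshold = 0.2,
                            max_gap = 7.5,
                            min_day_coverage = 0.9,
                            require_hr = FALSE) {
  if (min_intensity <= 0) stop_config("min_intensity", "must be positive")
  if (activity_threshold <= 0) {
    stop_config("activity_threshold", "must be positive")
  }
  if (max_gap <= 0) stop_config("max_gap", "must be positive")
  if (min_day_coverage <= 0 || min_day_coverage > 1) {
    stop_config("min_day_coverage", "must lie in (0, 1]")
  }
  structure(
    list(
      min_intensity = min_intensity,
      activity_threshold = activity_threshold,
      max_gap = max_gap,
      min_day_coverage = min_day_coverage,
      require_hr = isTRUE(require_hr)
    ),
    class = "cleaning_config"
  )
}

#' Label CGM registrations with ongoing exercise
#'
#' A grid point `t` is labeled 1 iff some reported episode with intensity at
#' least `config$min_intensity` satisfies `start <= t < start + duration`
#' (half-open interval). Events with a missing or non-positive duration are
#' rejected with a warning and contribute no labels.
#'
#' @param glucose_grid POSIXct (or numeric minutes) vector of registration
#'   times, sorted.
#' @param exercise_events `data.frame` with columns `time` (same type as the
#'   grid), `intensity`, `duration` (minutes).
#' @param config a [cleaning_config()].
#' @return integer 0/1 vector along the grid.
#' @export
label_exercise <- function(glucose_grid, exercise_events,
                           config = cleaning_config()) {
  t_min <- if (inherits(glucose_grid, "POSIXct")) {
    as.numeric(glucose_grid) / 60
  } else {
    as.numeric(glucose_grid)
  }
  if (is.unsorted(t_min)) stop("glucose grid must be sorted", call. = FALSE)
  labels <- integer(length(t_min))
  if (is.null(exercise_events) || nrow(exercise_events) == 0) {
    return(labels)
  }
  ev_start <- if (inherits(exercise_events$time, "POSIXct")) {
    as.numeric(exercise_events$time) / 60
  } else {
    as.numeric(exercise_events$time)
  }
  bad <- is.na(exercise_events$duration) | exercise_events$duration <= 0
  if (any(bad)) {
    warning(sprintf(
      "%d exercise event(s) with missing/invalid duration ignored", sum(bad)
    ), call. = FALSE)
  }
  for (k in which(!bad)) {
    if (!is.na(exercise_events$intensity[k]) &&
      exercise_events$intensity[k] < config$min_intensity) {
      next
    }
    inside <- t_min >= ev_start[k] &
      t_min < ev_start[k] + exercise_events$duration[k]
    labels[inside] <- 1L
  }
  labels
}

#' Extract labeled midnight-to-midnight analysis blocks
#'
#' Keeps only 24 h calendar days that (a) have CGM coverage of at least
#' `min_day_coverage` of the nominal grid with no intra-day spacing larger
#' than `max_gap`, (b) contain at least one exercise-positive registration,
#' and (c), when `require_hr`, have heart rate at every registration. Days
#' with reported exercise but insufficient CGM, and days with CGM but no
#' reported exercise, are both dropped.
#'
#' @param series a labeled [subject_series()].
#' @param config a [cleaning_config()].
#' @return list of `day_block` objects: lists with `subject_id`, `weight`,
#'   `date`, `records`, `has_hr`.
#' @export
extract_day_blocks <- function(series, config = cleaning_config()) {
  stopifnot(inherits(series, "subject_series"))
  rec <- series$records
  if (nrow(rec) == 0) {
    return(list())
  }
  day <- as.Date(rec$time, tz = "UTC")
  per_day <- 24 * 60 / series$nominal_interval
  blocks <- list()
  for (d in sort(unique(day))) {
    sub <- rec[day == d, , drop = FALSE]
    coverage <- nrow(sub) / per_day
    if (coverage < config$min_day_coverage) next
    if (nrow(sub) > 1) {
      gaps <- diff(as.numeric(sub$time)) / 60
      if (max(gaps) > config$max_gap) next
    }
    if (sum(sub$exercise) == 0) next
    has_hr <- all(!is.na(sub$hr_bpm))
    if (config$require_hr && !has_hr) next
    blocks[[length(blocks) + 1]] <- structure(
      list(
        subject_id = series$subject_id,
        weight = series$weight,
        date = as.Date(d, origin = "1970-01-01"),
        records = sub,
        has_hr = has_hr
      ),
      class = "day_block"
    )
  }
  blocks
}

#' Aggregate a 1 Hz wearable stream onto the CGM grid
#'
#' For each consecutive registration pair `(t_i, t_{i+1}]`, averages the
#' heart-rate and activity samples inside the interval and assigns the means
#' to registration `i+1` (the interval's closing registration). The exercise
#' label is 1 iff the mean activity level strictly exceeds
#' `config$activity_threshold`. Intervals containing no samples yield an
#' absent heart rate and are flagged. The first registration opens no
#' interval and is likewise flagged empty.
#'
#' Aggregated heart rate is rounded to the nearest integer, matching the
#' integer-bpm record structure.
#'
#' @param highrate_stream `data.frame(time, hr_bpm, activity)` at ~1 Hz.
#' @param glucose_grid sorted POSIXct vector of registration times.
#' @param config a [cleaning_config()].
#' @return `data.frame(time, hr_bpm, activity, exercise, n_samples, empty)`
#'   with one row per registration.
#' @export
aggregate_highrate <- function(highrate_stream, glucose_grid,
                               config = cleaning_config()) {
  grid_s <- as.numeric(glucose_grid)
  if (is.unsorted(grid_s)) stop("glucose grid must be sorted", call. = FALSE)
  n <- length(grid_s)
  out <- data.frame(
    time = glucose_grid,
    hr_bpm = rep(NA_integer_, n),
    activity = rep(NA_real_, n),
    exercise = rep(0L, n),
    n_samples = rep(0L, n),
    empty = rep(TRUE, n)
  )
  if (n == 0 || is.null(highrate_stream) || nrow(highrate_stream) == 0) {
    return(out)
  }
  st <- as.numeric(highrate_stream$time)
  # interval index: sample in (t_i, t_{i+1}] is assigned to registration i+1
  idx <- findInterval(st, grid_s, left.open = TRUE) + 1L
  keep <- st > grid_s[1] & idx <= n & idx >= 2
  idx <- idx[keep]
  if (length(idx) > 0) {
    hr_sum <- tapply(highrate_stream$hr_bpm[keep], idx, sum)
    act_sum <- tapply(highrate_stream$activity[keep], idx, sum)
    cnt <- tapply(rep(1L, length(idx)), idx, sum)
    rows <- as.integer(names(cnt))
    out$n_samples[rows] <- as.integer(cnt)
    out$hr_bpm[rows] <- as.integer(round(hr_sum / cnt))
    out$activity[rows] <- act_sum / cnt
    out$empty[rows] <- FALSE
    out$exercise[rows] <- as.integer(
      (act_sum / cnt) > config$activity_threshold
    )
  }
  out
}

# --- raw-to-series assembly -------------------------------------------------

#' Assemble a labeled series from raw Ohio-style data
#'
#' The CGM events define the 5-minute grid; heart-rate events are matched to
#' registrations by exact timestamp; labels come from [label_exercise()]
#' applied to the self-reported episodes.
#'
#' @param raw a `raw_subject_data` from [read_ohio_subject()].
#' @param config a [cleaning_config()].
#' @return a [subject_series()].
#' @export
ohio_series <- function(raw, config = cleaning_config()) {
  g <- raw$glucose_events
  hr <- rep(NA_integer_, nrow(g))
  if (nrow(raw$hr_events) > 0) {
    m <- match(as.numeric(g$time), as.numeric(raw$hr_events$time))
    hr <- as.integer(round(raw$hr_events$value[m]))
  }
  labels <- label_exercise(g$time, raw$exercise_events, config)
  subject_series(
    subject_id = raw$subject_id,
    weight = raw$weight,
    records = data.frame(
      time = g$time, bg_mgdl = g$value,
      hr_bpm = hr, exercise = labels
    ),
    unit_system = "mg/dL"
  )
}

#' Assemble a labeled series from raw D1namo-style data
#'
#' Uses the CGM-typed registrations as the grid (manual finger sticks are
#' excluded), converts mmol/L to mg/dL unless `unit_convert = FALSE`, and
#' derives heart rate, activity and the exercise label by aggregating the
#' 1 Hz stream between registrations ([aggregate_highrate()]).
#'
#' @param raw a `raw_subject_data` from [read_d1namo_subject()].
#' @param config a [cleaning_config()].
#' @param unit_convert convert mmol/L to mg/dL (default `TRUE`; feature
#'   comparability across dialects requires a single unit system).
#' @param weight fallback body weight in kg if the folder provides none.
#' @return a [subject_series()].
#' @export
d1namo_series <- function(raw, config = cleaning_config(),
                          unit_convert = TRUE, weight = NULL) {
  g <- raw$glucose_events
  g <- g[g$type == "cgm", , drop = FALSE]
  bg <- if (unit_convert) mmol_to_mgdl(g$value) else g$value
  agg <- aggregate_highrate(raw$highrate_stream, g$time, config)
  w <- raw$weight
  if (is.na(w) && !is.null(weight)) w <- weight
  if (is.na(w)) {
    stop(sprintf("weight unavailable for subject %s", raw$subject_id),
      call. = FALSE
    )
  }
  subject_series(
    subject_id = raw$subject_id,
    weight = w,
    records = data.frame(
      time = g$time, bg_mgdl = bg,
      hr_bpm = agg$hr_bpm, exercise = agg$exercise
    ),
    unit_system = if (unit_convert) "converted_mmol/L" else "mmol/L"
  )
}
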