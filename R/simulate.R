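# Synthetic cohort generator.
#
# Each physiological component draws from its own seeded substream (see
# substream_seed) so that, e.g., two cohorts differing only in cgm_noise_sd
# share identical episode schedules.

SIM_ORIGIN <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")

#' Generate one synthetic subject
#'
#' Simulates a subject's CGM series at the 5-minute grid, an optional 1 Hz
#' heart-rate/activity stream, and the ground-truth exercise episode list.
#' Glucose is a per-subject baseline plus slow mean-reverting wander, meal
#' excursions, exercise-induced decline starting `glycemic_lag` minutes after
#' episode onset (piecewise-linear drop, exponential post-episode recovery),
#' and additive sensor noise. Heart rate responds to every episode with a
#' first-order rise of `hr_gain * intensity` bpm. Unreported episodes affect
#' the physiology but carry no label; CGM dropouts remove grid points.
#'
#' Deterministic given `(config$seed, subject_index)`.
#'
#' @param config a [sim_config()].
#' @param subject_index 1-based subject index, at most `config$n_subjects`.
#' @param highrate if `FALSE`, skip the 1 Hz stream (the CGM-grid series is
#'   unaffected: the wearable stream has its own noise substream).
#' @return list with elements `series` (a [subject_series()]), `highrate`
#'   (`data.frame(time, hr_bpm, activity)` or `NULL`), and `truth`
#'   (`data.frame(start_min, start_time, duration, intensity, reported)`).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 1, days_per_subject = 2, seed = 3)
#' sub <- generate_subject(cfg, 1, highrate = FALSE)
#' nrow(sub$series$records)
generate_subject <- function(config, subject_index, highrate = TRUE) {
  if (!inherits(config, "sim_config")) validate_sim_config(config)
  if (subject_index < 1 || subject_index > config$n_subjects) {
    stop_config("n_subjects", sprintf(
      "does not cover subject_index %d", subject_index
    ))
  }

  horizon <- config$days_per_subject * 1440 # minutes
  dt <- config$cgm_interval
  grid <- seq(0, horizon - dt, by = dt)

  traits <- with_substream(
    substream_seed(config$seed, subject_index, "subject"),
    list(
      weight = stats::runif(
        1, config$weight_range[1],
        config$weight_range[2]
      ),
      baseline = stats::rnorm(1, config$baseline_bg[1], config$baseline_bg[2]),
      resting_hr = stats::rnorm(1, config$resting_hr[1], config$resting_hr[2])
    )
  )

  episodes <- with_substream(
    substream_seed(config$seed, subject_index, "episodes"),
    draw_episodes(config)
  )
  meals <- with_substream(
    substream_seed(config$seed, subject_index, "meals"),
    draw_meals(config)
  )
  drift <- with_substream(
    substream_seed(config$seed, subject_index, "drift"),
    draw_drift(config, length(grid))
  )
  cgm_noise <- with_substream(
    substream_seed(config$seed, subject_index, "cgm_noise"),
    stats::rnorm(length(grid), 0, config$cgm_noise_sd)
  )
  hr_grid_noise <- with_substream(
    substream_seed(config$seed, subject_index, "hr_grid_noise"),
    stats::rnorm(length(grid), 0, config$hr_noise_sd)
  )
  gaps <- with_substream(
    substream_seed(config$seed, subject_index, "gaps"),
    draw_gaps(config)
  )

  bg <- traits$baseline + drift +
    meal_effect(grid, meals, config) +
    exercise_bg_effect(grid, episodes, config) +
    cgm_noise
  bg <- pmax(bg, 20) # physical floor; untouched at realistic settings

  hr_grid <- round(
    hr_mechanism(grid, episodes, traits$resting_hr, config) + hr_grid_noise
  )

  flag <- as.integer(in_reported_episode(grid, episodes))

  keep <- !in_gap(grid, gaps)
  records <- data.frame(
    time = SIM_ORIGIN + grid[keep] * 60,
    bg_mgdl = bg[keep],
    hr_bpm = as.integer(hr_grid[keep]),
    exercise = flag[keep]
  )

  series <- subject_series(
    subject_id = sprintf("S%03d", subject_index),
    weight = traits$weight,
    records = records,
    nominal_interval = dt,
    unit_system = "mg/dL"
  )

  hr_stream <- NULL
  if (isTRUE(highrate)) {
    step <- config$highrate_interval # seconds
    t_sec <- seq(0, horizon * 60 - step, by = step)
    t_min <- t_sec / 60
    noise <- with_substream(
      substream_seed(config$seed, subject_index, "highrate_noise"),
      list(
        hr = stats::rnorm(length(t_sec), 0, config$hr_noise_sd),
        act = stats::rnorm(length(t_sec), 0, config$activity_noise_sd)
      )
    )
    hr_stream <- data.frame(
      time = SIM_ORIGIN + t_sec,
      hr_bpm = round(
        hr_mechanism(t_min, episodes, traits$resting_hr, config) + noise$hr
      ),
      activity = pmax(
        activity_mechanism(t_min, episodes, config) + noise$act, 0
      )
    )
  }

  truth <- episodes
  truth$start_time <- SIM_ORIGIN + truth$start_min * 60
  list(series = series, highrate = hr_stream, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Calls [generate_subject()] for each of `config$n_subjects` subjects.
#' Reproducible from `config$seed`; per-subject streams are independent
#' substreams, so a cohort is identical whether subjects are generated
#' together or one at a time.
#'
#' @inheritParams generate_subject
#' @return list of per-subject bundles as returned by [generate_subject()].
#' @export
generate_cohort <- function(config, highrate = TRUE) {
  if (!inherits(config, "sim_config")) validate_sim_config(config)
  lapply(
    seq_len(config$n_subjects),
    function(i) generate_subject(config, i, highrate = highrate)
  )
}

# --- episode / meal / gap schedules ----------------------------------------

# Non-overlapping exercise episodes, confined to single days so that
# midnight-to-midnight day blocks own whole episodes. Rejection sampling
# keeps per-day episodes disjoint. Start times and durations are quantized
# to whole minutes: episodes emulate self-reports, which carry
# minute-resolution timestamps.
draw_episodes <- function(config) {
  out <- list()
  ints <- seq(
    ceiling(config$exercise_intensity[1]),
    floor(config$exercise_intensity[2])
  )
  for (day in seq_len(config$days_per_subject) - 1) {
    n <- stats::rpois(1, config$exercise_rate)
    day_eps <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(day_eps) < n && tries < 200) {
      tries <- tries + 1
      dur <- round(stats::runif(
        1, config$exercise_duration[1],
        config$exercise_duration[2]
      ))
      start <- day * 1440 + floor(stats::runif(1, 0, 1440 - dur))
      ok <- nrow(day_eps) == 0 ||
        all(start + dur <= day_eps[, 1] | start >= day_eps[, 1] + day_eps[, 2])
      if (ok) day_eps <- rbind(day_eps, c(start, dur))
    }
    if (nrow(day_eps) > 0) {
      intensity <- ints[sample.int(length(ints), nrow(day_eps),
        replace = TRUE
      )]
      reported <- stats::runif(nrow(day_eps)) >= config$unreported_fraction
      out[[length(out) + 1]] <- data.frame(
        start_min = day_eps[, 1], duration = day_eps[, 2],
        intensity = intensity, reported = reported
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      start_min = numeric(0), duration = numeric(0),
      intensity = numeric(0), reported = logical(0)
    ))
  }
  res <- do.call(rbind, out)
  res[order(res$start_min), , drop = FALSE]
}

draw_meals <- function(config) {
  n <- stats::rpois(config$days_per_subject, config$meal_rate)
  total <- sum(n)
  if (total == 0) {
    return(data.frame(
      start_min = numeric(0),
      magnitude = numeric(0)
    ))
  }
  day <- rep(seq_len(config$days_per_subject) - 1, n)
  data.frame(
    start_min = day * 1440 + stats::runif(total, 0, 1440),
    magnitude = stats::runif(total, config$meal_rise[1], config$meal_rise[2])
  )
}

draw_gaps <- function(config) {
  n <- stats::rpois(config$days_per_subject, config$gap_rate)
  total <- sum(n)
  if (total == 0) {
    return(data.frame(start_min = numeric(0), duration = numeric(0)))
  }
  day <- rep(seq_len(config$days_per_subject) - 1, n)
  data.frame(
    start_min = day * 1440 + stats::runif(total, 0, 1440),
    duration = stats::runif(total, config$gap_duration[1],
      config$gap_duration[2]
    )
  )
}

# Ornstein-Uhlenbeck-style wander discretized on the CGM grid.
draw_drift <- function(config, n) {
  rate <- config$bg_drift[1]
  sd <- config$bg_drift[2]
  dt <- config$cgm_interval
  if (sd == 0 || n == 0) {
    return(numeric(n))
  }
  innov <- stats::rnorm(n, 0, sd * sqrt(dt))
  a <- max(0, 1 - rate * dt)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# --- mechanistic signal components -----------------------------------------

# Meal excursion: linear rise over meal_rise_duration, then exponential
# decay with meal_decay_duration time constant.
meal_effect <- function(t, meals, config) {
  eff <- numeric(length(t))
  if (nrow(meals) == 0) {
    return(eff)
  }
  rise <- config$meal_rise_duration
  tau <- config$meal_decay_duration
  for (k in seq_len(nrow(meals))) {
    rel <- t - meals$start_min[k]
    up <- rel > 0 & rel <= rise
    down <- rel > rise
    eff[up] <- eff[up] + meals$magnitude[k] * rel[up] / rise
    eff[down] <- eff[down] + meals$magnitude[k] * exp(-(rel[down] - rise) / tau)
  }
  eff
}

# Exercise-induced glucose deficit: zero until glycemic_lag after onset,
# linear decline at glucose_drop_rate * intensity while the (lag-shifted)
# episode is ongoing, then exponential recovery.
exercise_bg_effect <- function(t, episodes, config) {
  eff <- numeric(length(t))
  if (nrow(episodes) == 0) {
    return(eff)
  }
  lag <- config$glycemic_lag
  tau <- config$post_exercise_decay
  for (k in seq_len(nrow(episodes))) {
    r <- config$glucose_drop_rate * episodes$intensity[k]
    s <- episodes$start_min[k] + lag
    e <- episodes$start_min[k] + episodes$duration[k] + lag
    during <- t >= s & t < e
    after <- t >= e
    eff[during] <- eff[during] - r * (t[during] - s)
    eff[after] <- eff[after] - r * (e - s) * exp(-(t[after] - e) / tau)
  }
  eff
}

# First-order heart-rate response to every episode (reported or not).
hr_mechanism <- function(t, episodes, resting, config) {
  hr <- rep(resting, length(t))
  if (nrow(episodes) == 0) {
    return(hr)
  }
  tau <- config$hr_onset_tau
  for (k in seq_len(nrow(episodes))) {
    amp <- config$hr_gain * episodes$intensity[k]
    s <- episodes$start_min[k]
    e <- s + episodes$duration[k]
    during <- t >= s & t < e
    after <- t >= e
    hr[during] <- hr[during] + amp * (1 - exp(-(t[during] - s) / tau))
    peak <- amp * (1 - exp(-(e - s) / tau))
    hr[after] <- hr[after] + peak * exp(-(t[after] - e) / tau)
  }
  hr
}

# Wearable activity level: resting mean 0.05, step elevation during
# episodes so the 0.2 mild-activity threshold is informative.
activity_mechanism <- function(t, episodes, config) {
  act <- rep(0.05, length(t))
  if (nrow(episodes) == 0) {
    return(act)
  }
  for (k in seq_len(nrow(episodes))) {
    s <- episodes$start_min[k]
    e <- s + episodes$duration[k]
    during <- t >= s & t < e
    act[during] <- act[during] + config$activity_gain * episodes$intensity[k]
  }
  act
}

# Membership of grid times in reported episodes (half-open intervals).
in_reported_episode <- function(t, episodes) {
  res <- logical(length(t))
  rep_eps <- episodes[episodes$reported, , drop = FALSE]
  for (k in seq_len(nrow(rep_eps))) {
    res <- res | (t >= rep_eps$start_min[k] &
      t < rep_eps$start_min[k] + rep_eps$duration[k])
  }
  res
}

# Membership of grid times in any episode, reported or not.
in_any_episode <- function(t, episodes) {
  res <- logical(length(t))
  for (k in seq_len(nrow(episodes))) {
    res <- res | (t >= episodes$start_min[k] &
      t < episodes$start_min[k] + episodes$duration[k])
  }
  res
}

in_gap <- function(t, gaps) {
  res <- logical(length(t))
  for (k in seq_len(nrow(gaps))) {
    res <- res | (t >= gaps$start_min[k] &
      t < gaps$start_min[k] + gaps$duration[k])
  }
  res
}
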