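#' Simulation configuration for a synthetic CGM/HR cohort
#'
#' Bundles every tunable of the synthetic cohort generator. The defaults
#' describe a cohort that a detection study of this kind assumes: CGM sampled
#' every 5 minutes with additive sensor noise, a 1 Hz wearable heart-rate and
#' activity stream, self-reported exercise episodes of 10--90 minutes that
#' depress glucose after a short physiological lag while elevating heart
#' rate, meal excursions, slow glycemic wander, occasional CGM dropouts and a
#' fraction of episodes that go unreported.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param days_per_subject days of data simulated per subject.
#' @param cgm_interval CGM sampling interval in minutes; must divide 24 h.
#' @param highrate_interval wearable sampling interval in seconds.
#' @param weight_range `c(low, high)` body weight range in kg.
#' @param baseline_bg `c(mean, sd)` of the per-subject baseline glucose,
#'   mg/dL.
#' @param bg_drift `c(rate, sd)`: mean-reversion rate (per min) and diffusion
#'   sd (mg/dL per sqrt(min)) of the slow Ornstein--Uhlenbeck-style glucose
#'   wander.
#' @param meal_rate meal events per day (Poisson).
#' @param meal_rise `c(low, high)` meal excursion magnitude, mg/dL.
#' @param meal_rise_duration linear rise time of a meal excursion, minutes.
#' @param meal_decay_duration exponential decay time constant of a meal
#'   excursion, minutes.
#' @param exercise_rate exercise episodes per day (Poisson).
#' @param exercise_duration `c(low, high)` episode duration, minutes.
#' @param exercise_intensity `c(low, high)` self-reported intensity on the
#'   1--10 scale (integers are drawn).
#' @param glucose_drop_rate glucose decline during exercise, mg/dL per minute
#'   per intensity unit.
#' @param glycemic_lag delay between episode onset and the start of the
#'   glucose decline, minutes.
#' @param post_exercise_decay time constant of the post-episode recovery of
#'   the exercise-induced glucose deficit, minutes.
#' @param resting_hr `c(mean, sd)` of the per-subject resting heart rate,
#'   bpm.
#' @param hr_gain heart-rate elevation per intensity unit, bpm.
#' @param hr_onset_tau first-order time constant of the heart-rate response,
#'   minutes.
#' @param cgm_noise_sd additive CGM sensor noise sd, mg/dL.
#' @param hr_noise_sd additive heart-rate sensor noise sd, bpm.
#' @param activity_gain wearable activity-level units per intensity unit
#'   (resting mean is 0.05, so the 0.2 mild-activity threshold is exceeded
#'   for any intensity at the default gain).
#' @param activity_noise_sd additive activity-level noise sd.
#' @param unreported_fraction probability that an episode is not
#'   self-reported (it still affects glucose and heart rate, but carries no
#'   label).
#' @param gap_rate CGM dropout events per day (Poisson).
#' @param gap_duration `c(low, high)` dropout duration, minutes.
#' @param seed integer seed governing every random draw of the generator.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, days_per_subject = 3, seed = 7)
#' cfg$exercise_rate
sim_config <- function(n_subjects = 10,
                       days_per_subject = 7,
                       cgm_interval = 5,
                       highrate_interval = 1,
                       weight_range = c(55, 95),
                       baseline_bg = c(mean = 140, sd = 20),
                       bg_drift = c(rate = 0.005, sd = 0.25),
                       meal_rate = 3,
                       meal_rise = c(40, 80),
                       meal_rise_duration = 45,
                       meal_decay_duration = 120,
                       exercise_rate = 1,
                       exercise_duration = c(10, 90),
                       exercise_intensity = c(3, 8),
                       glucose_drop_rate = 0.3,
                       glycemic_lag = 12,
                       post_exercise_decay = 45,
                       resting_hr = c(mean = 70, sd = 6),
                       hr_gain = 9,
                       hr_onset_tau = 2,
                       cgm_noise_sd = 5,
                       hr_noise_sd = 3,
                       activity_gain = 0.12,
                       activity_noise_sd = 0.02,
                       unreported_fraction = 0.1,
                       gap_rate = 0.2,
                       gap_duration = c(15, 120),
                       seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects, days_per_subject = days_per_subject,
    cgm_interval = cgm_interval, highrate_interval = highrate_interval,
    weight_range = weight_range, baseline_bg = unname(baseline_bg),
    bg_drift = unname(bg_drift), meal_rate = meal_rate,
    meal_rise = meal_rise, meal_rise_duration = meal_rise_duration,
    meal_decay_duration = meal_decay_duration,
    exercise_rate = exercise_rate, exercise_duration = exercise_duration,
    exercise_intensity = exercise_intensity,
    glucose_drop_rate = glucose_drop_rate, glycemic_lag = glycemic_lag,
    post_exercise_decay = post_exercise_decay,
    resting_hr = unname(resting_hr), hr_gain = hr_gain,
    hr_onset_tau = hr_onset_tau, cgm_noise_sd = cgm_noise_sd,
    hr_noise_sd = hr_noise_sd, activity_gain = activity_gain,
    activity_noise_sd = activity_noise_sd,
    unreported_fraction = unreported_fraction, gap_rate = gap_rate,
    gap_duration = gap_duration, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop_config(field, "must be a single positive number")
    }
  }
  nonneg <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop_config(field, "must be a single non-negative number")
    }
  }
  range2 <- function(field, lo_ok = -Inf) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v))) {
      stop_config(field, "must be a numeric c(low, high) pair")
    }
    if (v[1] > v[2]) stop_config(field, "must satisfy low <= high")
    if (v[1] < lo_ok) {
      stop_config(field, sprintf("must have low >= %g", lo_ok))
    }
  }

  for (f in c("n_subjects", "days_per_subject", "cgm_interval",
              "highrate_interval", "glycemic_lag", "post_exercise_decay",
              "meal_rise_duration", "meal_decay_duration", "hr_onset_tau")) {
    pos(f)
  }
  for (f in c("meal_rate", "exercise_rate", "gap_rate", "cgm_noise_sd",
              "hr_noise_sd", "activity_noise_sd", "glucose_drop_rate",
              "hr_gain", "activity_gain")) {
    nonneg(f)
  }
  range2("weight_range", lo_ok = 1)
  range2("meal_rise", lo_ok = 0)
  range2("exercise_duration", lo_ok = 1)
  range2("exercise_intensity", lo_ok = 1)
  range2("gap_duration", lo_ok = 1)
  if (cfg$exercise_intensity[2] > 10) {
    stop_config("exercise_intensity", "must lie within the 1-10 scale")
  }
  if (!is.numeric(cfg$baseline_bg) || length(cfg$baseline_bg) != 2 ||
    cfg$baseline_bg[1] <= 0 || cfg$baseline_bg[2] < 0) {
    stop_config("baseline_bg", "must be c(mean > 0, sd >= 0)")
  }
  if (!is.numeric(cfg$resting_hr) || length(cfg$resting_hr) != 2 ||
    cfg$resting_hr[1] <= 0 || cfg$resting_hr[2] < 0) {
    stop_config("resting_hr", "must be c(mean > 0, sd >= 0)")
  }
  if (!is.numeric(cfg$bg_drift) || length(cfg$bg_drift) != 2 ||
    cfg$bg_drift[1] < 0 || cfg$bg_drift[2] < 0) {
    stop_config("bg_drift", "must be c(rate >= 0, sd >= 0)")
  }
  if (cfg$unreported_fraction < 0 || cfg$unreported_fraction > 1) {
    stop_config("unreported_fraction", "must lie in [0, 1]")
  }
  if ((24 * 60) %% cfg$cgm_interval != 0) {
    stop_config("cgm_interval", "must divide 24 hours")
  }
  if (cfg$exercise_duration[2] >= 24 * 60) {
    stop_config("exercise_duration", "episodes must fit within one day")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d subjects x %g days; CGM every %g min, wearable every %g s\n",
    x$n_subjects, x$days_per_subject, x$cgm_interval, x$highrate_interval
  ))
  cat(sprintf(
    "  exercise: %g/day, %g-%g min, intensity %g-%g, %.0f%% unreported\n",
    x$exercise_rate, x$exercise_duration[1], x$exercise_duration[2],
    x$exercise_intensity[1], x$exercise_intensity[2],
    100 * x$unreported_fraction
  ))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
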