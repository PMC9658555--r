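# Independent brute-force oracles used by the tests. These deliberately
# transcribe the defining formulas term by term (loops, explicit sums) and
# share no code with the package implementations they check.

# Window features evaluated straight from the definitions.
brute_features <- function(bg, t, weight, hr = NULL) {
  delta_t <- t[2] - t[1]
  d <- bg[15] - bg[1]
  dp <- numeric(14)
  for (i in 0:13) dp[i + 1] <- bg[i + 2] - bg[i + 1]
  dpp <- numeric(3)
  for (i in 0:2) {
    acc <- 0
    for (j in 0:3) acc <- acc + bg[5 * i + j + 2] - bg[5 * i + j + 1]
    dpp[i + 1] <- acc
  }
  v <- (bg[15] - bg[1]) / (t[15] - t[1])
  vp <- numeric(14)
  for (i in 0:13) vp[i + 1] <- (bg[i + 2] - bg[i + 1]) / (t[i + 2] - t[i + 1])
  vpp <- numeric(3)
  for (i in 0:2) vpp[i + 1] <- dpp[i + 1] / (t[5 * i + 5] - t[5 * i + 1])
  ap <- numeric(13)
  for (i in 0:12) {
    ap[i + 1] <- (bg[i + 3] - bg[i + 1]) / (t[i + 3] - t[i + 1])^2
  }
  out <- c(weight, d, dp, dpp, v, vp, vpp, ap)
  if (!is.null(hr)) out <- c(out, hr[15], hr[15] - hr[14])
  out
}

# AUC as the pairwise concordance probability (ties count half).
brute_auc <- function(y_true, scores) {
  pos <- scores[y_true == 1]
  neg <- scores[y_true == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Half-open interval membership by direct enumeration.
brute_labels <- function(grid_min, starts, durations) {
  out <- integer(length(grid_min))
  for (i in seq_along(grid_min)) {
    for (k in seq_along(starts)) {
      if (grid_min[i] >= starts[k] &&
        grid_min[i] < starts[k] + durations[k]) {
        out[i] <- 1L
      }
    }
  }
  out
}

# A small noise-free configuration: mechanism only, no meals, no drift,
# no gaps, everything reported.
noisefree_config <- function(...) {
  args <- list(
    baseline_bg = c(140, 0), bg_drift = c(0.005, 0),
    meal_rate = 0, cgm_noise_sd = 0, hr_noise_sd = 0,
    activity_noise_sd = 0, resting_hr = c(70, 0),
    unreported_fraction = 0, gap_rate = 0
  )
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}

# Truth-derived episode membership for a subject bundle's CGM grid.
truth_membership <- function(bundle) {
  t_min <- as.numeric(bundle$series$records$time) / 60
  starts <- as.numeric(bundle$truth$start_time) / 60
  brute_labels(t_min, starts, bundle$truth$duration)
}
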