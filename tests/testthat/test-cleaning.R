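grid_at <- function(start, n, by_min = 5) {
  as.POSIXct(start, tz = "UTC") + (0:(n - 1)) * by_min * 60
}

test_that("exercise labels follow the half-open episode interval", {
  grid <- grid_at("2023-01-02 09:00:00", 24) # 09:00 .. 10:55
  events <- data.frame(
    time = as.POSIXct("2023-01-02 10:00:00", tz = "UTC"),
    intensity = 5, duration = 30
  )
  labels <- label_exercise(grid, events)
  # oracle: direct enumeration over the half-open interval
  expected <- brute_labels(
    as.numeric(grid) / 60,
    as.numeric(events$time) / 60, events$duration
  )
  expect_identical(labels, expected)
  # 1 exactly at 10:00..10:25, 0 again at 10:30
  on <- format(grid[labels == 1], "%H:%M", tz = "UTC")
  expect_identical(on, c("10:00", "10:05", "10:10", "10:15", "10:20", "10:25"))
})

test_that("low-intensity reports and absent events produce no labels", {
  grid <- grid_at("2023-01-02 09:00:00", 12)
  low <- data.frame(
    time = as.POSIXct("2023-01-02 09:10:00", tz = "UTC"),
    intensity = 1, duration = 30
  )
  expect_true(all(label_exercise(grid, low) == 0))
  expect_true(all(label_exercise(grid, NULL) == 0))
  # missing duration: warned about and treated as label 0
  bad <- data.frame(
    time = as.POSIXct("2023-01-02 09:10:00", tz = "UTC"),
    intensity = 5, duration = NA_real_
  )
  expect_warning(labels <- label_exercise(grid, bad), "invalid duration")
  expect_true(all(labels == 0))
})

make_series <- function(days = 3, episode_days = 2, gap_day = NULL,
                        with_hr = TRUE) {
  # full 5-min coverage, an episode 10:00-10:30 on the given days,
  # optionally a 3 h gap on one day
  recs <- list()
  for (d in seq_len(days)) {
    times <- grid_at(sprintf("2023-01-0%d 00:00:00", d + 1), 288)
    ex <- integer(288)
    if (d %in% episode_days) ex[121:126] <- 1L # 10:00..10:25
    keep <- rep(TRUE, 288)
    if (!is.null(gap_day) && d == gap_day) keep[145:180] <- FALSE # 3 h gap
    recs[[d]] <- data.frame(
      time = times[keep],
      bg_mgdl = 120 + numeric(sum(keep)),
      hr_bpm = if (with_hr) 72L else NA_integer_,
      exercise = ex[keep]
    )
  }
  subject_series("T01", 70, do.call(rbind, recs))
}

test_that("day blocks keep only exercise days with adequate CGM", {
  s <- make_series(days = 3, episode_days = 2)
  blocks <- extract_day_blocks(s, cleaning_config())
  expect_length(blocks, 1)
  expect_identical(format(blocks[[1]]$date), "2023-01-03")
  expect_equal(nrow(blocks[[1]]$records), 288)
  expect_true(blocks[[1]]$has_hr)
})

test_that("a day with a reported episode but a 3 h CGM gap is excluded", {
  s <- make_series(days = 3, episode_days = c(2, 3), gap_day = 3)
  blocks <- extract_day_blocks(s, cleaning_config())
  expect_length(blocks, 1)
  expect_identical(format(blocks[[1]]$date), "2023-01-03")
  # direct coverage count confirms the exclusion reason
  s3 <- s$records[as.Date(s$records$time, tz = "UTC") == "2023-01-04", ]
  expect_lt(nrow(s3) / 288, 1)
  expect_gt(max(diff(as.numeric(s3$time)) / 60), cleaning_config()$max_gap)
})

test_that("require_hr drops blocks lacking heart rate", {
  s <- make_series(days = 2, episode_days = 1:2, with_hr = FALSE)
  expect_length(extract_day_blocks(s, cleaning_config(require_hr = TRUE)), 0)
  expect_length(extract_day_blocks(s, cleaning_config()), 2)
})

test_that("tightening the cleaning thresholds never adds blocks or labels", {
  cfg <- sim_config(n_subjects = 3, days_per_subject = 5, seed = 61)
  coh <- generate_cohort(cfg, highrate = FALSE)
  for (sub in coh) {
    loose <- extract_day_blocks(sub$series, cleaning_config(
      min_day_coverage = 0.8
    ))
    tight <- extract_day_blocks(sub$series, cleaning_config(
      min_day_coverage = 0.97
    ))
    expect_lte(length(tight), length(loose))
  }
  # raising min_intensity cannot create positives
  grid <- grid_at("2023-01-02 09:00:00", 48)
  events <- data.frame(
    time = grid_at("2023-01-02 09:30:00", 3, 60),
    intensity = c(2, 5, 8), duration = c(20, 20, 20)
  )
  lab2 <- label_exercise(grid, events, cleaning_config(min_intensity = 2))
  lab6 <- label_exercise(grid, events, cleaning_config(min_intensity = 6))
  expect_true(all(lab6 <= lab2))
})

test_that("cleaning a cleaned series is a no-op", {
  cfg <- sim_config(n_subjects = 1, days_per_subject = 5, seed = 71)
  s <- generate_subject(cfg, 1, highrate = FALSE)$series
  blocks <- extract_day_blocks(s, cleaning_config())
  skip_if(length(blocks) == 0, "no retained day in this draw")
  once <- do.call(rbind, lapply(blocks, `[[`, "records"))
  s2 <- subject_series(s$subject_id, s$weight, once)
  blocks2 <- extract_day_blocks(s2, cleaning_config())
  twice <- do.call(rbind, lapply(blocks2, `[[`, "records"))
  rownames(once) <- rownames(twice) <- NULL
  expect_identical(twice, once)
})

test_that("wearable aggregation averages per interval and labels strictly
          above the activity threshold", {
  grid <- grid_at("2023-01-02 08:00:00", 3)
  base <- as.POSIXct("2023-01-02 08:00:00", tz = "UTC")
  # interval 1: constant 80 bpm, activity alternating 0.1/0.4 (mean 0.25)
  # interval 2: activity exactly 0.2 throughout
  stream <- data.frame(
    time = base + c(1:300, 301:600),
    hr_bpm = c(rep(80, 300), rep(95, 300)),
    activity = c(rep(c(0.1, 0.4), 150), rep(0.2, 300))
  )
  agg <- aggregate_highrate(stream, grid)
  expect_equal(agg$n_samples, c(0L, 300L, 300L))
  expect_true(agg$empty[1]) # no interval opens before the first registration
  expect_equal(agg$hr_bpm[2:3], c(80L, 95L))
  expect_equal(agg$activity[2:3], c(0.25, 0.2))
  expect_equal(agg$exercise, c(0L, 1L, 0L)) # strict "higher than 0.2"
})

test_that("intervals without samples are flagged and leave HR absent", {
  grid <- grid_at("2023-01-02 08:00:00", 4)
  base <- as.POSIXct("2023-01-02 08:00:00", tz = "UTC")
  stream <- data.frame(
    # samples only in (t2, t3], which closes at registration 3
    time = base + 301:600,
    hr_bpm = rep(77, 300), activity = rep(0.05, 300)
  )
  agg <- aggregate_highrate(stream, grid)
  expect_identical(agg$empty, c(TRUE, TRUE, FALSE, TRUE))
  expect_identical(is.na(agg$hr_bpm), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(agg$hr_bpm[3], 77L)
  # a single sample in an interval is accepted; (t3, t4] closes at row 4
  one <- data.frame(
    time = base + 750, hr_bpm = 99,
    activity = 0.5
  )
  agg1 <- aggregate_highrate(one, grid)
  expect_equal(agg1$hr_bpm[4], 99L)
  expect_equal(agg1$exercise[4], 1L)
})

test_that("labels recovered from a clean simulation equal the ground truth", {
  cfg <- noisefree_config(n_subjects = 2, days_per_subject = 4, seed = 91)
  coh <- generate_cohort(cfg, highrate = FALSE)
  for (sub in coh) {
    expect_identical(
      sub$series$records$exercise,
      truth_membership(sub)
    )
  }
})
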