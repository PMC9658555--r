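ohio_fixture <- function(path, body) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>', body, ""
  ), path)
  path
}

test_that("a hand-written Ohio fixture parses with the expected counts", {
  path <- withr::local_tempfile(fileext = ".xml")
  ohio_fixture(path, c(
    '<patient id="P1" weight="71.5">',
    "  <glucose_level>",
    '    <event ts="07-01-2023 00:00:00" value="120.0"/>',
    '    <event ts="07-01-2023 00:05:00" value="122.5"/>',
    '    <event ts="07-01-2023 00:10:00" value="121.0"/>',
    "  </glucose_level>",
    "  <exercise>",
    '    <event ts="07-01-2023 10:00:00" intensity="5" type="run"',
    '           duration="30" competitive="No"/>',
    "  </exercise>",
    "</patient>"
  ))
  raw <- read_ohio_subject(path)
  expect_equal(nrow(raw$glucose_events), 3)
  expect_equal(nrow(raw$exercise_events), 1)
  expect_equal(raw$exercise_events$intensity, 5)
  expect_equal(raw$exercise_events$duration, 30)
  expect_equal(raw$weight, 71.5)
  # no basis_heart_rate section: empty events, not failure
  expect_equal(nrow(raw$hr_events), 0)
})

test_that("missing weight and malformed XML are explicit errors", {
  p1 <- withr::local_tempfile(fileext = ".xml")
  ohio_fixture(p1, c(
    '<patient id="P1">',
    "  <glucose_level/>",
    "</patient>"
  ))
  expect_error(read_ohio_subject(p1), "weight unavailable")

  p2 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<patient><glucose_level>", p2)
  expect_error(read_ohio_subject(p2), "malformed XML")

  expect_error(read_ohio_subject("no/such/file.xml"), "not found")
})

test_that("the reader sorts events regardless of document order", {
  path <- withr::local_tempfile(fileext = ".xml")
  ohio_fixture(path, c(
    '<patient id="P1" weight="70">',
    "  <glucose_level>",
    '    <event ts="07-01-2023 00:10:00" value="121.0"/>',
    '    <event ts="07-01-2023 00:00:00" value="120.0"/>',
    '    <event ts="07-01-2023 00:05:00" value="122.5"/>',
    "  </glucose_level>",
    "</patient>"
  ))
  raw <- read_ohio_subject(path)
  expect_equal(raw$glucose_events$value, c(120, 122.5, 121))
})

test_that("both timestamp dialects parse to the same instants", {
  p1 <- withr::local_tempfile(fileext = ".xml")
  ohio_fixture(p1, c(
    '<patient id="A" weight="70">',
    '  <glucose_level><event ts="2023-01-07 08:30:00" value="100"/>',
    "  </glucose_level>",
    "</patient>"
  ))
  p2 <- withr::local_tempfile(fileext = ".xml")
  ohio_fixture(p2, c(
    '<patient id="B" weight="70">',
    '  <glucose_level><event ts="07-01-2023 08:30:00" value="100"/>',
    "  </glucose_level>",
    "</patient>"
  ))
  t1 <- read_ohio_subject(p1)$glucose_events$time
  t2 <- read_ohio_subject(p2)$glucose_events$time
  expect_identical(as.numeric(t1), as.numeric(t2))
})

test_that("a simulator-written 2-day archive yields 576 glucose events", {
  cfg <- sim_config(
    n_subjects = 1, days_per_subject = 2, gap_rate = 0,
    seed = 8
  )
  bundle <- generate_subject(cfg, 1, highrate = FALSE)
  path <- withr::local_tempfile(fileext = ".xml")
  write_ohio_xml(bundle, path)
  raw <- read_ohio_subject(path)
  expect_equal(nrow(raw$glucose_events), 2 * 24 * 12)
  expect_equal(nrow(raw$hr_events), 2 * 24 * 12)
  # reassembled series reproduces the simulated labels
  ser <- ohio_series(raw)
  expect_identical(ser$records$exercise, bundle$series$records$exercise)
  expect_identical(ser$records$hr_bpm, bundle$series$records$hr_bpm)
  expect_lt(max(abs(ser$records$bg_mgdl - bundle$series$records$bg_mgdl)),
    0.05 + 1e-9
  )
})

test_that("D1namo-style folders parse rows, units and the 1 Hz stream", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "date,time,glucose,type",
    "2014-10-01,08:00:00,5.5,cgm",
    "2014-10-01,08:05:00,5.7,cgm",
    "2014-10-01,08:02:00,6.1,manual",
    "2014-10-01,badtime,9.9,cgm"
  ), file.path(dir, "glucose.csv"))
  sensor_times <- format(
    as.POSIXct("2014-10-01 08:00:01", tz = "UTC") + 0:299,
    "%Y-%m-%d %H:%M:%S"
  )
  writeLines(
    c("datetime,hr,activity", paste0(sensor_times, ",80,0.05")),
    file.path(dir, "sensor.csv")
  )
  expect_message(raw <- read_d1namo_subject(dir), "skipped 1")
  expect_equal(nrow(raw$glucose_events), 3)
  expect_true(all(raw$glucose_events$unit == "mmol/L"))
  expect_setequal(raw$glucose_events$type, c("cgm", "manual"))
  # ~300 wearable samples between two registrations
  expect_equal(nrow(raw$highrate_stream), 300)

  ser <- d1namo_series(raw, weight = 65)
  expect_equal(nrow(ser$records), 2) # manual row excluded from the grid
  expect_equal(ser$records$bg_mgdl, c(5.5, 5.7) * 18.0182)
  expect_equal(ser$records$hr_bpm[2], 80L)
  expect_identical(ser$unit_system, "converted_mmol/L")
  # opting out of unit conversion keeps mmol/L
  ser2 <- d1namo_series(raw, unit_convert = FALSE, weight = 65)
  expect_equal(ser2$records$bg_mgdl, c(5.5, 5.7))
})

test_that("an empty sensor CSV still reads, with an empty stream", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "date,time,glucose,type",
    "2014-10-01,08:00:00,5.5,cgm"
  ), file.path(dir, "glucose.csv"))
  writeLines("datetime,hr,activity", file.path(dir, "sensor.csv"))
  raw <- read_d1namo_subject(dir)
  expect_equal(nrow(raw$highrate_stream), 0)
  expect_error(
    read_d1namo_subject(withr::local_tempdir()),
    "glucose CSV not found"
  )
})

test_that("missing columns raise schema errors naming the column", {
  dir <- withr::local_tempdir()
  writeLines(c("date,time,glucose", "2014-10-01,08:00:00,5.5"),
    file.path(dir, "glucose.csv")
  )
  writeLines("datetime,hr,activity", file.path(dir, "sensor.csv"))
  expect_error(read_d1namo_subject(dir), "'type'")
})

test_that("the cleaned interchange format round-trips losslessly", {
  cfg <- sim_config(n_subjects = 1, days_per_subject = 2, seed = 19)
  s <- generate_subject(cfg, 1, highrate = FALSE)$series
  path <- withr::local_tempfile(fileext = ".csv")
  write_cleaned(s, path)
  s2 <- read_cleaned(path)
  expect_identical(s2$subject_id, s$subject_id)
  expect_equal(s2$weight, s$weight)
  expect_identical(s2$unit_system, s$unit_system)
  expect_equal(as.numeric(s2$records$time), as.numeric(s$records$time))
  expect_equal(s2$records$bg_mgdl, s$records$bg_mgdl)
  expect_identical(s2$records$hr_bpm, s$records$hr_bpm)
  expect_identical(s2$records$exercise, s$records$exercise)

  # absent HR stays absent through the round trip
  s$records$hr_bpm <- rep(NA_integer_, nrow(s$records))
  write_cleaned(s, path)
  s3 <- read_cleaned(path)
  expect_true(all(is.na(s3$records$hr_bpm)))

  expect_error(read_cleaned("no/such/file.csv"), "not found")
})
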