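#!/usr/bin/env Rscript
# Build the FS1 (50-dim, CGM-only) and FS2 (52-dim, CGM + HR) design
# matrices from the cleaned interchange files and write them as CSV, one
# row per registration in chronological order, with subject, timestamp and
# label columns. Warm-up rows (the first 14 of every day block) are
# zero-padded.
#
# Run after 02_ingest_clean.R.

suppressPackageStartupMessages(library(exdetect))

clean_dir <- "results/cleaned"
feat_dir <- "results/features"
dir.create(feat_dir, recursive = TRUE, showWarnings = FALSE)
cfg <- cleaning_config(require_hr = TRUE)

cohort_blocks <- function(prefix) {
  files <- list.files(clean_dir,
    pattern = paste0("^", prefix, "_.*[.]csv$"),
    full.names = TRUE
  )
  unlist(
    lapply(files, function(f) extract_day_blocks(read_cleaned(f), cfg)),
    recursive = FALSE
  )
}

for (cohort in c("ohio", "d1namo")) {
  blocks <- cohort_blocks(cohort)
  for (fs in c("fs1", "fs2")) {
    dm <- featurize_blocks(blocks, include_hr = fs == "fs2")
    out <- data.frame(
      subject = dm$meta$subject_id,
      timestamp = format(dm$meta$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      dm$X,
      label = dm$y,
      check.names = FALSE
    )
    path <- file.path(feat_dir, sprintf("%s_%s.csv", cohort, fs))
    utils::write.csv(out, path, row.names = FALSE)
    message(sprintf(
      "%s %s: %d rows x %d features, %d positive (%d warm-up rows padded)",
      cohort, toupper(fs), nrow(dm$X), ncol(dm$X), sum(dm$y),
      sum(dm$meta$padded)
    ))
  }
}
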