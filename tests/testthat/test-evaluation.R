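test_that("metrics match a hand-computed confusion", {
  # TP=3, FN=1, TN=4, FP=2
  y_true <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  y_pred <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  m <- compute_metrics(y_true, y_pred)
  expect_equal(unname(m$counts), c(3, 4, 2, 1)) # TP TN FP FN
  expect_equal(unname(m$metrics[["ACC"]]), 0.7)
  expect_equal(unname(m$metrics[["TPR"]]), 0.75)
  expect_equal(unname(m$metrics[["TNR"]]), 4 / 6)
  expect_equal(unname(m$metrics[["PPV"]]), 0.6)
  expect_equal(unname(m$metrics[["FPR"]]), 1 / 3)
  expect_equal(unname(m$metrics[["F1"]]), 6 / 9)
  expect_length(m$degenerate, 0)
})

test_that("perfect predictions and degenerate confusions behave as
          documented", {
  y <- c(1, 1, 0, 0, 0)
  p <- compute_metrics(y, y)
  expect_equal(unname(p$metrics[c("ACC", "TPR", "TNR", "PPV", "F1")]),
    rep(1, 5)
  )
  expect_equal(unname(p$metrics[["FPR"]]), 0)

  # all-negative predictions: TP = FP = 0, PPV and F1 reported 0 + flagged
  d <- compute_metrics(c(1, 1, 0, 0), c(0, 0, 0, 0))
  expect_equal(unname(d$metrics[["PPV"]]), 0)
  expect_equal(unname(d$metrics[["F1"]]), 0)
  expect_true(all(c("PPV", "F1") %in% d$degenerate))

  expect_error(compute_metrics(c(1, 0), c(1, 0, 0)), "differ")
  expect_error(compute_metrics(c(1, 2), c(1, 0)), "binary")
})

test_that("metric identities hold on random confusions", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    y <- as.integer(runif(n) < runif(1, 0.2, 0.8))
    p <- as.integer(runif(n) < runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    m <- compute_metrics(y, p)
    mm <- m$metrics
    expect_equal(unname(mm[["FPR"]]), 1 - mm[["TNR"]], tolerance = 1e-12)
    if (!any(c("PPV", "TPR", "F1") %in% m$degenerate) &&
      (mm[["PPV"]] + mm[["TPR"]]) > 0) {
      expect_equal(
        unname(mm[["F1"]]),
        2 * mm[["PPV"]] * mm[["TPR"]] / (mm[["PPV"]] + mm[["TPR"]]),
        tolerance = 1e-12
      )
    }
  }
})

test_that("ROC handles the canonical small cases", {
  # hand case: concordant pairs 3 of 4
  r <- roc_curve(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(r$auc, 0.75)
  # perfect scorer
  y <- c(rep(1, 5), rep(0, 5))
  expect_equal(roc_curve(y, y)$auc, 1.0)
  # constant scorer is uninformative
  expect_equal(roc_curve(y, rep(0.3, 10))$auc, 0.5)
  expect_error(roc_curve(rep(1, 4), runif(4)), "both classes")
})

test_that("ROC points are monotone from (0,0) to (1,1) and AUC equals
          brute-force concordance", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    y <- as.integer(runif(n) < 0.4)
    if (length(unique(y)) < 2) next
    # rounded scores force ties across and within classes
    s <- round(runif(n), 1)
    r <- roc_curve(y, s)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(r$points$fpr[nrow(r$points)], 1)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(r$auc, brute_auc(y, s), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- as.integer(runif(150) < 0.5)
  s <- runif(150) + 0.5 * y
  ours <- roc_curve(y, s)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the Youden threshold maximizes TPR - FPR", {
  set.seed(15)
  y <- as.integer(runif(400) < 0.3)
  s <- runif(400) + y
  r <- roc_curve(y, s)
  thr <- youden_threshold(r)
  j_at <- function(th) {
    p <- as.integer(s >= th)
    m <- compute_metrics(y, p)$metrics
    m[["TPR"]] - m[["FPR"]]
  }
  best <- max(vapply(unique(s), j_at, 0))
  expect_equal(j_at(thr), best, tolerance = 1e-12)
})

split_fixture <- function(n = 100, subjects = c("A", "B")) {
  set.seed(16)
  meta <- data.frame(
    subject_id = rep(subjects, length.out = n),
    time = as.POSIXct("2023-01-02", tz = "UTC") + seq_len(n) * 300
  )
  list(
    X = matrix(rnorm(n * 4), n, 4),
    y = rep(c(0L, 0L, 1L, 0L), length.out = n),
    meta = meta
  )
}

test_that("splits produce 75/25 with the documented structure", {
  d <- split_fixture()
  cfg <- use_case_config(1, "fs1", split_mode = "chronological")
  parts <- split_train_test(d$X, d$y, d$meta, cfg)
  expect_equal(length(parts$train$y), 76) # ceil(0.75 * 50) per subject
  expect_equal(length(parts$train$y) + length(parts$test$y), 100)
  # chronological: all training timestamps precede test timestamps
  for (s in c("A", "B")) {
    tr <- parts$train$meta$time[parts$train$meta$subject_id == s]
    te <- parts$test$meta$time[parts$test$meta$subject_id == s]
    expect_lt(max(as.numeric(tr)), min(as.numeric(te)))
  }

  one <- split_fixture(100, subjects = "A")
  p1 <- split_train_test(one$X, one$y, one$meta, cfg)
  expect_equal(length(p1$train$y), 75)
  expect_equal(length(p1$test$y), 25)
})

test_that("random splits are stratified, seeded and reproducible", {
  d <- split_fixture(200)
  cfg <- use_case_config(1, "fs1", split_mode = "random", seed = 99)
  p1 <- split_train_test(d$X, d$y, d$meta, cfg)
  p2 <- split_train_test(d$X, d$y, d$meta, cfg)
  expect_identical(p1$train$y, p2$train$y)
  expect_identical(rownames(p1$train$meta), rownames(p2$train$meta))
  # stratification: positive fraction preserved up to rounding
  expect_equal(sum(p1$train$y), ceiling(0.75 * sum(d$y)))
  cfg2 <- use_case_config(1, "fs1", split_mode = "random", seed = 100)
  p3 <- split_train_test(d$X, d$y, d$meta, cfg2)
  expect_false(identical(rownames(p1$train$meta), rownames(p3$train$meta)))
})

test_that("use-case configs enforce the source invariants", {
  expect_error(use_case_config(5, "fs2", "A", "A"), "differ")
  expect_error(use_case_config(2, "fs1", "A", "B"), "equal")
  expect_error(use_case_config(7, "fs1"), "1..5")
  expect_silent(use_case_config(5, "fs2", "ohio", "d1namo"))
})

test_that("a use-case run reports all 14 models on a synthetic cohort", {
  cfg <- sim_config(n_subjects = 3, days_per_subject = 6, seed = 23)
  coh <- generate_cohort(cfg, highrate = FALSE)
  blocks <- unlist(
    lapply(coh, function(s) extract_day_blocks(s$series, cleaning_config())),
    recursive = FALSE
  )
  uc <- use_case_config(1, "fs2", seed = 23)
  res <- run_use_case(uc, blocks)
  expect_equal(nrow(res$table), 14)
  expect_identical(
    res$table$model,
    vapply(classifier_registry(), `[[`, "", "label")
  )
  expect_true(all(res$table$AUC >= 0 & res$table$AUC <= 1))
  expect_length(res$roc, 14)
  expect_equal(res$counts$n_train + res$counts$n_test, length(
    featurize_blocks(blocks, include_hr = TRUE)$y
  ))

  # FS2 without HR is refused
  blocks_nohr <- lapply(blocks, function(b) {
    b$records$hr_bpm <- NA_integer_
    b$has_hr <- FALSE
    b
  })
  expect_error(run_use_case(uc, blocks_nohr), "heart rate")
})
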