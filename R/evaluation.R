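# Confusion-matrix metrics, ROC/AUC, train/test splitting and the use-case
# driver that produces one result table per classifier suite run.

#' Confusion counts and classification metrics
#'
#' Computes TP/TN/FP/FN and the standard binary metrics: accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, recall/sensitivity `TPR = TP/(TP+FN)`,
#' specificity `TNR = TN/(TN+FP)`, precision `PPV = TP/(TP+FP)`,
#' `FPR = FP/(TN+FP)`, and the F1 (Dice) score `2TP/(2TP+FP+FN)`. Ratios
#' with a zero denominator are reported as 0 and named in the `degenerate`
#' field.
#'
#' @param y_true binary 0/1 truth vector.
#' @param y_pred binary 0/1 prediction vector of equal length.
#' @return list with `counts` (named TP/TN/FP/FN), `metrics` (named numeric:
#'   ACC, TPR, TNR, PPV, FPR, F1), and `degenerate` (character vector of
#'   zero-denominator metrics).
#' @export
#' @examples
#' m <- compute_metrics(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
#'   c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0))
#' m$metrics[["ACC"]] # 0.7
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)

  degenerate <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  metrics <- c(
    ACC = ratio(tp + tn, tp + tn + fp + fn, "ACC"),
    TPR = ratio(tp, tp + fn, "TPR"),
    TNR = ratio(tn, tn + fp, "TNR"),
    PPV = ratio(tp, tp + fp, "PPV"),
    FPR = ratio(fp, tn + fp, "FPR"),
    F1 = ratio(2 * tp, 2 * tp + fp + fn, "F1")
  )
  # undefined precision makes the harmonic F1 undefined too, even though
  # the direct formula evaluates to 0: flag both
  if (tp + fp == 0 && !"F1" %in% degenerate) {
    degenerate <- c(degenerate, "F1")
  }
  list(
    counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
    metrics = metrics,
    degenerate = degenerate
  )
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct score values (ties
#' grouped), yielding monotone (FPR, TPR) points from (0, 0) to (1, 1), and
#' integrates the area under the curve by the trapezoidal rule. The AUC
#' equals the probability that a random positive outscores a random
#' negative (ties counted half).
#'
#' @param y_true binary 0/1 truth vector containing both classes.
#' @param scores numeric scores, higher = more likely positive.
#' @return object of class `roc_curve`: list with `points`
#'   (`data.frame(threshold, fpr, tpr)`) and `auc`.
#' @export
roc_curve <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    stop("y_true and scores lengths differ", call. = FALSE)
  }
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes in y_true", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y_true[ord]
  # group tied scores: cumulative counts at the last index of each tie group
  last <- which(!duplicated(s, fromLast = TRUE))
  cum_tp <- cumsum(y == 1)[last]
  cum_fp <- cumsum(y == 0)[last]
  points <- data.frame(
    threshold = c(Inf, s[last]),
    fpr = c(0, cum_fp / n_neg),
    tpr = c(0, cum_tp / n_pos)
  )
  auc <- sum(diff(points$fpr) *
    (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "<roc_curve> %d thresholds, AUC = %.4f\n",
    nrow(x$points) - 1, x$auc
  ))
  invisible(x)
}

#' Youden-optimal threshold of a ROC curve
#'
#' Returns the threshold maximizing TPR - FPR (Youden's J). The default
#' operating point of the pipeline is the learner's 0.5 score threshold;
#' this is the optional ROC-derived alternative.
#'
#' @param roc a [roc_curve()].
#' @return the threshold (numeric scalar).
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  p <- roc$points[-1, ] # drop the (0,0) sentinel with threshold Inf
  p$threshold[which.max(p$tpr - p$fpr)]
}

#' Use-case configuration
#'
#' Describes one evaluation protocol: which feature set, which source
#' cohorts, and how to split. Use-cases 1--4 evaluate one cohort with an
#' internal 75/25 split (chronological per subject by default, preventing
#' leakage between overlapping windows; seeded stratified random available);
#' use-case 5 trains on one cohort and tests on another in full.
#'
#' @param id use-case id, 1 to 5.
#' @param feature_set `"fs1"` (CGM only) or `"fs2"` (CGM + HR).
#' @param train_source,test_source dataset tags; must coincide for ids 1--4
#'   and differ for id 5.
#' @param split_fraction training fraction for the internal split.
#' @param split_mode `"chronological"` or `"random"`.
#' @param seed seed for the random split mode and fit-time randomness.
#' @return object of class `use_case_config`.
#' @export
use_case_config <- function(id, feature_set = c("fs1", "fs2"),
                            train_source = "cohort",
                            test_source = train_source,
                            split_fraction = 0.75,
                            split_mode = c("chronological", "random"),
                            seed = 1L) {
  feature_set <- match.arg(feature_set)
  split_mode <- match.arg(split_mode)
  if (!id %in% 1:5) stop_config("id", "must be 1..5")
  if (id <= 4 && !identical(train_source, test_source)) {
    stop_config("test_source", "must equal train_source for use-cases 1-4")
  }
  if (id == 5 && identical(train_source, test_source)) {
    stop_config("test_source", "must differ from train_source for use-case 5")
  }
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop_config("split_fraction", "must lie in (0, 1)")
  }
  structure(
    list(
      id = id, feature_set = feature_set,
      train_source = train_source, test_source = test_source,
      split_fraction = split_fraction, split_mode = split_mode,
      seed = as.integer(seed)
    ),
    class = "use_case_config"
  )
}

#' Split a design matrix into train and test parts
#'
#' Chronological mode takes the earliest `split_fraction` of rows per
#' subject (train sizes rounded up), so every training timestamp precedes
#' every test timestamp within a subject. Random mode draws a seeded,
#' label-stratified sample. Errors if either part ends up single-class.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param meta `data.frame` with `subject_id` and `time` columns (as from
#'   [featurize_blocks()]).
#' @param config a [use_case_config()].
#' @return list with `train` and `test`, each holding `X`, `y`, `meta`.
#' @export
split_train_test <- function(X, y, meta, config) {
  stopifnot(inherits(config, "use_case_config"))
  n <- nrow(X)
  if (n != length(y) || n != nrow(meta)) {
    stop("X, y and meta sizes differ", call. = FALSE)
  }
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least 2 rows per class to split", call. = FALSE)
  }
  if (config$split_mode == "chronological") {
    train_idx <- integer(0)
    for (s in unique(meta$subject_id)) {
      rows <- which(meta$subject_id == s)
      rows <- rows[order(meta$time[rows])]
      k <- ceiling(config$split_fraction * length(rows))
      train_idx <- c(train_idx, rows[seq_len(k)])
    }
    train_idx <- sort(train_idx)
  } else {
    train_idx <- with_substream(config$seed, {
      picks <- lapply(c(0, 1), function(cl) {
        rows <- which(y == cl)
        sample(rows, ceiling(config$split_fraction * length(rows)))
      })
      sort(unlist(picks))
    })
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(unique(y[train_idx])) < 2 || length(unique(y[test_idx])) < 2) {
    stop("degenerate split: a part contains a single class", call. = FALSE)
  }
  list(
    train = list(
      X = X[train_idx, , drop = FALSE], y = y[train_idx],
      meta = meta[train_idx, , drop = FALSE]
    ),
    test = list(
      X = X[test_idx, , drop = FALSE], y = y[test_idx],
      meta = meta[test_idx, , drop = FALSE]
    )
  )
}

#' Run one use-case over the full classifier suite
#'
#' Featurizes the cleaned day blocks (all subjects pooled), applies the
#' use-case's split protocol (internal 75/25 for ids 1--4; train-cohort /
#' test-cohort for id 5), fits every registry model, and evaluates on the
#' test rows: metrics at the 0.5 score threshold plus the ROC curve and
#' AUC.
#'
#' @param config a [use_case_config()].
#' @param blocks_train list of day blocks of the training cohort.
#' @param blocks_test list of day blocks of the test cohort (use-case 5
#'   only; ignored with ids 1--4).
#' @param models `"all"` or a character vector of spec ids/labels.
#' @param standardize,balance passed to [fit_classifier()].
#' @param warmup warm-up row policy passed to [featurize_blocks()].
#' @return object of class `use_case_result`: list with `table` (one row per
#'   model: ACC, TPR, TNR, PPV, FPR, F1, AUC), `roc` (named list of
#'   [roc_curve()] objects), `config`, and `counts` (train/test sizes and
#'   class balance).
#' @export
run_use_case <- function(config, blocks_train, blocks_test = NULL,
                         models = "all", standardize = FALSE,
                         balance = TRUE, warmup = "zero_pad") {
  stopifnot(inherits(config, "use_case_config"))
  include_hr <- config$feature_set == "fs2"
  if (include_hr) {
    has_hr <- vapply(blocks_train, `[[`, TRUE, "has_hr")
    if (!all(has_hr)) {
      stop("FS2 requested but some training blocks lack heart rate",
        call. = FALSE
      )
    }
  }
  dm <- featurize_blocks(blocks_train, include_hr = include_hr,
    warmup = warmup
  )
  if (config$id == 5) {
    if (is.null(blocks_test)) {
      stop("use-case 5 requires a test cohort", call. = FALSE)
    }
    dm_test <- featurize_blocks(blocks_test, include_hr = include_hr,
      warmup = warmup
    )
    train <- dm
    test <- dm_test
  } else {
    parts <- split_train_test(dm$X, dm$y, dm$meta, config)
    train <- parts$train
    test <- parts$test
  }

  specs <- if (identical(models, "all")) {
    classifier_registry(config$seed)
  } else {
    lapply(models, classifier_spec, seed = config$seed)
  }

  rows <- list()
  rocs <- list()
  for (spec in specs) {
    model <- fit_classifier(spec, train$X, train$y,
      standardize = standardize, balance = balance
    )
    s <- score_classifier(model, test$X)
    pred <- as.integer(s >= 0.5)
    m <- compute_metrics(test$y, pred)
    roc <- roc_curve(test$y, s)
    rocs[[spec$label]] <- roc
    rows[[spec$label]] <- data.frame(
      model = spec$label,
      ACC = m$metrics[["ACC"]], TPR = m$metrics[["TPR"]],
      TNR = m$metrics[["TNR"]], PPV = m$metrics[["PPV"]],
      FPR = m$metrics[["FPR"]], F1 = m$metrics[["F1"]],
      AUC = roc$auc
    )
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  structure(
    list(
      table = table,
      roc = rocs,
      config = config,
      counts = list(
        n_train = length(train$y),
        n_test = length(test$y),
        train_pos = sum(train$y == 1),
        test_pos = sum(test$y == 1)
      )
    ),
    class = "use_case_result"
  )
}

#' @export
print.use_case_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<use_case_result> use-case %d, %s, %s split; %d train / %d test rows\n",
    cfg$id, toupper(cfg$feature_set), cfg$split_mode,
    x$counts$n_train, x$counts$n_test
  ))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
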