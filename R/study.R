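# Study driver: the pipeline's central comparison, CGM-only (FS1) versus
# CGM + heart rate (FS2) detection performance over repeated seeded cohorts.

#' Compare FS1 and FS2 detection performance over seeded cohorts
#'
#' For each seed, generates a synthetic cohort, applies the cleaning rules,
#' runs the internal 75/25 use-case protocol once with the CGM-only feature
#' set (FS1) and once with the CGM + heart-rate set (FS2), and records the
#' test AUC of the requested models. This is the pipeline's headline
#' comparison: the gain from adding wearable heart-rate features to glucose
#' dynamics.
#'
#' @param seeds integer vector; one cohort is generated per seed.
#' @param models character vector of classifier ids or labels.
#' @param n_subjects,days_per_subject cohort dimensions passed to
#'   [sim_config()].
#' @param sim_args named list of further [sim_config()] overrides.
#' @param cleaning a [cleaning_config()].
#' @return `data.frame(seed, model, auc_fs1, auc_fs2)`.
#' @export
#' @examples
#' \donttest{
#' res <- compare_feature_sets(seeds = 1:2, models = "RandomForest",
#'   n_subjects = 3, days_per_subject = 5)
#' aggregate(cbind(auc_fs1, auc_fs2) ~ model, res, median)
#' }
compare_feature_sets <- function(seeds = 1:10,
                                 models = c(
                                   "LR", "AdaBoost",
                                   "RandomForest"
                                 ),
                                 n_subjects = 10, days_per_subject = 7,
                                 sim_args = list(),
                                 cleaning = cleaning_config()) {
  rows <- list()
  for (seed in seeds) {
    args <- c(
      list(
        n_subjects = n_subjects, days_per_subject = days_per_subject,
        seed = seed
      ),
      sim_args
    )
    cfg <- do.call(sim_config, args)
    cohort <- generate_cohort(cfg, highrate = FALSE)
    blocks <- unlist(
      lapply(cohort, function(s) extract_day_blocks(s$series, cleaning)),
      recursive = FALSE
    )
    r1 <- run_use_case(
      use_case_config(1, "fs1", seed = seed), blocks,
      models = models
    )
    r2 <- run_use_case(
      use_case_config(3, "fs2", seed = seed), blocks,
      models = models
    )
    rows[[length(rows) + 1]] <- data.frame(
      seed = seed,
      model = r1$table$model,
      auc_fs1 = r1$table$AUC,
      auc_fs2 = r2$table$AUC
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
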