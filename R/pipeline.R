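#' Run the full fault-detection analysis end to end
#'
#' Orchestrates cohort synthesis, preprocessing (filtering, coach-channel
#' transition detection, sample labelling), stride segmentation, feature
#' extraction, the classifier bank with two-repetition cross-validation,
#' cohort aggregation, the four-stage selection funnel and the simplified
#' regular-vs-irregular evaluation of the survivors. Deterministic for a
#' fixed configuration.
#'
#' @param config An [generator_config()]; its seed drives everything.
#' @param specs Classifier specs (default all nine).
#' @param keys Dataset keys to evaluate (default all 12, e.g. `"SH_a"`).
#' @param out_dir Optional directory; when given, the result tables are
#'   written there as CSV (`records.csv`, `aggregated.csv`,
#'   `funnel_outcome.csv`, `binary_evaluation.csv`).
#' @return A list of class `rw_run`: `records`, `aggregated`, `funnel`,
#'   `binary` (NULL when there are no survivors), `config`.
#' @export
run_pipeline <- function(config, specs = classifier_spec(), keys = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "rw_config"))
  cohort <- generate_cohort(config)
  datasets <- cohort_datasets(cohort)
  records <- run_bank(datasets, specs = specs, keys = keys)
  aggregated <- aggregate_results(records)
  funnel <- selection_funnel(aggregated)
  binary <- if (length(funnel$survivors) > 0)
    binary_evaluation(records, funnel$survivors) else NULL
  out <- list(records = records, aggregated = aggregated, funnel = funnel,
              binary = binary, config = config)
  class(out) <- "rw_run"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(records, file.path(out_dir, "records.csv"), row.names = FALSE)
    write.csv(aggregated, file.path(out_dir, "aggregated.csv"),
              row.names = FALSE)
    write.csv(funnel$outcome, file.path(out_dir, "funnel_outcome.csv"),
              row.names = FALSE)
    if (!is.null(binary))
      write.csv(binary, file.path(out_dir, "binary_evaluation.csv"),
                row.names = FALSE)
  }
  out
}

#' Build the per-athlete feature datasets of a cohort
#'
#' Preprocesses and segments every session of the cohort and assembles the
#' 12 feature datasets per athlete-repetition.
#'
#' @param cohort An `rw_cohort` from [generate_cohort()].
#' @param segments Segments to process (default all four).
#' @return Nested list `datasets[[athlete_id]][[repetition]]` of named
#'   `rw_features` lists, as consumed by [run_bank()].
#' @export
cohort_datasets <- function(cohort, segments = c("pelvis", "thigh",
                                                 "shank", "foot")) {
  stopifnot(inherits(cohort, "rw_cohort"))
  config <- attr(cohort, "config")
  out <- list()
  for (nm in names(cohort)) {
    session <- preprocess_session(cohort[[nm]]$session,
                                  conditions = config$conditions)
    strides <- segment_session(session, segments = segments)
    ds <- if (length(segments) == 4L) build_datasets(strides) else {
      keys <- list()
      for (seg in segments)
        for (combo in names(RW_COMBOS))
          keys[[paste(RW_SEGMENT_CODES[[seg]], combo, sep = "_")]] <-
            assemble_dataset(strides, seg, combo)
      keys
    }
    ath <- session$athlete_id
    out[[ath]] <- c(out[[ath]], stats::setNames(list(ds), NULL))
  }
  out
}

#' @export
print.rw_run <- function(x, ...) {
  cat("<rw_run>", length(unique(x$records$athlete_id)), "athletes,",
      nrow(x$records), "result records\n")
  print(x$funnel)
  if (!is.null(x$binary)) {
    cat("simplified regular-vs-irregular evaluation:\n")
    print(x$binary, row.names = FALSE)
  }
  invisible(x)
}
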