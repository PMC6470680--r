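#' Confusion matrix from true and predicted labels
#'
#' @param truth,pred Equal-length label vectors.
#' @param levels Class order; class order of the 3-class problem is regular,
#'   LC, KB.
#' @return `k x k` count matrix, cell (i, j) = true class i predicted as j.
#' @export
confusion_matrix <- function(truth, pred, levels = RW_CONDITIONS) {
  if (length(truth) != length(pred))
    stop("input error: truth and prediction lengths differ")
  cm <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  m <- matrix(as.numeric(cm), nrow = length(levels),
              dimnames = list(true = levels, predicted = levels))
  m
}

#' Performance metrics of a multiclass confusion matrix
#'
#' Overall accuracy is the fraction of correctly classified strides
#' (trace over total). Recall, precision and F1 are computed one-vs-rest per
#' class; overall precision and overall F1 are the unweighted means across
#' classes. With balanced classes the mean recall coincides with the overall
#' accuracy. A class never predicted has undefined precision; it is reported
#' as 0 with a warning so downstream selection stays conservative.
#'
#' @param cm Square confusion matrix (rows = true).
#' @return A list of class `rw_metrics`: `accuracy`, `recall`, `precision`,
#'   `f1` (per class, named), `precision_overall`, `f1_overall`.
#' @export
compute_metrics <- function(cm) {
  if (nrow(cm) != ncol(cm)) stop("input error: confusion matrix must be square")
  total <- sum(cm)
  if (total <= 0) stop("input error: empty confusion matrix")
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  if (any(tp + fp == 0))
    warning("precision undefined for never-predicted class(es); reported as 0")
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  f1 <- ifelse(recall + precision > 0,
               2 * recall * precision / (recall + precision), 0)
  out <- list(
    accuracy = sum(tp) / total,
    recall = recall, precision = precision, f1 = f1,
    precision_overall = mean(precision),
    f1_overall = mean(f1)
  )
  class(out) <- "rw_metrics"
  out
}

# Per-record metrics table from a run_bank() records data frame.
record_metrics <- function(records) {
  cms <- as.matrix(records[, paste0("cm", as.vector(t(outer(1:3, 1:3, paste0))))])
  out <- list()
  for (i in seq_len(nrow(records))) {
    cm <- matrix(cms[i, ], 3, 3, byrow = TRUE,
                 dimnames = list(RW_CONDITIONS, RW_CONDITIONS))
    m <- compute_metrics(cm)
    out[[i]] <- data.frame(
      A = m$accuracy,
      R_regular = m$recall[1], R_LC = m$recall[2], R_KB = m$recall[3],
      P_overall = m$precision_overall,
      P_regular = m$precision[1], P_LC = m$precision[2], P_KB = m$precision[3],
      F1_overall = m$f1_overall,
      F1_regular = m$f1[1], F1_LC = m$f1[2], F1_KB = m$f1[3])
  }
  cbind(records[, c("athlete_id", "classifier", "segment", "combo", "name")],
        do.call(rbind, out), row.names = NULL)
}

#' Aggregate per-athlete metrics across the cohort
#'
#' Computes the metrics of every result record and their mean and standard
#' deviation across athletes for each classifier-dataset combination,
#' matching the layout used to report cohort-level accuracy, recall and
#' precision tables.
#'
#' @param records Data frame from [run_bank()].
#' @return Data frame with one row per classifier-dataset: name, classifier,
#'   segment, combo, then `<metric>_mean` and `<metric>_sd` columns for A,
#'   per-class R, overall and per-class P, overall and per-class F1.
#' @export
aggregate_results <- function(records) {
  pm <- record_metrics(records)
  n_ath <- length(unique(pm$athlete_id))
  if (n_ath < 2L)
    warning("single athlete: standard deviations reported as 0")
  metric_cols <- setdiff(names(pm),
                         c("athlete_id", "classifier", "segment", "combo", "name"))
  groups <- unique(pm[, c("name", "classifier", "segment", "combo")])
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    sub <- pm[pm$name == groups$name[i], metric_cols, drop = FALSE]
    mu <- colMeans(sub)
    sdv <- if (nrow(sub) > 1L) apply(sub, 2, sd) else rep(0, ncol(sub))
    row <- c(as.list(groups[i, ]),
             as.list(stats::setNames(mu, paste0(metric_cols, "_mean"))),
             as.list(stats::setNames(sdv, paste0(metric_cols, "_sd"))))
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cascaded selection funnel for the classifier bank
#'
#' Applies the four selection criteria in order to the cohort-mean metrics,
#' all with the same threshold (0.80 by default):
#' 1. overall accuracy;
#' 2. recall of every race-walking condition;
#' 3. overall precision;
#' 4. precision of every race-walking condition.
#'
#' Comparisons are made on means rounded to `digits` decimals (2 by default),
#' the precision at which cohort tables are reported. Later-stage metrics may
#' be `NA` for rows already rejected at an earlier stage.
#'
#' @param agg Aggregated table from [aggregate_results()] (columns `name`,
#'   `A_mean`, `R_*_mean`, `P_overall_mean`, `P_*_mean`).
#' @param threshold Threshold shared by the four criteria (default 0.80).
#' @param digits Rounding applied before comparison (default 2).
#' @return A list of class `rw_funnel`: `outcome` (data frame with `name`,
#'   `stage_reached` in `rejected@1`..`rejected@4`/`survivor`, and
#'   `reason`), and `survivors`, the character vector of surviving names.
#' @export
selection_funnel <- function(agg, threshold = 0.80, digits = 2) {
  need <- c("name", "A_mean", "R_regular_mean", "R_LC_mean", "R_KB_mean",
            "P_overall_mean", "P_regular_mean", "P_LC_mean", "P_KB_mean")
  missing_cols <- setdiff(need, names(agg))
  if (length(missing_cols) > 0)
    stop("input error: missing metric column(s): ",
         paste(missing_cols, collapse = ", "))
  r <- function(x) round(x, digits)
  n <- nrow(agg)
  stage <- rep("survivor", n)
  reason <- rep("", n)
  fail <- function(vals, lab) {
    vapply(seq_len(n), function(i) {
      v <- r(vals[i, , drop = FALSE])
      bad <- which(!is.na(v) & v < threshold)
      nav <- which(is.na(v))
      if (length(nav) > 0 && length(bad) == 0)
        return(NA_character_)  # metric unavailable: cannot evaluate
      if (length(bad) == 0) return("")
      j <- bad[which.min(v[bad])]
      paste0(lab[j], " = ", v[j], " < ", threshold)
    }, character(1))
  }
  stages <- list(
    list(vals = agg[, "A_mean", drop = FALSE], lab = "A"),
    list(vals = agg[, c("R_regular_mean", "R_LC_mean", "R_KB_mean")],
         lab = c("R(regular)", "R(LC)", "R(KB)")),
    list(vals = agg[, "P_overall_mean", drop = FALSE], lab = "P(overall)"),
    list(vals = agg[, c("P_regular_mean", "P_LC_mean", "P_KB_mean")],
         lab = c("P(regular)", "P(LC)", "P(KB)"))
  )
  alive <- rep(TRUE, n)
  for (k in seq_along(stages)) {
    res <- fail(stages[[k]]$vals, stages[[k]]$lab)
    for (i in which(alive)) {
      if (is.na(res[i])) {
        stage[i] <- paste0("rejected@", k)
        reason[i] <- "metric not available (rejected upstream)"
        alive[i] <- FALSE
      } else if (nzchar(res[i])) {
        stage[i] <- paste0("rejected@", k)
        reason[i] <- res[i]
        alive[i] <- FALSE
      }
    }
  }
  outcome <- data.frame(name = agg$name, stage_reached = stage,
                        reason = reason, stringsAsFactors = FALSE)
  out <- list(outcome = outcome, survivors = agg$name[alive],
              threshold = threshold, digits = digits)
  class(out) <- "rw_funnel"
  out
}

#' @export
print.rw_funnel <- function(x, ...) {
  cat("<rw_funnel> threshold", x$threshold, "\n")
  print(table(x$outcome$stage_reached))
  cat("survivors:", paste(x$survivors, collapse = ", "), "\n")
  invisible(x)
}

#' Number of rows surviving up to a funnel stage
#'
#' @param funnel An `rw_funnel`.
#' @param stage Stage number 1..4.
#' @return Count of rows not rejected at or before `stage`.
#' @export
funnel_survivors_at <- function(funnel, stage) {
  rejected_by <- as.integer(sub("rejected@", "",
                                funnel$outcome$stage_reached[
                                  grepl("^rejected", funnel$outcome$stage_reached)]))
  nrow(funnel$outcome) - sum(rejected_by <= stage)
}

#' Collapse a 3-class confusion matrix to regular vs irregular
#'
#' The two fault classes (loss of contact and knee bent) are merged into a
#' single "irregular" class; confusions between the two faults therefore land
#' on the binary diagonal.
#'
#' @param cm 3x3 confusion matrix, class order regular, LC, KB.
#' @return 2x2 confusion matrix, class order regular, irregular.
#' @export
collapse_binary <- function(cm) {
  stopifnot(nrow(cm) == 3, ncol(cm) == 3)
  m <- matrix(c(cm[1, 1], sum(cm[1, 2:3]),
                sum(cm[2:3, 1]), sum(cm[2:3, 2:3])),
              2, 2, byrow = TRUE,
              dimnames = list(true = c("regular", "irregular"),
                              predicted = c("regular", "irregular")))
  m
}

#' Goodness index of a binary classifier
#'
#' Euclidean distance in ROC space between the classifier and the perfect
#' classifier, computed on rates: with TP the true-positive rate (irregular
#' detected as irregular) and TN the true-negative rate (regular detected as
#' regular), `G = sqrt((1 - TP)^2 + (1 - TN)^2)`. `G` ranges from 0 (perfect)
#' to `sqrt(2)`; a chance-level classifier (TP = TN = 0.5) has
#' `G = sqrt(0.5)`, about 0.70. Categories: optimum `G <= 0.25`; good
#' `0.25 < G <= 0.70`; bad `G > 0.70` (with chance level sitting at the
#' good/bad boundary).
#'
#' @param cm2 2x2 confusion matrix (class order regular, irregular), or a
#'   list with elements `tp` and `tn` giving the rates directly.
#' @return A list with `G`, `category`, `tp_rate`, `tn_rate`.
#' @export
#' @examples
#' goodness_index(list(tp = 0.5, tn = 0.5))$G  # sqrt(0.5)
goodness_index <- function(cm2) {
  if (is.list(cm2) && !is.null(cm2$tp)) {
    tp <- cm2$tp; tn <- cm2$tn
  } else {
    stopifnot(nrow(cm2) == 2, ncol(cm2) == 2)
    if (any(rowSums(cm2) == 0))
      stop("input error: both classes must be present")
    tn <- cm2[1, 1] / sum(cm2[1, ])
    tp <- cm2[2, 2] / sum(cm2[2, ])
  }
  g <- sqrt((1 - tp)^2 + (1 - tn)^2)
  category <- if (g <= 0.25) "optimum" else if (g <= 0.70) "good" else "bad"
  list(G = g, category = category, tp_rate = tp, tn_rate = tn)
}

#' Simplified regular-vs-irregular evaluation of funnel survivors
#'
#' For each surviving classifier-dataset, the per-athlete averaged 3x3
#' confusion matrices are pooled (summed) across athletes, collapsed to 2x2,
#' and assessed by overall accuracy and the goodness index.
#'
#' @param records Data frame from [run_bank()].
#' @param survivors Character vector of record names to evaluate.
#' @return Data frame with `name`, binary `accuracy`, `G` and `category`.
#' @export
binary_evaluation <- function(records, survivors) {
  rows <- list()
  for (nm in survivors) {
    sub <- records[records$name == nm, , drop = FALSE]
    if (nrow(sub) == 0) stop("input error: no records named '", nm, "'")
    cm <- matrix(colSums(sub[, paste0("cm", as.vector(t(outer(1:3, 1:3, paste0))))]),
                 3, 3, byrow = TRUE)
    b <- collapse_binary(cm)
    g <- goodness_index(b)
    rows[[nm]] <- data.frame(name = nm, accuracy = sum(diag(b)) / sum(b),
                             G = g$G, category = g$category,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
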