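#' Reference cohort-level metrics of the original eight-athlete experiment
#'
#' Loads the reference benchmark tables shipped with the package: the
#' cohort-mean (and sd) overall accuracy of all 108 classifier-dataset
#' combinations, the per-condition recall of the 30 combinations passing the
#' accuracy criterion, and the overall/per-condition precision of the 14
#' combinations passing the recall criterion. Metrics that were only reported
#' for earlier-stage survivors are `NA` elsewhere. The returned table has the
#' [aggregate_results()] schema, so it can be fed directly to
#' [selection_funnel()].
#'
#' @return Data frame with one row per classifier-dataset combination.
#' @export
#' @examples
#' funnel <- selection_funnel(published_metrics())
#' length(funnel$survivors)  # 7
published_metrics <- function() {
  path <- function(f) system.file("extdata", f, package = "racewalkr",
                                  mustWork = TRUE)
  acc <- read.csv(path("published_accuracy.csv"), stringsAsFactors = FALSE)
  rec <- read.csv(path("published_recall.csv"), stringsAsFactors = FALSE)
  prec <- read.csv(path("published_precision.csv"), stringsAsFactors = FALSE)
  out <- data.frame(
    name = mapply(record_name, acc$classifier, acc$combo, acc$segment,
                  USE.NAMES = FALSE),
    classifier = acc$classifier, segment = acc$segment, combo = acc$combo,
    A_mean = acc$mean, A_sd = acc$sd,
    stringsAsFactors = FALSE
  )
  key <- function(d) paste(d$classifier, d$combo, d$segment)
  i <- match(key(out), key(rec))
  out$R_regular_mean <- rec$regular_mean[i]
  out$R_regular_sd <- rec$regular_sd[i]
  out$R_LC_mean <- rec$LC_mean[i]
  out$R_LC_sd <- rec$LC_sd[i]
  out$R_KB_mean <- rec$KB_mean[i]
  out$R_KB_sd <- rec$KB_sd[i]
  j <- match(key(out), key(prec))
  out$P_overall_mean <- prec$overall_mean[j]
  out$P_overall_sd <- prec$overall_sd[j]
  out$P_regular_mean <- prec$regular_mean[j]
  out$P_regular_sd <- prec$regular_sd[j]
  out$P_LC_mean <- prec$LC_mean[j]
  out$P_LC_sd <- prec$LC_sd[j]
  out$P_KB_mean <- prec$KB_mean[j]
  out$P_KB_sd <- prec$KB_sd[j]
  out
}
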