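#' Write a session recording to a delimited table
#'
#' One row per sample: `time_s`, the 42 kinematic channels
#' (`<segment>_<side>_<acc|gyr>_<x|y|z>`), and `coach_acc_v`. An optional
#' ground-truth sidecar (same path with extension `.truth.json`) stores
#' transitions, heel strikes and per-stride labels.
#'
#' @param session An `rw_session`.
#' @param path Output CSV path.
#' @param truth Optional `rw_truth` written as a JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, truth = NULL) {
  stopifnot(inherits(session, "rw_session"))
  df <- data.frame(
    time_s = (seq_len(nrow(session$data)) - 1) / session$sampling_rate,
    session$data, coach_acc_v = session$coach, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(sampling_rate = session$sampling_rate,
           athlete_id = session$athlete_id, repetition = session$repetition,
           transitions = truth$transitions,
           heel_strikes = truth$heel_strikes,
           stride_labels = truth$stride_labels,
           conditions = truth$conditions),
      sub("\\.csv$", ".truth.json", path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a session recording written by [write_session()]
#'
#' Unknown extra columns are accepted with a warning; a missing kinematic or
#' coach column is a format error.
#'
#' @param path CSV path.
#' @param athlete_id,repetition,sampling_rate Metadata; taken from the
#'   ground-truth sidecar when present.
#' @return An `rw_session`.
#' @export
read_session <- function(path, athlete_id = "A01", repetition = 1L,
                         sampling_rate = NULL) {
  df <- read.csv(path, check.names = FALSE)
  expected <- as.vector(t(outer(
    paste(RW_SEGMENTS$segment, RW_SEGMENTS$side, sep = "_"),
    RW_CHANNELS, paste, sep = "_")))
  missing_cols <- setdiff(c("time_s", expected, "coach_acc_v"), names(df))
  if (length(missing_cols) > 0)
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), c("time_s", expected, "coach_acc_v"))
  if (length(extra) > 0)
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  sidecar <- sub("\\.csv$", ".truth.json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    athlete_id <- meta$athlete_id
    repetition <- meta$repetition
    sampling_rate <- meta$sampling_rate
  }
  if (is.null(sampling_rate)) {
    dt <- diff(df$time_s[1:2])
    sampling_rate <- round(1 / dt)
  }
  session <- list(
    athlete_id = athlete_id, repetition = as.integer(repetition),
    sampling_rate = sampling_rate,
    data = as.matrix(df[, expected]),
    coach = df$coach_acc_v)
  class(session) <- "rw_session"
  session
}

#' Read the ground-truth sidecar of a session
#'
#' @param path Session CSV path (the sidecar path is derived from it).
#' @return An `rw_truth`.
#' @export
read_truth <- function(path) {
  sidecar <- sub("\\.csv$", ".truth.json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  truth <- list(
    heel_strikes = lapply(meta$heel_strikes, as.integer),
    stride_labels = meta$stride_labels,
    transitions = as.integer(meta$transitions),
    conditions = meta$conditions)
  class(truth) <- "rw_truth"
  truth
}

#' Write a feature dataset to a delimited table
#'
#' @param fm An `rw_features`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "rw_features"))
  df <- data.frame(fm$meta, condition = fm$labels, fm$x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature dataset written by [write_features()]
#'
#' @param path CSV path.
#' @param segment,combo Dataset key (stored in the filename by convention,
#'   not in the table).
#' @return An `rw_features`.
#' @export
read_features <- function(path, segment, combo) {
  df <- read.csv(path, check.names = FALSE)
  meta_cols <- c("athlete_id", "repetition", "side", "condition")
  out <- list(
    x = as.matrix(df[, setdiff(names(df), meta_cols)]),
    labels = df$condition,
    meta = df[, c("athlete_id", "repetition", "side")],
    segment = segment, combo = combo)
  class(out) <- "rw_features"
  out
}
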