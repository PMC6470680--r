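#' Detect heel strikes from the shank sagittal angular velocity
#'
#' Shank-gyroscope gait-event scheme: mid-swing is located as the prominent
#' positive peaks of the sagittal angular velocity (minimum spacing 0.4 times
#' the median inter-peak interval of a first pass), and the heel strike is
#' the negative minimum of the signal within the following 0.9 cycle,
#' stopping short of the next mid-swing peak.
#'
#' @param gyro Filtered shank sagittal angular-velocity channel (deg/s).
#' @param sampling_rate Sampling frequency in Hz.
#' @return Strictly increasing 1-based heel-strike sample indices (possibly
#'   empty when no qualifying peaks exist).
#' @export
detect_heel_strikes <- function(gyro, sampling_rate) {
  n <- length(gyro)
  if (n < 4L) return(integer(0))
  thr <- 0.4 * max(gyro)
  if (!is.finite(thr) || max(gyro) <= 0) return(integer(0))
  pk <- pracma::findpeaks(gyro, minpeakheight = thr)
  if (is.null(pk)) return(integer(0))
  spacing <- diff(sort(pk[, 2]))
  minsep <- if (length(spacing) > 0) max(3L, floor(0.4 * stats::median(spacing))) else 3L
  pk <- pracma::findpeaks(gyro, minpeakheight = thr, minpeakdistance = minsep)
  if (is.null(pk)) return(integer(0))
  peaks <- sort(pk[, 2])
  period <- if (length(peaks) > 1) stats::median(diff(peaks)) else n
  hs <- integer(0)
  for (p in peaks) {
    # the heel strike is the deep minimum following mid-swing; the search
    # window stops short of the next mid-swing peak
    win <- (p + 1L):min(n, p + max(3L, round(0.9 * period)))
    if (length(win) < 3L) next
    i <- win[which.min(gyro[win])]
    if (gyro[i] < 0 && i < n) hs <- c(hs, i)
  }
  unique(hs)
}

#' Partition a labelled recording into strides
#'
#' A stride is the interval between two consecutive heel strikes of the same
#' foot (half-open). A stride keeps the condition covering all of its
#' samples; strides straddling a condition transition (mixed labels) are
#' discarded, mirroring a protocol in which strides performed in a condition
#' not required during that lap are excluded.
#'
#' @param heel_strikes Sorted 1-based heel-strike indices of one foot.
#' @param sample_labels Per-sample condition labels of the recording.
#' @return Data frame with columns `start`, `end` (half-open) and
#'   `condition`; zero rows when fewer than two heel strikes are given.
#' @export
partition_strides <- function(heel_strikes, sample_labels) {
  heel_strikes <- as.integer(heel_strikes)
  if (is.unsorted(heel_strikes, strictly = TRUE))
    stop("input error: heel strikes must be strictly increasing")
  if (length(heel_strikes) < 2L)
    return(data.frame(start = integer(0), end = integer(0),
                      condition = character(0), stringsAsFactors = FALSE))
  start <- heel_strikes[-length(heel_strikes)]
  end <- heel_strikes[-1L]
  cond <- character(length(start))
  keep <- logical(length(start))
  for (i in seq_along(start)) {
    lab <- unique(sample_labels[start[i]:(end[i] - 1L)])
    keep[i] <- length(lab) == 1L
    cond[i] <- lab[1L]
  }
  data.frame(start = start[keep], end = end[keep], condition = cond[keep],
             stringsAsFactors = FALSE)
}

#' Trim adaptation strides and balance condition counts
#'
#' Per condition (within one foot's stride list, in time order) the first 3
#' and last 3 strides are removed to discard the adaptation to the new
#' condition; all conditions are then truncated to the minimum remaining
#' count, keeping the earliest strides.
#'
#' @param strides Data frame from [partition_strides()].
#' @param conditions Condition labels that must all be present.
#' @param n_trim Strides removed at each end of a condition (default 3).
#' @return The balanced subset of `strides`, equal counts per condition.
#' @export
trim_and_balance <- function(strides, conditions = RW_CONDITIONS, n_trim = 3L) {
  pieces <- list()
  for (cond in conditions) {
    s <- strides[strides$condition == cond, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) <= 2L * n_trim)
      stop("insufficient-data error: condition '", cond, "' has ", nrow(s),
           " strides, need more than ", 2L * n_trim)
    pieces[[cond]] <- s[(n_trim + 1L):(nrow(s) - n_trim), , drop = FALSE]
  }
  n_min <- min(vapply(pieces, nrow, integer(1)))
  out <- do.call(rbind, lapply(pieces, function(s) s[seq_len(n_min), , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Time-normalize stride channels to a fixed number of samples
#'
#' Linear interpolation onto a uniform grid preserving the first and last
#' samples.
#'
#' @param x Numeric vector or a matrix with one column per channel.
#' @param target Output length (default 100).
#' @return Vector or matrix with `target` samples per channel.
#' @export
resample_stride <- function(x, target = 100L) {
  if (is.matrix(x)) {
    if (nrow(x) < 2L) stop("input error: stride shorter than 2 samples")
    return(apply(x, 2, resample_stride, target = target))
  }
  n <- length(x)
  if (n < 2L) stop("input error: stride shorter than 2 samples")
  if (n == target) return(x)
  approx(seq_len(n), x, xout = seq(1, n, length.out = target))$y
}

#' Segment a preprocessed session into time-normalized strides
#'
#' Heel strikes are detected independently for the left and right shank
#' sagittal angular velocity. Thigh, shank and foot strides use their own
#' side's heel strikes; the midline pelvis uses the left-foot events as cycle
#' boundaries. Each side's strides are trimmed and balanced, then every
#' stride of every requested segment is cut out and resampled to
#' `n_norm` samples per channel.
#'
#' @param session A preprocessed session ([preprocess_session()]).
#' @param segments Segments to extract (default all four).
#' @param n_norm Normalized samples per stride (default 100).
#' @param n_trim Adaptation strides trimmed per end (default 3).
#' @return A list of class `rw_strides`: `meta` (data frame with athlete,
#'   repetition, segment, side, condition, start, end) and `channels`, a
#'   numeric array `n_strides x 6 x n_norm` with the channel order
#'   acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z.
#' @export
segment_session <- function(session,
                            segments = c("pelvis", "thigh", "shank", "foot"),
                            n_norm = 100L, n_trim = 3L) {
  stopifnot(inherits(session, "rw_session"))
  if (is.null(session$sample_labels))
    stop("input error: session must be preprocessed (missing sample labels)")
  conds <- unique(session$sample_labels)
  per_side <- list()
  for (side in c("left", "right")) {
    hs <- detect_heel_strikes(session$data[, paste0("shank_", side, "_gyr_y")],
                              session$sampling_rate)
    raw <- partition_strides(hs, session$sample_labels)
    per_side[[side]] <- trim_and_balance(raw, conditions = conds, n_trim = n_trim)
  }

  meta <- list(); chans <- list(); k <- 0L
  for (seg in segments) {
    sides <- if (seg == "pelvis") "center" else c("left", "right")
    for (side in sides) {
      ev_side <- if (seg == "pelvis") "left" else side
      st <- per_side[[ev_side]]
      cols <- paste(seg, side, RW_CHANNELS, sep = "_")
      for (i in seq_len(nrow(st))) {
        k <- k + 1L
        meta[[k]] <- data.frame(
          athlete_id = session$athlete_id, repetition = session$repetition,
          segment = seg, side = side, condition = st$condition[i],
          start = st$start[i], end = st$end[i], stringsAsFactors = FALSE)
        raw <- session$data[st$start[i]:(st$end[i] - 1L), cols, drop = FALSE]
        chans[[k]] <- t(resample_stride(raw, target = n_norm))
      }
    }
  }
  meta <- do.call(rbind, meta)
  arr <- array(0, dim = c(nrow(meta), length(RW_CHANNELS), n_norm),
               dimnames = list(NULL, RW_CHANNELS, NULL))
  for (i in seq_len(nrow(meta))) arr[i, , ] <- chans[[i]]
  out <- list(meta = meta, channels = arr)
  class(out) <- "rw_strides"
  out
}

#' @export
print.rw_strides <- function(x, ...) {
  cat("<rw_strides>", nrow(x$meta), "strides x", dim(x$channels)[2],
      "channels x", dim(x$channels)[3], "samples\n")
  print(table(x$meta$segment, x$meta$condition))
  invisible(x)
}
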