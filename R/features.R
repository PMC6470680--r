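#' Biased sample autocorrelation
#'
#' Autocovariance of the mean-removed sequence with the biased (1/N)
#' normalization: `r(tau) = (1/N) * sum_t (x_t - xbar) (x_{t+tau} - xbar)`,
#' for lags 0 to N-1, so `r(0)` is the biased sample variance.
#'
#' @param x Numeric sequence, length >= 4.
#' @return Numeric vector of length `length(x)` (lags 0..N-1).
#' @export
stride_autocorr <- function(x) {
  n <- length(x)
  if (n < 4L) stop("input error: need at least 4 samples")
  if (sd(x) == 0) return(rep(0, n))
  as.numeric(acf(x, lag.max = n - 1L, type = "covariance",
                 plot = FALSE, demean = TRUE)$acf)
}

# Height and lag of the "second peak" of the autocorrelation: the largest
# local maximum of r at lag >= 1 occurring at or after the first zero
# crossing of r. Returns c(height, lag); c(0, 0) when none exists.
second_autocorr_peak <- function(r) {
  n <- length(r)
  if (n < 3L || all(r == 0)) return(c(0, 0))
  zc <- which(r[-1] * r[-n] <= 0 & r[-n] != 0)[1]  # first sign change
  if (is.na(zc)) return(c(0, 0))
  idx <- which(diff(sign(diff(r))) < 0) + 1L       # local maxima (1-based pos)
  idx <- idx[idx > zc]
  if (length(idx) == 0) return(c(0, 0))
  best <- idx[which.max(r[idx])]
  c(r[best], best - 1L)                            # lag is 0-based
}

#' Extract the seven per-channel stride features
#'
#' Four time-domain features (mean, standard deviation, maximum, minimum) and
#' three autocorrelation features: the height of the main peak (`r(0)`, the
#' signal power after mean removal), and the height and lag (in samples) of
#' the second autocorrelation peak (largest local maximum past the first zero
#' crossing). Zero-variance channels yield (0, 0, 0) for the autocorrelation
#' features.
#'
#' @param x One stride channel of length 100 (or `n_norm`).
#' @param expected_length Required input length (default 100).
#' @return Named numeric vector of length 7.
#' @export
#' @examples
#' extract_stride_features(rep(5, 100))
extract_stride_features <- function(x, expected_length = 100L) {
  if (length(x) != expected_length)
    stop("input error: expected a channel of length ", expected_length)
  r <- stride_autocorr(x)
  p2 <- second_autocorr_peak(r)
  out <- c(mean(x), sd(x), max(x), min(x), r[1], p2[1], p2[2])
  names(out) <- RW_FEATURES
  out
}

#' Assemble one feature dataset for a segment and signal combination
#'
#' Builds the n-strides-by-f feature matrix for one body segment and one
#' signal combination: `"a"` uses the three acceleration channels (21
#' features), `"w"` the three angular-velocity channels (21), `"aw"` all six
#' (42). For the bilateral segments (thigh, shank, foot) left and right
#' strides are pooled as separate rows, exploiting the left/right symmetry of
#' race walking.
#'
#' @param strides An `rw_strides` object.
#' @param segment One of `"pelvis"`, `"thigh"`, `"shank"`, `"foot"`.
#' @param combo One of `"a"`, `"w"`, `"aw"`.
#' @return A list of class `rw_features`: `x` (feature matrix with stable
#'   `<channel>_<feature>` column names), `labels` (condition per row),
#'   `meta` (athlete, repetition, side per row), `segment`, `combo`.
#' @export
assemble_dataset <- function(strides, segment, combo = c("a", "w", "aw")) {
  stopifnot(inherits(strides, "rw_strides"))
  combo <- match.arg(combo)
  segment <- match.arg(segment, names(RW_SEGMENT_CODES))
  rows <- which(strides$meta$segment == segment)
  if (length(rows) == 0)
    stop("input error: no strides for segment '", segment, "'")
  chans <- RW_COMBOS[[combo]]
  n_norm <- dim(strides$channels)[3]
  x <- matrix(0, nrow = length(rows), ncol = length(chans) * length(RW_FEATURES))
  colnames(x) <- as.vector(t(outer(chans, RW_FEATURES, paste, sep = "_")))
  for (i in seq_along(rows)) {
    for (ch in chans) {
      feats <- extract_stride_features(strides$channels[rows[i], ch, ],
                                       expected_length = n_norm)
      x[i, paste(ch, RW_FEATURES, sep = "_")] <- feats
    }
  }
  out <- list(
    x = x,
    labels = strides$meta$condition[rows],
    meta = strides$meta[rows, c("athlete_id", "repetition", "side")],
    segment = segment, combo = combo
  )
  class(out) <- "rw_features"
  out
}

#' Build the 12 feature datasets of one athlete-repetition
#'
#' 4 body segments (pelvis, thighs, shanks, feet) times 3 signal combinations
#' (accelerations, angular velocities, both).
#'
#' @param strides An `rw_strides` object containing all four segments.
#' @return Named list of 12 `rw_features`, keys `"<SEG>_<combo>"` such as
#'   `"SH_a"`.
#' @export
build_datasets <- function(strides) {
  stopifnot(inherits(strides, "rw_strides"))
  missing_seg <- setdiff(names(RW_SEGMENT_CODES), unique(strides$meta$segment))
  if (length(missing_seg) > 0)
    stop("input error: missing segment(s): ", paste(missing_seg, collapse = ", "))
  out <- list()
  for (seg in names(RW_SEGMENT_CODES))
    for (combo in names(RW_COMBOS))
      out[[paste(RW_SEGMENT_CODES[[seg]], combo, sep = "_")]] <-
        assemble_dataset(strides, seg, combo)
  out
}

#' @export
print.rw_features <- function(x, ...) {
  cat("<rw_features>", RW_SEGMENT_CODES[[x$segment]], "/", x$combo, "-",
      nrow(x$x), "strides x", ncol(x$x), "features\n")
  invisible(x)
}
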