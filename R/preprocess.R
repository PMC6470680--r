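#' Zero-phase low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth filter forward and backward
#' (`signal::filtfilt`) so the net filter has the requested order and zero
#' phase: gait events keep their timing. A net order of 4 is obtained by
#' designing a 2nd-order filter and running it in both directions.
#'
#' @param x Numeric channel.
#' @param sampling_rate Sampling frequency in Hz.
#' @param cutoff Cut-off frequency in Hz (default 20).
#' @param order Net filter order; must be even (default 4).
#' @return Filtered channel, same length as `x`.
#' @export
lowpass_filter <- function(x, sampling_rate, cutoff = 20, order = 4) {
  if (cutoff >= sampling_rate / 2)
    stop("parameter error: cutoff must be below the Nyquist frequency")
  if (order %% 2 != 0 || order < 2)
    stop("parameter error: order must be a positive even number")
  if (length(x) <= 3 * order)
    stop("input error: channel too short for filtering")
  bf <- signal::butter(order / 2, cutoff / (sampling_rate / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass
  n <- length(x)
  pad <- min(n - 1L, 60L)
  xp <- c(2 * x[1] - x[(pad + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  yp[(pad + 1L):(pad + n)]
}

#' Detect condition transitions from the coach channel
#'
#' The coach sensor is rotated 180 degrees at each condition transition, so
#' its vertical acceleration flips sign. The channel is low-pass filtered
#' (same 20 Hz Butterworth as the kinematic channels), and a transition is
#' declared at the first sample of a sign change that persists for at least
#' `debounce` samples.
#'
#' @param coach Coach vertical-acceleration channel (m/s^2).
#' @param sampling_rate Sampling frequency in Hz.
#' @param debounce Persistence window in samples (default 30, i.e. 0.5 s at
#'   60 Hz).
#' @param cutoff,order Filter settings, passed to [lowpass_filter()].
#' @return Strictly increasing 1-based sample indices (possibly empty).
#' @export
detect_transitions <- function(coach, sampling_rate, debounce = 30L,
                               cutoff = 20, order = 4) {
  if (length(coach) < debounce)
    stop("input error: channel shorter than the debounce window")
  f <- lowpass_filter(coach, sampling_rate, cutoff, order)
  if (max(abs(f)) < 1e-8)
    stop("detection error: coach channel has no gravity component")
  s <- sign(f)
  s[s == 0] <- 1
  n <- length(s)
  out <- integer(0)
  i <- 2L
  while (i <= n) {
    if (s[i] != s[i - 1L]) {
      w <- s[i:min(n, i + debounce - 1L)]
      if (all(w == s[i])) {
        out <- c(out, i)
        i <- i + debounce
        next
      }
    }
    i <- i + 1L
  }
  out
}

#' Build the reference sequence of race-walking conditions
#'
#' @param transitions Strictly increasing 1-based transition indices.
#' @param condition_order Condition labels, one more than `transitions`.
#' @return A list of class `rw_sref` with `transitions` and `labels`.
#' @export
build_reference_sequence <- function(transitions, condition_order) {
  transitions <- as.integer(transitions)
  if (length(transitions) > 0 && is.unsorted(transitions, strictly = TRUE))
    stop("input error: transitions must be strictly increasing")
  if (length(condition_order) != length(transitions) + 1L)
    stop("input error: need exactly one more condition label than transitions")
  out <- list(transitions = transitions, labels = as.character(condition_order))
  class(out) <- "rw_sref"
  out
}

#' Label every sample of a recording with its condition
#'
#' Spans are half-open: a transition index is the first sample of the new
#' condition.
#'
#' @param n_samples Recording length (or an `rw_session`, from which the
#'   length is taken).
#' @param sref An [build_reference_sequence()] object.
#' @return Character vector of length `n_samples`.
#' @export
label_samples <- function(n_samples, sref) {
  if (inherits(n_samples, "rw_session")) n_samples <- nrow(n_samples$data)
  stopifnot(inherits(sref, "rw_sref"))
  if (length(sref$transitions) > 0 && any(sref$transitions > n_samples))
    stop("input error: transition index beyond the recording")
  bounds <- c(1L, sref$transitions, n_samples + 1L)
  labels <- character(n_samples)
  for (i in seq_along(sref$labels))
    labels[bounds[i]:(bounds[i + 1L] - 1L)] <- sref$labels[i]
  labels
}

#' Filter all kinematic channels of a session
#'
#' @param session An `rw_session`.
#' @param cutoff,order Settings for [lowpass_filter()].
#' @return The session with every kinematic channel filtered (the coach
#'   channel is left untouched; [detect_transitions()] filters its own copy).
#' @export
filter_session <- function(session, cutoff = 20, order = 4) {
  stopifnot(inherits(session, "rw_session"))
  session$data <- apply(session$data, 2, lowpass_filter,
                        sampling_rate = session$sampling_rate,
                        cutoff = cutoff, order = order)
  session
}

#' Preprocess a session: filter, detect transitions, label samples
#'
#' @param session An `rw_session`.
#' @param conditions Condition order of the protocol.
#' @param cutoff,order,debounce See [lowpass_filter()] and
#'   [detect_transitions()].
#' @return The session with filtered channels plus elements `sref` and
#'   `sample_labels`.
#' @export
preprocess_session <- function(session, conditions = RW_CONDITIONS,
                               cutoff = 20, order = 4, debounce = 30L) {
  tr <- detect_transitions(session$coach, session$sampling_rate,
                           debounce = debounce, cutoff = cutoff, order = order)
  if (length(tr) != length(conditions) - 1L)
    stop("data error: detected ", length(tr), " transitions but the protocol ",
         "defines ", length(conditions) - 1L)
  session <- filter_session(session, cutoff = cutoff, order = order)
  session$sref <- build_reference_sequence(tr, conditions)
  session$sample_labels <- label_samples(nrow(session$data), session$sref)
  session
}
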