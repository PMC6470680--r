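#' Configuration for the synthetic race-walking cohort generator
#'
#' Bundles every tunable of the simulated testing protocol: a cohort of
#' athletes each performs `n_repetitions` sessions, and a session is one
#' contiguous recording of three laps, one per race-walking condition
#' (regular, loss of contact, knee bent), sampled at `sampling_rate` Hz from
#' seven body-worn inertial units plus a hand-held coach reference sensor.
#'
#' @param n_athletes Number of athletes in the cohort.
#' @param n_repetitions Sessions per athlete.
#' @param conditions Ordered condition labels, one lap each.
#' @param strides_per_condition Strides (per foot) generated per lap.
#' @param sampling_rate Sampling frequency in Hz.
#' @param stride_duration_mean Mean stride duration in seconds.
#' @param stride_duration_cv Coefficient of variation of stride duration.
#' @param n_harmonics Number of harmonics in each channel template.
#' @param delta Class-separation scale (>= 0): condition-specific template
#'   differences are proportional to `delta`; 0 makes the three conditions
#'   indistinguishable.
#' @param athlete_variability Fractional multiplicative perturbation of the
#'   templates per athlete.
#' @param noise_sd_acc Additive Gaussian noise sd on accelerometer channels
#'   (m/s^2).
#' @param noise_sd_gyr Additive Gaussian noise sd on gyroscope channels
#'   (deg/s).
#' @param seed Master seed; all athlete- and session-level randomness is
#'   derived from it.
#' @return A list of class `rw_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_athletes = 1, strides_per_condition = 20)
#' cohort <- generate_cohort(cfg)
generator_config <- function(n_athletes = 8,
                             n_repetitions = 2,
                             conditions = RW_CONDITIONS,
                             strides_per_condition = 120,
                             sampling_rate = 60,
                             stride_duration_mean = 0.70,
                             stride_duration_cv = 0.05,
                             n_harmonics = 6,
                             delta = 1,
                             athlete_variability = 0.10,
                             noise_sd_acc = 0.5,
                             noise_sd_gyr = 5,
                             seed = 1L) {
  cfg <- list(
    n_athletes = as.integer(n_athletes),
    n_repetitions = as.integer(n_repetitions),
    conditions = as.character(conditions),
    strides_per_condition = as.integer(strides_per_condition),
    sampling_rate = sampling_rate,
    stride_duration_mean = stride_duration_mean,
    stride_duration_cv = stride_duration_cv,
    n_harmonics = as.integer(n_harmonics),
    delta = delta,
    athlete_variability = athlete_variability,
    noise_sd_acc = noise_sd_acc,
    noise_sd_gyr = noise_sd_gyr,
    seed = as.integer(seed)
  )
  if (cfg$n_athletes < 1L || cfg$n_repetitions < 1L ||
      cfg$strides_per_condition < 1L || cfg$n_harmonics < 1L)
    stop("configuration error: all counts must be >= 1")
  if (cfg$delta < 0) stop("configuration error: delta must be >= 0")
  if (cfg$stride_duration_mean <= 0)
    stop("configuration error: stride_duration_mean must be > 0")
  if (cfg$sampling_rate <= 0)
    stop("configuration error: sampling_rate must be > 0")
  if (!all(cfg$conditions %in% RW_CONDITIONS))
    stop("configuration error: conditions must be among ",
         paste(RW_CONDITIONS, collapse = ", "))
  class(cfg) <- "rw_config"
  cfg
}

# Deterministic sub-seed derivation (kept below 2^31).
rw_subseed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483647
  as.integer(s)
}

# Periodic raised-cosine bump centred at `center` (cycle fraction) with full
# width `width` and height `height`, evaluated at phases `phi` in [0, 1).
rw_bump <- function(phi, center, width, height) {
  d <- (phi - center) %% 1
  d <- pmin(d, 1 - d)
  ifelse(d < width / 2, height * 0.5 * (1 + cos(2 * pi * d / width)), 0)
}

#' Build the waveform templates of one athlete
#'
#' Each of the 42 kinematic channels is modelled as a truncated Fourier series
#' over the stride cycle plus a per-condition additive signature scaled by the
#' class-separation parameter `delta`:
#' * loss of contact adds a free-fall-like dip (toward -9.81 m/s^2) on the
#'   vertical acceleration of pelvis, shanks and feet during the flight
#'   window of the cycle;
#' * knee bent adds mid-stance amplitude changes on the sagittal angular
#'   velocity and anteroposterior acceleration of shanks and thighs.
#'
#' The left-shank sagittal angular velocity template has one dominant positive
#' peak per cycle (mid-swing) flanked by two negative minima, with the
#' post-peak minimum placed exactly at the cycle boundary so heel-strike
#' detection is well posed. Right-side templates equal left-side templates
#' shifted by half a cycle.
#'
#' @param config An [generator_config()] object.
#' @param athlete_index Athlete index in `1:config$n_athletes`.
#' @return A list of class `rw_profile` with per-channel harmonic
#'   coefficients, condition signatures and the athlete stride duration.
#' @export
make_profile <- function(config, athlete_index) {
  stopifnot(inherits(config, "rw_config"))
  if (athlete_index < 1 || athlete_index > config$n_athletes)
    stop("configuration error: athlete_index out of range")
  nh <- config$n_harmonics
  withr::with_seed(rw_subseed(config$seed, 11, athlete_index), {
    templates <- vector("list", nrow(RW_SEGMENTS))
    names(templates) <- paste(RW_SEGMENTS$segment, RW_SEGMENTS$side, sep = "_")
    for (b in seq_len(nrow(RW_SEGMENTS))) {
      seg <- RW_SEGMENTS$segment[b]
      side <- RW_SEGMENTS$side[b]
      if (side == "right") next  # filled below from the left template
      chans <- vector("list", length(RW_CHANNELS))
      names(chans) <- RW_CHANNELS
      for (ch in RW_CHANNELS) {
        is_acc <- startsWith(ch, "acc")
        base_amp <- if (is_acc) {
          if (seg == "pelvis") 2.0 else 3.0
        } else {
          if (seg == "pelvis") 30 else 80
        }
        amp <- base_amp * runif(nh, 0.3, 1.0) / seq_len(nh)
        phase <- runif(nh, 0, 2 * pi)
        if (seg == "shank" && ch == "gyr_y") {
          # -100 cos(2 pi phi) + 30 cos(4 pi phi) - 10 cos(6 pi phi): a
          # single dominant positive peak (+140 deg/s) at mid-swing
          # (phi = 0.5) and a single sharp negative minimum (-80 deg/s)
          # exactly at the cycle boundary, anchoring heel-strike detection
          # to the true stride boundary.
          amp <- c(100, 30, 10, rep(0, nh - 3))[seq_len(nh)]
          phase <- c(pi, 0, pi, rep(0, nh - 3))[seq_len(nh)]
        }
        baseline <- if (ch == "acc_z") GRAVITY else 0
        chans[[ch]] <- list(baseline = baseline, amp = amp, phase = phase)
      }
      templates[[paste(seg, side, sep = "_")]] <- chans
    }
    for (b in which(RW_SEGMENTS$side == "right")) {
      seg <- RW_SEGMENTS$segment[b]
      templates[[paste(seg, "right", sep = "_")]] <-
        templates[[paste(seg, "left", sep = "_")]]
    }
    # Per-athlete multiplicative perturbation of the oscillatory part and the
    # condition signatures (shared between sides, preserving symmetry).
    av <- config$athlete_variability
    gain <- list()
    for (seg in unique(RW_SEGMENTS$segment))
      for (ch in RW_CHANNELS)
        gain[[paste(seg, ch, sep = ".")]] <- max(0.2, 1 + av * rnorm(1))
    dur <- config$stride_duration_mean * max(0.5, 1 + av * rnorm(1) / 2)
  })
  prof <- list(
    athlete_id = sprintf("A%02d", athlete_index),
    athlete_index = as.integer(athlete_index),
    templates = templates,
    gain = gain,
    delta = config$delta,
    stride_duration_mean = dur,
    config = config
  )
  class(prof) <- "rw_profile"
  prof
}

# Evaluate one channel of a profile at stride-cycle phases `phi` (any real;
# wrapped to [0,1)) for a given condition. Right-side channels are the left
# template shifted by half a cycle.
eval_template <- function(profile, segment, side, channel, condition, phi) {
  key <- paste(segment, side, sep = "_")
  tpl <- profile$templates[[key]][[channel]]
  if (is.null(tpl)) stop("unknown segment/side/channel: ", key, "/", channel)
  g <- profile$gain[[paste(segment, channel, sep = ".")]]
  ph <- (phi + if (side == "right") 0.5 else 0) %% 1
  y <- rep(tpl$baseline, length(ph))
  for (k in seq_along(tpl$amp))
    y <- y + g * tpl$amp[k] * cos(2 * pi * k * ph + tpl$phase[k])
  d <- profile$delta * g
  if (condition == "LC") {
    # Flight-phase dip toward free fall on vertical acceleration.
    if (channel == "acc_z" && segment %in% c("pelvis", "shank", "foot")) {
      if (segment == "pelvis") {
        # the pelvis sees a flight window after each step, twice per stride
        y <- y - rw_bump(ph, 0.175, 0.15, 6 * d) - rw_bump(ph, 0.675, 0.15, 6 * d)
      } else {
        y <- y - rw_bump(ph, 0.175, 0.18, 8 * d)
      }
    }
  } else if (condition == "KB") {
    # Mid-stance signature of the bent supporting knee on shank/thigh.
    if (segment %in% c("shank", "thigh")) {
      if (channel == "gyr_y") y <- y + rw_bump(ph, 0.35, 0.20, 15 * d)
      if (channel == "acc_x") y <- y + rw_bump(ph, 0.35, 0.20, 5 * d)
    }
  }
  y
}

#' Synthesize the coach reference channel
#'
#' The coach holds a reference sensor and rotates it 180 degrees at every
#' condition transition, so its vertical acceleration flips between about
#' +9.81 and -9.81 m/s^2 at each transition index.
#'
#' @param transitions Strictly increasing 1-based sample indices at which the
#'   sign flips (first sample of the new span); may be empty.
#' @param n_samples Length of the channel.
#' @param noise_sd Additive Gaussian noise sd (m/s^2).
#' @param seed Optional seed for the noise.
#' @return Numeric vector of length `n_samples`.
#' @export
#' @examples
#' synthesize_coach_channel(c(501L), 1000L, noise_sd = 0)[c(500, 501)]
synthesize_coach_channel <- function(transitions, n_samples, noise_sd = 0.5,
                                     seed = NULL) {
  transitions <- as.integer(transitions)
  if (length(transitions) > 0) {
    if (is.unsorted(transitions, strictly = TRUE))
      stop("input error: transitions must be strictly increasing")
    if (any(transitions < 2L) || any(transitions > n_samples))
      stop("input error: transitions out of range")
  }
  sign_of <- rep(GRAVITY, n_samples)
  s <- 1
  bounds <- c(1L, transitions, n_samples + 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    sign_of[bounds[i]:(bounds[i + 1L] - 1L)] <- s * GRAVITY
    s <- -s
  }
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) rnorm(n_samples, 0, noise_sd)
             else withr::with_seed(seed, rnorm(n_samples, 0, noise_sd))
    sign_of <- sign_of + noise
  }
  sign_of
}

#' Synthesize one recording session for an athlete
#'
#' Generates a contiguous multi-lap recording: one block per condition in the
#' configured order, each containing `strides_per_condition` strides per foot
#' with Gaussian-jittered durations, all 42 kinematic channels evaluated from
#' the athlete's templates, plus the coach reference channel, and the matching
#' ground truth (heel strikes per side, per-stride labels, transitions).
#'
#' Left heel strikes fall on integer stride phases; right heel strikes are
#' offset by half a cycle. The boundary event closing one lap coincides with
#' the first stride boundary of the next lap, so a session carries
#' `n_conditions * strides_per_condition + 1` left heel strikes in total.
#'
#' @param profile An [make_profile()] object.
#' @param repetition Repetition index (>= 1); selects the noise realization.
#' @param config The [generator_config()] used to build the profile.
#' @return A list with elements `session` (class `rw_session`) and `truth`
#'   (class `rw_truth`).
#' @export
synthesize_session <- function(profile, repetition, config = profile$config) {
  stopifnot(inherits(profile, "rw_profile"))
  fs <- config$sampling_rate
  nst <- config$strides_per_condition
  seed_s <- rw_subseed(config$seed, 23, profile$athlete_index, repetition)

  withr::with_seed(seed_s, {
    blocks <- list()
    offset <- 0L           # samples already emitted
    left_hs <- integer(0)  # 1-based sample indices
    right_hs <- integer(0)
    transitions <- integer(0)
    stride_labels_left <- character(0)
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[ci]
      dur <- rnorm(nst, profile$stride_duration_mean,
                   config$stride_duration_cv * profile$stride_duration_mean)
      dur <- pmax(dur, 0.4 * profile$stride_duration_mean)
      bnd <- c(0, cumsum(dur))                # stride boundaries in seconds
      n_samp <- floor(bnd[nst + 1] * fs)      # samples in this block
      t <- (seq_len(n_samp) - 1) / fs
      idx <- findInterval(t, bnd, rightmost.closed = FALSE)
      idx <- pmin(pmax(idx, 1L), nst)
      phi <- (idx - 1) + (t - bnd[idx]) / dur[idx]   # continuous stride phase

      if (ci > 1L) transitions <- c(transitions, offset + 1L)
      # stride-start boundaries only; the shared end boundary of the final
      # block is appended after the loop, keeping the sequence strictly
      # increasing across contiguous blocks
      left_b <- offset + round(bnd[seq_len(nst)] * fs) + 1L
      left_hs <- c(left_hs, left_b)
      if (ci == length(config$conditions))
        left_hs <- c(left_hs, min(offset + round(bnd[nst + 1] * fs) + 1L,
                                  offset + n_samp))
      mid <- bnd[seq_len(nst)] + dur / 2             # right heel strikes
      right_hs <- c(right_hs, offset + round(mid * fs) + 1L)
      stride_labels_left <- c(stride_labels_left, rep(cond, nst))
      blocks[[ci]] <- list(cond = cond, phi = phi, n = n_samp)
      offset <- offset + n_samp
    }
    n_total <- offset

    # Assemble the 42 channels block by block.
    data <- matrix(0, nrow = n_total, ncol = nrow(RW_SEGMENTS) * length(RW_CHANNELS))
    colnames(data) <- as.vector(t(outer(
      paste(RW_SEGMENTS$segment, RW_SEGMENTS$side, sep = "_"),
      RW_CHANNELS, paste, sep = "_")))
    row0 <- 0L
    for (blk in blocks) {
      rows <- row0 + seq_len(blk$n)
      for (b in seq_len(nrow(RW_SEGMENTS))) {
        seg <- RW_SEGMENTS$segment[b]; side <- RW_SEGMENTS$side[b]
        for (ch in RW_CHANNELS) {
          col <- paste(seg, side, ch, sep = "_")
          data[rows, col] <- eval_template(profile, seg, side, ch, blk$cond, blk$phi)
        }
      }
      row0 <- row0 + blk$n
    }
    acc_cols <- grepl("_acc_", colnames(data))
    data[, acc_cols] <- data[, acc_cols] +
      rnorm(sum(acc_cols) * n_total, 0, config$noise_sd_acc)
    data[, !acc_cols] <- data[, !acc_cols] +
      rnorm(sum(!acc_cols) * n_total, 0, config$noise_sd_gyr)

    coach <- synthesize_coach_channel(transitions, n_total,
                                      noise_sd = config$noise_sd_acc)
  })

  # Drop duplicated lap-boundary events and anything beyond the recording.
  left_hs <- unique(left_hs[left_hs >= 1L & left_hs <= n_total])
  right_hs <- unique(right_hs[right_hs >= 1L & right_hs <= n_total])

  session <- list(
    athlete_id = profile$athlete_id,
    repetition = as.integer(repetition),
    sampling_rate = fs,
    data = data,
    coach = coach
  )
  class(session) <- "rw_session"
  truth <- list(
    heel_strikes = list(left = left_hs, right = right_hs),
    stride_labels = list(left = stride_labels_left),
    transitions = transitions,
    conditions = config$conditions
  )
  class(truth) <- "rw_truth"
  list(session = session, truth = truth)
}

#' @export
print.rw_session <- function(x, ...) {
  cat("<rw_session>", x$athlete_id, "rep", x$repetition, "-",
      nrow(x$data), "samples @", x$sampling_rate, "Hz,",
      ncol(x$data), "kinematic channels + coach channel\n")
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' @param config An [generator_config()] object.
#' @return A list of class `rw_cohort`: one element per (athlete, repetition),
#'   named `"A01_r1"` etc., each a list with `session` and `truth`; the
#'   athlete profiles are attached as attribute `profiles`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "rw_config"))
  profiles <- lapply(seq_len(config$n_athletes), function(a) make_profile(config, a))
  out <- list()
  for (a in seq_len(config$n_athletes)) {
    for (r in seq_len(config$n_repetitions)) {
      out[[sprintf("%s_r%d", profiles[[a]]$athlete_id, r)]] <-
        synthesize_session(profiles[[a]], r, config)
    }
  }
  attr(out, "profiles") <- profiles
  attr(out, "config") <- config
  class(out) <- "rw_cohort"
  out
}

# Template of one channel sampled on a regular phase grid; used by tests and
# by the class-separation diagnostics.
template_waveform <- function(profile, segment, side, channel, condition,
                              n = 200L) {
  phi <- (seq_len(n) - 1) / n
  eval_template(profile, segment, side, channel, condition, phi)
}
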