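test_that("profiles are deterministic and condition templates scale with delta", {
  cfg <- small_config()
  p1 <- make_profile(cfg, 1)
  p2 <- make_profile(cfg, 1)
  expect_identical(p1, p2)

  # delta = 0: the three condition templates coincide
  cfg0 <- small_config(delta = 0)
  p0 <- make_profile(cfg0, 1)
  for (cond in c("LC", "KB"))
    expect_equal(
      racewalkr:::template_waveform(p0, "shank", "left", "acc_z", cond),
      racewalkr:::template_waveform(p0, "shank", "left", "acc_z", "regular"))

  # template separation is linear in delta (same seed, same athlete)
  d1 <- make_profile(small_config(delta = 1), 1)
  d2 <- make_profile(small_config(delta = 2), 1)
  l2 <- function(p) {
    a <- racewalkr:::template_waveform(p, "shank", "left", "acc_z", "regular")
    b <- racewalkr:::template_waveform(p, "shank", "left", "acc_z", "LC")
    sqrt(sum((a - b)^2))
  }
  expect_gt(l2(d1), 0)
  expect_equal(l2(d2) / l2(d1), 2, tolerance = 1e-10)

  # fault signatures live on the documented channels
  kb_moves <- function(p, seg, ch) {
    a <- racewalkr:::template_waveform(p, seg, "left", ch, "regular")
    b <- racewalkr:::template_waveform(p, seg, "left", ch, "KB")
    sqrt(sum((a - b)^2))
  }
  expect_gt(kb_moves(d1, "shank", "gyr_y"), 0)
  expect_equal(kb_moves(d1, "foot", "gyr_y"), 0)
})

test_that("right-side templates are the left templates shifted half a cycle", {
  p <- make_profile(small_config(), 1)
  n <- 200L
  left <- racewalkr:::template_waveform(p, "shank", "left", "gyr_y", "regular", n)
  right <- racewalkr:::template_waveform(p, "shank", "right", "gyr_y", "regular", n)
  expect_equal(right, left[((seq_len(n) - 1 + n / 2) %% n) + 1], tolerance = 1e-10)
})

test_that("coach channel flips sign at each transition", {
  x <- synthesize_coach_channel(501L, 1000L, noise_sd = 0)
  expect_equal(unique(x[1:500]), 9.81)
  expect_equal(unique(x[501:1000]), -9.81)

  expect_equal(unique(synthesize_coach_channel(integer(0), 100L, 0)), 9.81)

  y <- synthesize_coach_channel(c(301L, 601L), 900L, 0)
  expect_equal(sign(y[c(1, 300, 301, 600, 601, 900)]),
               c(1, 1, -1, -1, 1, 1))

  expect_error(synthesize_coach_channel(c(600L, 300L), 900L, 0),
               "strictly increasing")
  expect_error(synthesize_coach_channel(1200L, 900L, 0), "out of range")
})

test_that("sessions have the documented structure and ground truth", {
  fix <- fixture_session()
  cfg <- fix$config
  s <- fix$raw; truth <- fix$truth
  expect_equal(ncol(s$data), 42)
  expect_equal(length(s$coach), nrow(s$data))
  expect_equal(length(truth$transitions), 2)
  # one contiguous block per condition, 30 strides each, shared boundaries
  expect_equal(length(truth$heel_strikes$left),
               3 * cfg$strides_per_condition + 1)
  expect_true(!is.unsorted(truth$heel_strikes$left, strictly = TRUE))
  expect_true(!is.unsorted(truth$transitions, strictly = TRUE))
  # total duration close to n_cond * strides * mean duration (athlete
  # durations are perturbed ~ athlete_variability/2)
  expect_equal(nrow(s$data) / cfg$sampling_rate,
               3 * cfg$strides_per_condition * cfg$stride_duration_mean,
               tolerance = 0.15)
})

test_that("noise-free generation repeats the same waveform every stride", {
  # athlete_variability = 0 keeps the stride at exactly 42 samples, so
  # successive strides sample identical phases
  cfg <- small_config(noise_sd_acc = 0, noise_sd_gyr = 0,
                      stride_duration_cv = 0, athlete_variability = 0)
  sim <- synthesize_session(make_profile(cfg, 1), 1, cfg)
  hs <- sim$truth$heel_strikes$left
  ch <- sim$session$data[, "shank_left_acc_z"]
  s1 <- ch[hs[5]:(hs[6] - 1)]
  s2 <- ch[hs[6]:(hs[7] - 1)]
  n <- min(length(s1), length(s2))
  expect_equal(s1[1:n], s2[1:n], tolerance = 1e-8)
})

test_that("cohorts are reproducible and have n_athletes x n_repetitions sessions", {
  cfg <- generator_config(n_athletes = 2, n_repetitions = 2,
                          strides_per_condition = 10, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_equal(length(c1), 4)
  expect_identical(c1, c2)
  expect_identical(names(c1), c("A01_r1", "A01_r2", "A02_r1", "A02_r2"))

  one <- generate_cohort(generator_config(n_athletes = 1, n_repetitions = 1,
                                          strides_per_condition = 10))
  expect_equal(length(one), 1)

  # repetitions share the profile but not the noise
  expect_false(identical(c1$A01_r1$session$data, c1$A01_r2$session$data))
  expect_equal(length(c1$A01_r1$truth$heel_strikes$left),
               length(c1$A01_r2$truth$heel_strikes$left))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_athletes = 0), "counts")
  expect_error(generator_config(delta = -1), "delta")
  expect_error(generator_config(stride_duration_mean = 0), "stride_duration")
  expect_error(make_profile(small_config(), 99), "out of range")
})
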