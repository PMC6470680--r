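# Small cohorts shared across test files; built once per test run.

small_config <- function(..., seed = 11) {
  generator_config(n_athletes = 2, n_repetitions = 2,
                   strides_per_condition = 30, seed = seed, ...)
}

# One preprocessed session + its ground truth at small scale.
fixture_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config()
      sim <- synthesize_session(make_profile(cfg, 1), 1, cfg)
      cache <<- list(raw = sim$session, truth = sim$truth,
                     prep = preprocess_session(sim$session),
                     config = cfg)
    }
    cache
  }
})

# Strides of the fixture session, all segments.
fixture_strides <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- segment_session(fixture_session()$prep)
    cache
  }
})

# Per-athlete feature datasets of a small 2-athlete, 2-repetition cohort.
fixture_datasets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(small_config())
      cache <<- cohort_datasets(cohort)
    }
    cache
  }
})

# Brute-force biased autocorrelation (independent oracle).
acf_oracle <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  vapply(0:(n - 1), function(lag) {
    sum(xc[seq_len(n - lag)] * xc[seq_len(n - lag) + lag]) / n
  }, numeric(1))
}

# Brute-force one-vs-rest metrics from a confusion matrix (independent
# oracle for compute_metrics).
metrics_oracle <- function(cm) {
  k <- nrow(cm); total <- sum(cm)
  recall <- precision <- f1 <- numeric(k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    recall[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    precision[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1[i] <- if (recall[i] + precision[i] > 0)
      2 * recall[i] * precision[i] / (recall[i] + precision[i]) else 0
  }
  list(accuracy = sum(diag(cm)) / total, recall = recall,
       precision = precision, f1 = f1)
}

# Fraction of reference events recovered within a tolerance.
event_recovery <- function(detected, truth, tol = 3) {
  if (length(detected) == 0) return(0)
  d <- vapply(truth, function(t) min(abs(detected - t)), numeric(1))
  mean(d <= tol)
}
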