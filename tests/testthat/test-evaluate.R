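test_that("confusion matrices count true-vs-predicted pairs", {
  cm <- confusion_matrix(c("regular", "LC", "KB"), c("regular", "KB", "KB"))
  expect_equal(cm["regular", "regular"], 1)
  expect_equal(cm["LC", "KB"], 1)
  expect_equal(cm["KB", "KB"], 1)
  expect_equal(sum(cm), 3)
  perfect <- confusion_matrix(rep(c("regular", "LC", "KB"), 5),
                              rep(c("regular", "LC", "KB"), 5))
  expect_equal(sum(diag(perfect)), sum(perfect))
  expect_error(confusion_matrix(c("a", "b"), "a"), "lengths differ")
})

test_that("metrics match hand-evaluated and brute-force values", {
  m <- compute_metrics(diag(c(10, 10, 10)))
  expect_equal(m$accuracy, 1)
  expect_equal(unname(m$recall), c(1, 1, 1))
  expect_equal(m$f1_overall, 1)

  cm <- matrix(c(8, 1, 1,
                 2, 8, 0,
                 0, 2, 8), 3, 3, byrow = TRUE)
  m2 <- compute_metrics(cm)
  expect_equal(m2$accuracy, 24 / 30)
  expect_equal(unname(m2$recall), c(0.8, 0.8, 0.8))
  expect_equal(unname(m2$precision), c(0.8, 8 / 11, 8 / 9))
  expect_equal(unname(m2$f1),
               2 * c(0.8 * 0.8 / 1.6, 0.8 * 8 / 11 / (0.8 + 8 / 11),
                     0.8 * 8 / 9 / (0.8 + 8 / 9)))
  expect_equal(m2$precision_overall, mean(c(0.8, 8 / 11, 8 / 9)))

  # oracle agreement on random integer confusion matrices
  set.seed(12)
  for (i in 1:200) {
    cm <- matrix(rpois(9, 8), 3, 3)
    if (any(rowSums(cm) == 0)) next
    m <- suppressWarnings(compute_metrics(cm))
    o <- metrics_oracle(cm)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(unname(m$recall), o$recall)
    expect_equal(unname(m$precision), o$precision)
    expect_equal(unname(m$f1), o$f1)
  }

  # balanced classes: mean recall equals overall accuracy
  set.seed(13)
  for (i in 1:50) {
    cm <- matrix(rpois(9, 5), 3, 3)
    rs <- rowSums(cm)
    if (any(rs == 0)) next
    cm <- cm / rs * 10  # balance the true-class totals
    m <- suppressWarnings(compute_metrics(cm))
    expect_equal(mean(m$recall), m$accuracy, tolerance = 1e-12)
  }

  # never-predicted class: precision 0 with warning
  cm0 <- matrix(c(5, 5, 0, 2, 8, 0, 1, 9, 0), 3, 3, byrow = TRUE)
  expect_warning(m0 <- compute_metrics(cm0), "undefined")
  expect_equal(unname(m0$precision[3]), 0)
})

test_that("aggregation reports cross-athlete mean and sample sd", {
  rec <- data.frame(
    athlete_id = c("A01", "A02"), classifier = "SVMq", segment = "SH",
    combo = "a", name = "SVMqaSH",
    cm11 = c(8, 9), cm12 = c(1, 1), cm13 = c(1, 0),
    cm21 = c(1, 0), cm22 = c(9, 10), cm23 = c(0, 0),
    cm31 = c(0, 0), cm32 = c(0, 0), cm33 = c(10, 10),
    stringsAsFactors = FALSE)
  agg <- aggregate_results(rec)
  a1 <- 27 / 30; a2 <- 29 / 30
  expect_equal(agg$A_mean, mean(c(a1, a2)))
  expect_equal(agg$A_sd, sd(c(a1, a2)))
  # two athletes 0.8 / 0.9 -> mean 0.85, sample sd ~0.0707
  expect_equal(sd(c(0.8, 0.9)), 0.0707, tolerance = 1e-3)

  rec1 <- rec[1, ]
  expect_warning(agg1 <- aggregate_results(rec1), "single athlete")
  expect_equal(agg1$A_sd, 0)
})

test_that("the funnel applies the four criteria in order with rounding", {
  mk <- function(A, R = rep(1, 3), Po = 1, P = rep(1, 3), name = "X") {
    data.frame(name = name, A_mean = A,
               R_regular_mean = R[1], R_LC_mean = R[2], R_KB_mean = R[3],
               P_overall_mean = Po, P_regular_mean = P[1],
               P_LC_mean = P[2], P_KB_mean = P[3], stringsAsFactors = FALSE)
  }
  agg <- rbind(
    mk(1, name = "all_one"),
    mk(0.79, name = "low_A"),
    mk(0.9, R = c(0.9, 0.79, 0.9), name = "low_R"),
    mk(0.9, Po = 0.7, name = "low_Po"),
    mk(0.9, P = c(0.9, 0.9, 0.5), name = "low_P"),
    mk(0.795, name = "rounds_up"))  # 0.795 rounds to 0.8 at 2 decimals
  f <- selection_funnel(agg)
  expect_equal(f$outcome$stage_reached,
               c("survivor", "rejected@1", "rejected@2", "rejected@3",
                 "rejected@4", "survivor"))
  expect_setequal(f$survivors, c("all_one", "rounds_up"))
  # nesting: survivors at stage k are a subset of survivors at stage k-1
  counts <- vapply(1:4, function(k) funnel_survivors_at(f, k), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(selection_funnel(agg[, -2]), "missing metric")
})

test_that("binary collapse merges the faults and preserves totals", {
  expect_equal(collapse_binary(diag(c(10, 10, 10))),
               matrix(c(10, 0, 0, 20), 2, 2, byrow = TRUE,
                      dimnames = list(true = c("regular", "irregular"),
                                      predicted = c("regular", "irregular"))))
  set.seed(3)
  for (i in 1:50) {
    cm <- matrix(rpois(9, 6), 3, 3)
    b <- collapse_binary(cm)
    expect_equal(sum(b), sum(cm))
    # LC <-> KB confusions land on the binary diagonal, so accuracy can
    # only rise
    expect_gte(sum(diag(b)) / sum(b), sum(diag(cm)) / sum(cm))
  }
})

test_that("the goodness index is the ROC distance to the perfect point", {
  expect_equal(goodness_index(list(tp = 1, tn = 1))$G, 0)
  expect_equal(goodness_index(list(tp = 1, tn = 1))$category, "optimum")
  g_chance <- goodness_index(list(tp = 0.5, tn = 0.5))$G
  expect_equal(g_chance, sqrt(0.5))
  expect_equal(round(g_chance, 1), 0.7)
  expect_equal(goodness_index(list(tp = 0, tn = 0))$G, sqrt(2))
  expect_equal(goodness_index(list(tp = 0, tn = 0))$category, "bad")
  # from a matrix
  b <- matrix(c(9, 1, 2, 8), 2, 2, byrow = TRUE)
  g <- goodness_index(b)
  expect_equal(g$tn_rate, 0.9)
  expect_equal(g$tp_rate, 0.8)
  expect_equal(g$G, sqrt(0.1^2 + 0.2^2))
  expect_error(goodness_index(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)),
               "both classes")
  # monotone decreasing in each rate; bounded by [0, sqrt(2)]
  grid <- seq(0, 1, by = 0.1)
  for (tn in c(0.2, 0.7)) {
    gs <- vapply(grid, function(tp) goodness_index(list(tp = tp, tn = tn))$G,
                 numeric(1))
    expect_true(all(diff(gs) < 0))
    expect_true(all(gs >= 0 & gs <= sqrt(2)))
  }
})
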