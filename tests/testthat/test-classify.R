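test_that("the kNN distances match their closed forms", {
  expect_equal(pairwise_distance("euclidean", c(0, 0), c(3, 4)), 5)
  expect_equal(pairwise_distance("cosine", c(1, 2), c(1, 2)), 0, tolerance = 1e-12)
  expect_equal(pairwise_distance("cosine", c(1, 0), c(0, 1)), 1)
  expect_equal(pairwise_distance("minkowski", c(0, 0), c(1, 1), q = 3),
               2^(1 / 3))
  expect_equal(pairwise_distance("weighted", c(0, 0), c(3, 4),
                                 w = c(1, 1)), 5)
  expect_equal(pairwise_distance("weighted", c(0, 0), c(3, 4),
                                 w = c(4, 1)), sqrt(4 * 9 + 16))
  expect_error(pairwise_distance("euclidean", 1:3, 1:2), "length")
  expect_error(pairwise_distance("cosine", c(0, 0), c(1, 1)), "zero vector")

  # the vectorized distance matrices agree with the scalar definition
  set.seed(1)
  a <- matrix(rnorm(12), 3); b <- matrix(rnorm(20), 5)
  for (m in c("euclidean", "cosine", "minkowski")) {
    d <- racewalkr:::rw_dist_matrix(m, a, b)
    expect_equal(d[2, 3], pairwise_distance(m, a[2, ], b[3, ]),
                 tolerance = 1e-10)
  }
})

test_that("exactly nine canonical specs exist with their documented settings", {
  specs <- classifier_spec()
  expect_length(specs, 9)
  expect_equal(specs$kNNf$k, 1L)
  expect_equal(specs$kNNw$vote, "squared_inverse")
  expect_equal(specs$kNNcu$q, 3)
  expect_equal(specs$SVMq$degree, 2L)
  expect_equal(specs$SVMq$cost, 1)
  expect_equal(specs$ANN$hidden, c(10L, 10L, 10L))
  expect_equal(specs$DTf$max_splits, 100L)
  expect_error(classifier_spec("SVMx"), "unknown classifier")
})

test_that("classifiers satisfy their sanity oracles", {
  set.seed(5)
  n <- 60
  x <- rbind(matrix(rnorm(n * 2, 0), ncol = 2),
             matrix(rnorm(n * 2, 6), ncol = 2),
             matrix(rnorm(n * 2, 12), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("regular", "LC", "KB"), each = n)

  # kNN with k = 1 memorizes its training set
  m <- train_classifier(classifier_spec("kNNf"), x, y)
  expect_equal(predict(m, x), y)

  # linear SVM separates well-separated Gaussians
  m2 <- train_classifier(classifier_spec("SVMl"), x, y)
  set.seed(6)
  xt <- rbind(matrix(rnorm(20, 0), ncol = 2), matrix(rnorm(20, 6), ncol = 2),
              matrix(rnorm(20, 12), ncol = 2))
  colnames(xt) <- colnames(x)
  yt <- rep(c("regular", "LC", "KB"), each = 10)
  expect_equal(predict(m2, xt), yt)

  # every classifier type is deterministic given its seed
  for (nm in c("DTf", "SVMq", "kNNw", "kNNco", "kNNcu", "ANN")) {
    sp <- classifier_spec(nm, seed = 3L)
    p1 <- predict(train_classifier(sp, x, y), xt)
    p2 <- predict(train_classifier(sp, x, y), xt)
    expect_identical(p1, p2)
    expect_gte(mean(p1 == yt), 0.9)  # easy problem: all should do well
  }
})

test_that("kNN ties break toward the smallest class index", {
  x <- rbind(c(0, 0), c(2, 0))
  y <- c("KB", "LC")
  spec <- classifier_spec("kNNco")  # k = 10 > n, uniform votes, full tie
  spec$metric <- "euclidean"
  m <- train_classifier(spec, x, y, levels = c("regular", "LC", "KB"))
  # test point equidistant: one vote each; LC precedes KB in the class order
  expect_equal(predict(m, matrix(c(1, 0), 1)), "LC")
})

test_that("cross-validation averages the two fold confusion matrices", {
  ds <- fixture_datasets()
  fm1 <- ds$A01[[1]]$SH_a
  fm2 <- ds$A01[[2]]$SH_a
  spec <- classifier_spec("SVMq")
  cm <- cross_validate(spec, fm1, fm2)
  m12 <- train_classifier(spec, fm1$x, fm1$labels)
  m21 <- train_classifier(spec, fm2$x, fm2$labels)
  cm12 <- confusion_matrix(fm2$labels, predict(m12, fm2$x))
  cm21 <- confusion_matrix(fm1$labels, predict(m21, fm1$x))
  expect_equal(cm, (cm12 + cm21) / 2)
  # row sums equal averaged per-condition test counts
  expect_equal(rowSums(cm),
               (rowSums(cm12) + rowSums(cm21)) / 2)

  # label permutation (fixed seed) drops accuracy to chance
  set.seed(8)
  fm1p <- fm1; fm1p$labels <- sample(fm1$labels)
  fm2p <- fm2; fm2p$labels <- sample(fm2$labels)
  cmp <- cross_validate(spec, fm1p, fm2p)
  acc <- sum(diag(cmp)) / sum(cmp)
  se <- sqrt((1 / 3) * (2 / 3) / sum(cmp))
  expect_lt(abs(acc - 1 / 3), 3 * se)

  expect_error(cross_validate(spec, fm1, ds$A01[[2]]$SH_aw), "schema")
})

test_that("the bank yields one named record per athlete-dataset-classifier", {
  ds <- fixture_datasets()
  # keep runtime modest: run 3 classifiers on all 12 datasets, all on one
  specs3 <- classifier_spec()[c("DTf", "SVMq", "kNNf")]
  rec <- run_bank(ds, specs = specs3)
  expect_equal(nrow(rec), 2 * 12 * 3)
  expect_equal(sum(rec$athlete_id == "A01"), 36)
  expect_equal(unique(table(rec$name)), 2L)
  expect_true("SVMqaSH" %in% rec$name)
  expect_equal(record_name("SVMq", "a", "SH"), "SVMqaSH")
  expect_equal(record_name("kNNw", "aw", "FT"), "kNNwa\u03c9FT")
  # confusion-matrix row sums are conserved per record
  rs <- rowSums(rec[rec$name == "SVMqaSH" & rec$athlete_id == "A01",
                    paste0("cm", c(11, 12, 13))])
  expect_gt(rs, 0)
})
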