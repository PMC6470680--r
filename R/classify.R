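RW_CLASSIFIERS <- c("DTf", "SVMl", "SVMq", "SVMc",
                    "kNNf", "kNNco", "kNNcu", "kNNw", "ANN")

#' The nine canonical classifier specifications
#'
#' Returns the complete hyperparameter set for each classifier of the bank:
#' * `DTf` — fine decision tree, Gini split criterion, at most 100 splits, no
#'   surrogate splits;
#' * `SVMl`, `SVMq`, `SVMc` — support vector machines with polynomial kernel
#'   of degree 1, 2, 3; box constraint 1, kernel scale 1, one-vs-one
#'   multiclass scheme;
#' * `kNNf` — k-nearest neighbours, Euclidean distance, k = 1;
#' * `kNNco` — cosine distance, k = 10;
#' * `kNNcu` — cubic Minkowski distance (q = 3), k = 10;
#' * `kNNw` — Euclidean distance, k = 10, votes weighted by the squared
#'   inverse of the neighbour distance;
#' * `ANN` — feed-forward network with three hidden layers (10 units each),
#'   cross-entropy objective, conjugate-gradient training, at most 1000
#'   iterations.
#'
#' @param name Classifier name; omit for the full named list of 9 specs.
#' @param seed Training seed stored in the spec (used by the ANN weight
#'   initialization).
#' @return A list of class `rw_spec`, or a named list of all nine.
#' @export
classifier_spec <- function(name = NULL, seed = 1L) {
  make <- function(nm) {
    spec <- switch(nm,
      DTf   = list(type = "dt", max_splits = 100L),
      SVMl  = list(type = "svm", degree = 1L, cost = 1, kernel_scale = 1),
      SVMq  = list(type = "svm", degree = 2L, cost = 1, kernel_scale = 1),
      SVMc  = list(type = "svm", degree = 3L, cost = 1, kernel_scale = 1),
      kNNf  = list(type = "knn", metric = "euclidean", k = 1L, vote = "uniform"),
      kNNco = list(type = "knn", metric = "cosine", k = 10L, vote = "uniform"),
      kNNcu = list(type = "knn", metric = "minkowski", q = 3, k = 10L,
                   vote = "uniform"),
      kNNw  = list(type = "knn", metric = "euclidean", k = 10L,
                   vote = "squared_inverse"),
      ANN   = list(type = "ann", hidden = c(10L, 10L, 10L), maxit = 1000L),
      stop("configuration error: unknown classifier '", nm, "'")
    )
    spec$name <- nm
    spec$seed <- as.integer(seed)
    spec$standardize <- TRUE
    class(spec) <- "rw_spec"
    spec
  }
  if (is.null(name)) {
    specs <- lapply(RW_CLASSIFIERS, make)
    names(specs) <- RW_CLASSIFIERS
    return(specs)
  }
  make(name)
}

#' Pairwise distances of the k-nearest-neighbour variants
#'
#' * `euclidean`: `sqrt(sum((x - y)^2))`;
#' * `cosine`: `1 - (x . y) / (||x|| ||y||)` (one minus the cosine
#'   similarity, so that identical directions give 0);
#' * `minkowski`: `(sum(|x - y|^q))^(1/q)`, cubic for `q = 3`;
#' * `weighted`: `sqrt(sum(w * (x - y)^2))` with weights `w`.
#'
#' @param metric One of `"euclidean"`, `"cosine"`, `"minkowski"`,
#'   `"weighted"`.
#' @param x,y Feature vectors of equal length.
#' @param q Minkowski exponent (default 3).
#' @param w Non-negative weights for `"weighted"` (default all 1).
#' @return A scalar distance >= 0.
#' @export
#' @examples
#' pairwise_distance("euclidean", c(0, 0), c(3, 4))
pairwise_distance <- function(metric = c("euclidean", "cosine", "minkowski",
                                         "weighted"),
                              x, y, q = 3, w = NULL) {
  metric <- match.arg(metric)
  if (length(x) != length(y)) stop("input error: length mismatch")
  switch(metric,
    euclidean = sqrt(sum((x - y)^2)),
    cosine = {
      nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
      if (nx == 0 || ny == 0)
        stop("input error: cosine distance undefined for a zero vector")
      1 - sum(x * y) / (nx * ny)
    },
    minkowski = sum(abs(x - y)^q)^(1 / q),
    weighted = {
      if (is.null(w)) w <- rep(1, length(x))
      sqrt(sum(w * (x - y)^2))
    }
  )
}

# Full test-by-train distance matrix for one metric.
rw_dist_matrix <- function(metric, test_x, train_x, q = 3) {
  if (metric == "euclidean") {
    cross <- tcrossprod(test_x, train_x)
    d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") - 2 * cross
    sqrt(pmax(d2, 0))
  } else if (metric == "cosine") {
    nt <- sqrt(rowSums(test_x^2)); nr <- sqrt(rowSums(train_x^2))
    if (any(nt == 0) || any(nr == 0))
      stop("input error: cosine distance undefined for a zero vector")
    1 - tcrossprod(test_x / nt, train_x / nr)
  } else if (metric == "minkowski") {
    d <- matrix(0, nrow(test_x), nrow(train_x))
    for (i in seq_len(nrow(test_x)))
      d[i, ] <- rowSums(abs(sweep(train_x, 2, test_x[i, ]))^q)^(1 / q)
    d
  } else stop("configuration error: unknown metric '", metric, "'")
}

# kNN prediction with vote weighting and deterministic tie-breaking (ties go
# to the smallest class index in `levels`).
rw_knn_predict <- function(train_x, train_y, test_x, k, metric, vote,
                           levels, q = 3) {
  d <- rw_dist_matrix(metric, test_x, train_x, q = q)
  k <- min(k, nrow(train_x))
  out <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    nn <- order(d[i, ])[seq_len(k)]
    dd <- d[i, nn]
    wts <- if (vote == "squared_inverse") {
      if (any(dd == 0)) as.numeric(dd == 0) else 1 / dd^2
    } else rep(1, k)
    score <- vapply(levels, function(lv) sum(wts[train_y[nn] == lv]),
                    numeric(1))
    out[i] <- levels[which.max(score)]  # which.max takes the first maximum
  }
  out
}

# ---- three-hidden-layer MLP (tanh hidden units, softmax output, -----------
# ---- cross-entropy loss, conjugate-gradient training) ---------------------

rw_mlp_shapes <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  lapply(seq_len(length(sizes) - 1L),
         function(l) c(sizes[l], sizes[l + 1L]))
}

rw_mlp_unpack <- function(par, shapes) {
  pos <- 0L
  lapply(shapes, function(s) {
    nw <- s[1] * s[2]
    W <- matrix(par[pos + seq_len(nw)], s[1], s[2])
    b <- par[pos + nw + seq_len(s[2])]
    pos <<- pos + nw + s[2]
    list(W = W, b = b)
  })
}

rw_mlp_loss_grad <- function(par, shapes, x, yind) {
  L <- rw_mlp_unpack(par, shapes)
  n <- nrow(x)
  acts <- list(x)
  a <- x
  for (l in seq_along(L)) {
    z <- sweep(a %*% L[[l]]$W, 2, L[[l]]$b, "+")
    a <- if (l < length(L)) tanh(z) else z
    acts[[l + 1L]] <- a
  }
  z <- a - apply(a, 1, max)                  # stabilized softmax
  ez <- exp(z)
  p <- ez / rowSums(ez)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), yind)], 1e-12)))
  delta <- p
  delta[cbind(seq_len(n), yind)] <- delta[cbind(seq_len(n), yind)] - 1
  delta <- delta / n
  grad <- vector("list", length(L))
  for (l in rev(seq_along(L))) {
    grad[[l]] <- list(W = crossprod(acts[[l]], delta), b = colSums(delta))
    if (l > 1L)
      delta <- (delta %*% t(L[[l]]$W)) * (1 - acts[[l]]^2)
  }
  gvec <- unlist(lapply(grad, function(g) c(as.numeric(g$W), g$b)))
  list(loss = loss, grad = gvec)
}

rw_mlp_train <- function(x, y, hidden, maxit, seed, levels) {
  yind <- match(y, levels)
  shapes <- rw_mlp_shapes(ncol(x), hidden, length(levels))
  npar <- sum(vapply(shapes, function(s) s[1] * s[2] + s[2], numeric(1)))
  par0 <- withr::with_seed(seed, {
    unlist(lapply(shapes, function(s)
      c(runif(s[1] * s[2], -1, 1) / sqrt(s[1]), rep(0, s[2]))))
  })
  stopifnot(length(par0) == npar)
  fit <- optim(par0,
               fn = function(p) rw_mlp_loss_grad(p, shapes, x, yind)$loss,
               gr = function(p) rw_mlp_loss_grad(p, shapes, x, yind)$grad,
               method = "CG", control = list(maxit = maxit))
  list(par = fit$par, shapes = shapes)
}

rw_mlp_predict <- function(model, x, levels) {
  L <- rw_mlp_unpack(model$par, model$shapes)
  a <- x
  for (l in seq_along(L)) {
    z <- sweep(a %*% L[[l]]$W, 2, L[[l]]$b, "+")
    a <- if (l < length(L)) tanh(z) else z
  }
  levels[max.col(a, ties.method = "first")]
}

# ---------------------------------------------------------------------------

#' Train one classifier of the bank
#'
#' Features are z-scored with training-set statistics (constant columns get
#' unit scale); the same transform is applied at prediction time. Training is
#' deterministic given `spec$seed`.
#'
#' @param spec An [classifier_spec()] object.
#' @param x Numeric feature matrix (rows = strides).
#' @param labels Condition label per row.
#' @param levels Class order; defaults to the race-walking conditions.
#' @return A fitted model of class `rw_model` with a [predict][predict.rw_model]
#'   method returning one label per row.
#' @export
train_classifier <- function(spec, x, labels, levels = RW_CONDITIONS) {
  stopifnot(inherits(spec, "rw_spec"))
  levels <- levels[levels %in% unique(labels)]
  if (length(levels) < 2L)
    stop("insufficient-data error: need at least two classes in training data")
  mu <- colMeans(x); sc <- apply(x, 2, sd)
  sc[sc == 0] <- 1
  if (isTRUE(spec$standardize)) xs <- scale(x, mu, sc) else xs <- x
  fit <- switch(spec$type,
    svm = e1071::svm(x = xs, y = factor(labels, levels = levels),
                     kernel = if (spec$degree == 1L) "linear" else "polynomial",
                     degree = spec$degree, gamma = 1 / spec$kernel_scale^2,
                     coef0 = 1, cost = spec$cost, scale = FALSE),
    dt = {
      df <- data.frame(.y = factor(labels, levels = levels), xs)
      tr <- rpart::rpart(.y ~ ., data = df, method = "class",
                         parms = list(split = "gini"),
                         control = rpart::rpart.control(
                           cp = 0, xval = 0, maxsurrogate = 0,
                           usesurrogate = 0, maxcompete = 0))
      # cap the number of splits at spec$max_splits by pruning
      ct <- tr$cptable
      ok <- ct[ct[, "nsplit"] <= spec$max_splits, , drop = FALSE]
      rpart::prune(tr, cp = ok[nrow(ok), "CP"])
    },
    knn = list(x = xs, y = as.character(labels)),
    ann = rw_mlp_train(xs, as.character(labels), spec$hidden, spec$maxit,
                       spec$seed, levels)
  )
  out <- list(spec = spec, fit = fit, mu = mu, sc = sc, levels = levels)
  class(out) <- "rw_model"
  out
}

#' Predict condition labels with a fitted classifier
#'
#' @param object An `rw_model` from [train_classifier()].
#' @param newdata Feature matrix with the training schema.
#' @param ... Unused.
#' @return Character vector of predicted labels, one per row.
#' @export
predict.rw_model <- function(object, newdata, ...) {
  xs <- if (isTRUE(object$spec$standardize))
    scale(newdata, object$mu, object$sc) else newdata
  spec <- object$spec
  switch(spec$type,
    svm = as.character(predict(object$fit, xs)),
    dt = {
      df <- as.data.frame(xs)
      as.character(predict(object$fit, df, type = "class"))
    },
    knn = rw_knn_predict(object$fit$x, object$fit$y, xs, spec$k, spec$metric,
                         spec$vote, object$levels,
                         q = if (is.null(spec$q)) 3 else spec$q),
    ann = rw_mlp_predict(object$fit, xs, object$levels)
  )
}

#' Two-fold session cross-validation of one classifier on one dataset
#'
#' Trains on the first repetition and tests on the second, then vice versa;
#' the two fold confusion matrices are averaged elementwise.
#'
#' @param spec An [classifier_spec()] object.
#' @param fm1,fm2 `rw_features` datasets of the two repetitions (same segment,
#'   combo and feature schema).
#' @param levels Class order of the confusion matrix.
#' @return Averaged 3x3 confusion matrix (rows = true, columns = predicted).
#' @export
cross_validate <- function(spec, fm1, fm2, levels = RW_CONDITIONS) {
  stopifnot(inherits(fm1, "rw_features"), inherits(fm2, "rw_features"))
  if (!identical(colnames(fm1$x), colnames(fm2$x)))
    stop("input error: feature schema mismatch between repetitions")
  if (!setequal(unique(fm1$labels), unique(fm2$labels)))
    stop("insufficient-data error: label sets differ between repetitions")
  cms <- lapply(list(list(fm1, fm2), list(fm2, fm1)), function(fold) {
    model <- train_classifier(spec, fold[[1]]$x, fold[[1]]$labels, levels)
    pred <- predict(model, fold[[2]]$x)
    confusion_matrix(fold[[2]]$labels, pred, levels)
  })
  (cms[[1]] + cms[[2]]) / 2
}

#' Run the full classifier bank for a cohort
#'
#' For every athlete, every one of the 12 (segment x signal-combination)
#' datasets and every one of the 9 classifiers, performs the two-repetition
#' cross-validation, yielding 108 result records per athlete. Each record is
#' named `<classifier><combo><segment>` (combo printed as `a`, omega, or a-omega), e.g. `"SVMqaSH"`.
#'
#' @param datasets Nested list: `datasets[[athlete]][[repetition]]` is the
#'   named list of 12 `rw_features` from [build_datasets()].
#' @param specs Classifier specs (default all nine).
#' @param keys Dataset keys to evaluate (default all 12).
#' @return Data frame with one row per record: athlete, classifier, segment,
#'   combo, name, and the nine confusion-matrix cells `cm11`..`cm33` (row =
#'   true, column = predicted, class order regular, LC, KB).
#' @export
run_bank <- function(datasets, specs = classifier_spec(), keys = NULL) {
  records <- list(); k <- 0L
  for (ath in names(datasets)) {
    reps <- datasets[[ath]]
    if (length(reps) != 2L)
      stop("input error: athlete '", ath, "' must have exactly 2 repetitions")
    use_keys <- if (is.null(keys)) names(reps[[1]]) else keys
    for (key in use_keys) {
      if (is.null(reps[[1]][[key]]) || is.null(reps[[2]][[key]]))
        stop("input error: missing dataset '", key, "' for athlete '", ath, "'")
      for (spec in specs) {
        cm <- cross_validate(spec, reps[[1]][[key]], reps[[2]][[key]])
        fm <- reps[[1]][[key]]
        k <- k + 1L
        records[[k]] <- data.frame(
          athlete_id = ath, classifier = spec$name,
          segment = RW_SEGMENT_CODES[[fm$segment]], combo = fm$combo,
          name = record_name(spec$name, fm$combo, RW_SEGMENT_CODES[[fm$segment]]),
          t(as.numeric(t(cm))), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, records)
  cmn <- as.vector(t(outer(1:3, 1:3, function(i, j) paste0("cm", i, j))))
  names(out)[6:14] <- cmn
  rownames(out) <- NULL
  out
}

#' Nomenclature of a classifier-dataset combination
#'
#' @param classifier,combo,segment Components of the name; `combo` is one of
#'   `"a"`, `"w"`, `"aw"` and is printed as `a`, `\u03c9`, `a\u03c9`.
#' @return Character name such as `"SVMqaSH"`.
#' @export
record_name <- function(classifier, combo, segment) {
  combo_print <- c(a = "a", w = "\u03c9", aw = "a\u03c9")[combo]
  paste0(classifier, combo_print, segment)
}
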