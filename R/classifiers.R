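#' Stratified train/test split
#'
#' Splits a sample set per class: `round(train_fraction * n)` points of
#' each class (half-up rounding) are tagged `train`, the remainder
#' `test`. Both splits are guaranteed non-empty for every class, so at
#' the boundary (e.g. two points with `train_fraction` near 1) the
#' split degrades to 1/1. Membership is deterministic given the seed.
#'
#' @param samples a `sample_set` data.frame (see [read_samples()]).
#' @param train_fraction fraction of points per class used for
#'   training, in (0, 1).
#' @param seed integer RNG seed.
#' @return the sample set with its `split` column filled.
#' @export
stratified_split <- function(samples, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  tab <- table(samples$class)
  if (any(tab < 2L))
    stop("class(es) with fewer than 2 samples cannot be split: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  set.seed(seed)
  samples$split <- NA_character_
  for (cl in names(tab)) {
    i <- which(samples$class == as.integer(cl))
    n <- length(i)
    n_train <- floor(train_fraction * n + 0.5)   # round half-up
    n_train <- min(max(n_train, 1L), n - 1L)
    tr <- sample(i, n_train)
    samples$split[tr] <- "train"
    samples$split[setdiff(i, tr)] <- "test"
  }
  samples
}

default_hyperparams <- function(kind, p) {
  switch(kind,
    RF = list(ntree = 500L, mtry = max(1L, floor(sqrt(p)))),
    SVM = list(kernel = "radial", cost = 10, gamma = 1 / p),
    WKNN = list(k = 11L, kernel = "triangular", minkowski = 2),
    ANN = list(size = max(1L, round(2 * p / 3)), decay = 5e-4,
               maxit = 500L),
    NB = list(var_floor = 1e-9),
    stop("unknown classifier kind: ", kind))
}

scale_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mean = mu, sd = sd)
}
scale_apply <- function(x, s) sweep(sweep(x, 2L, s$mean), 2L, s$sd, "/")

#' Train one probabilistic classifier backend
#'
#' Uniform harness over the five supported backends: random forest
#' (`RF`, tree-vote probabilities), support vector machine (`SVM`,
#' radial kernel with Platt pairwise-coupled probabilities), weighted
#' k-nearest neighbours (`WKNN`, kernel-weighted neighbour frequencies
#' on standardized features), single-hidden-layer neural network
#' (`ANN`, softmax outputs) and Gaussian naive Bayes (`NB`, posteriors
#' with a variance floor). Distance/margin backends (SVM, WKNN, ANN)
#' see z-scored features fitted on the training set; RF and NB see raw
#' features.
#'
#' @param kind one of `"RF"`, `"SVM"`, `"WKNN"`, `"ANN"`, `"NB"`.
#' @param features numeric training matrix with column names.
#' @param labels integer class codes (every scheme class must appear).
#' @param scheme a [lulc_scheme()].
#' @param hyperparams named list overriding the backend defaults.
#' @param seed integer seed; fits are reproducible given it.
#' @return object of class `lulc_classifier`.
#' @export
train_backend <- function(kind, features, labels, scheme = lulc_scheme(),
                          hyperparams = list(), seed = 1L) {
  kind <- match.arg(kind, c("RF", "SVM", "WKNN", "ANN", "NB"))
  features <- as.matrix(features)
  if (is.null(colnames(features))) stop("training features must be named")
  if (nrow(features) == 0L) stop("empty training set")
  present <- sort(unique(labels))
  if (!all(scheme$codes %in% present))
    stop("training set is missing class(es): ",
         paste(scheme$names[!scheme$codes %in% present], collapse = ", "))
  y <- factor(class_name(scheme, labels), levels = scheme$names)
  p <- ncol(features)
  hp <- utils::modifyList(default_hyperparams(kind, p), hyperparams)
  sds <- apply(features, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance feature(s): ",
            paste(colnames(features)[sds == 0], collapse = ", "))
  scaler <- if (kind %in% c("SVM", "WKNN", "ANN")) scale_fit(features) else NULL
  x <- if (is.null(scaler)) features else scale_apply(features, scaler)

  set.seed(seed)
  fit <- switch(kind,
    RF = randomForest::randomForest(x, y, ntree = hp$ntree, mtry = hp$mtry),
    SVM = e1071::svm(x, y, kernel = hp$kernel, cost = hp$cost,
                     gamma = hp$gamma, probability = TRUE, scale = FALSE),
    WKNN = {
      if (hp$k + 1L > nrow(x)) {
        hp$k <- max(1L, nrow(x) - 1L)
        warning("k truncated to ", hp$k, " (too few training points)")
      }
      list(x = x, y = y)
    },
    ANN = {
      err <- NULL
      f <- tryCatch(
        nnet::nnet(x, nnet::class.ind(y), size = hp$size, decay = hp$decay,
                   maxit = hp$maxit, softmax = TRUE, trace = FALSE,
                   MaxNWts = 100000L),
        error = function(e) { err <<- e; NULL })
      if (is.null(f)) stop("ANN backend failed: ", conditionMessage(err))
      f
    },
    NB = {
      f <- e1071::naiveBayes(x, y)
      floor_sd <- sqrt(hp$var_floor)
      f$tables <- lapply(f$tables, function(tb) {
        tb[, 2L] <- pmax(tb[, 2L], floor_sd); tb
      })
      f
    })
  structure(list(
    kind = kind, fit = fit, feature_names = colnames(features),
    scaler = scaler,
    medians = apply(features, 2L, stats::median),
    hyperparams = hp, scheme = scheme, seed = seed,
    n_per_class = table(y)), class = "lulc_classifier")
}

#' @export
print.lulc_classifier <- function(x, ...) {
  cat("<lulc_classifier> ", x$kind, ", ", length(x$feature_names),
      " features, ", sum(x$n_per_class), " training samples\n", sep = "")
  invisible(x)
}

wknn_proba <- function(fit, xq, k, kernel, minkowski, levels) {
  if (minkowski == 2) {
    d2 <- outer(rowSums(xq^2), rowSums(fit$x^2), "+") - 2 * tcrossprod(xq, fit$x)
    dm <- sqrt(pmax(d2, 0))
  } else {
    dm <- t(apply(xq, 1L, function(q)
      (colSums(abs(t(fit$x) - q)^minkowski))^(1 / minkowski)))
  }
  out <- matrix(0, nrow(xq), length(levels), dimnames = list(NULL, levels))
  for (r in seq_len(nrow(xq))) {
    o <- order(dm[r, ])[seq_len(k + 1L)]
    d <- dm[r, o]
    dref <- d[k + 1L]
    nb <- o[seq_len(k)]
    w <- switch(kernel,
      triangular = if (dref > 0) pmax(1 - d[seq_len(k)] / dref, 0)
                   else rep(1, k),
      rectangular = rep(1, k),
      stop("unknown WKNN kernel: ", kernel))
    if (sum(w) <= 0) w <- rep(1, k)   # all k neighbours at the scaling radius
    tw <- tapply(w, fit$y[nb], sum, default = 0)
    out[r, names(tw)] <- tw / sum(w)
  }
  out
}

#' Class-membership probabilities from a fitted backend
#'
#' Predict-time features are matched to the training features by name
#' (order-insensitive); missing values are imputed with the training
#' medians. Rows of the returned matrix sum to one within 1e-6.
#'
#' @param model a `lulc_classifier` from [train_backend()].
#' @param features numeric matrix with named columns.
#' @return `prob_cube` whose rows follow `features`.
#' @export
predict_proba <- function(model, features) {
  features <- as.matrix(features)
  miss <- setdiff(model$feature_names, colnames(features))
  extra <- setdiff(colnames(features), model$feature_names)
  if (length(miss) || length(extra))
    stop("feature mismatch; missing: [", paste(miss, collapse = ", "),
         "], unexpected: [", paste(extra, collapse = ", "), "]")
  x <- features[, model$feature_names, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- model$medians[j]
  }
  if (!is.null(model$scaler)) x <- scale_apply(x, model$scaler)
  lv <- model$scheme$names
  pr <- switch(model$kind,
    RF = {
      p <- stats::predict(model$fit, x, type = "prob")
      p[, lv, drop = FALSE]
    },
    SVM = {
      p <- attr(stats::predict(model$fit, x, probability = TRUE),
                "probabilities")
      p[, lv, drop = FALSE]
    },
    WKNN = wknn_proba(model$fit, x, model$hyperparams$k,
                      model$hyperparams$kernel,
                      model$hyperparams$minkowski, lv),
    ANN = {
      p <- stats::predict(model$fit, x, type = "raw")
      colnames(p) <- colnames(model$fit$fitted.values)
      p[, lv, drop = FALSE]
    },
    NB = stats::predict(model$fit, as.data.frame(x), type = "raw")[, lv,
                                                                   drop = FALSE])
  pr <- pmin(pmax(pr, 0), 1)
  pr <- pr / rowSums(pr)
  prob_cube(unname(pr), scheme = model$scheme, source = model$kind)
}

#' Hard class labels from a fitted backend
#'
#' Argmax of [predict_proba()], ties broken by the lowest class code.
#'
#' @inheritParams predict_proba
#' @return integer class codes.
#' @export
predict_label <- function(model, features) {
  pc <- predict_proba(model, features)
  model$scheme$codes[max.col(pc$probs, ties.method = "first")]
}

cv_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(factor(y))) {
    i <- which(y == cl)
    fold[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  fold
}

#' Cross-validated grid search for backend hyperparameters
#'
#' Exhaustive search over a parameter grid, scored by Cohen's kappa
#' under stratified k-fold cross-validation. Deterministic given the
#' seed; on score ties the first grid row wins.
#'
#' @param kind backend kind (see [train_backend()]).
#' @param features,labels,scheme training data as in [train_backend()].
#' @param grid data.frame of candidate settings (one column per
#'   hyperparameter) or a named list of vectors to be crossed.
#' @param folds number of cross-validation folds (>= 2, and at most the
#'   smallest class count).
#' @param seed integer seed.
#' @return list: `best` (named list of the winning settings), `scores`
#'   (the grid with a `kappa` column).
#' @export
tune_hyperparameters <- function(kind, features, labels,
                                 scheme = lulc_scheme(), grid,
                                 folds = 5L, seed = 1L) {
  if (!is.data.frame(grid)) grid <- expand.grid(grid, stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  stopifnot(folds >= 2L)
  if (folds > min(table(labels)))
    stop("folds exceed the smallest class count; stratified folding impossible")
  fold <- cv_folds(labels, folds, seed)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- as.list(grid[g, , drop = FALSE])
    kap <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- suppressWarnings(
        train_backend(kind, features[tr, , drop = FALSE], labels[tr],
                      scheme, hp, seed = seed + f))
      pred <- predict_label(m, features[!tr, , drop = FALSE])
      cm <- confusion_matrix(pred, labels[!tr], scheme)
      kap[f] <- accuracy_report(cm)$kappa
    }
    scores[g] <- mean(kap)
  }
  best <- which.max(scores)
  list(best = as.list(grid[best, , drop = FALSE]),
       scores = cbind(grid, kappa = scores))
}
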