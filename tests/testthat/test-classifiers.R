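test_that("stratified split follows the per-class rounding rule", {
  sch <- lulc_scheme(c(ENLF = 1L, GRAS = 2L))
  smp <- data.frame(row = seq_len(186 + 50), col = 1L,
                    class = c(rep(1L, 186), rep(2L, 50)),
                    class_name = c(rep("ENLF", 186), rep("GRAS", 50)),
                    split = NA_character_)
  sp <- stratified_split(smp, 0.7, seed = 11)
  tab <- table(sp$class, sp$split)
  expect_equal(unname(tab["1", "train"]), 130)   # round(0.7 * 186)
  expect_equal(unname(tab["1", "test"]), 56)
  expect_equal(unname(tab["2", "train"]), 35)

  sp2 <- stratified_split(smp, 0.7, seed = 12)
  expect_false(identical(sp$split, sp2$split))
  expect_equal(table(sp2$class, sp2$split), tab)

  # boundary: both splits stay non-empty
  tiny <- smp[c(1, 2, 187, 188), ]
  sp3 <- stratified_split(tiny, 0.999, seed = 1)
  expect_equal(as.vector(table(sp3$split)), c(2, 2))

  expect_error(stratified_split(smp[c(1, 187, 188), ], 0.7), "fewer than 2")
})

test_that("every backend separates Gaussian blobs and stays on the simplex", {
  bd <- blob_data(n_per_class = 50, m = 3, sep = 4, seed = 21)
  sp <- sample(rep(c(TRUE, FALSE), times = c(100, 50)))
  for (kind in c("RF", "SVM", "WKNN", "ANN", "NB")) {
    m <- suppressWarnings(train_backend(kind, bd$x[sp, ], bd$y[sp],
                                        bd$scheme, seed = 5))
    p <- predict_proba(m, bd$x[!sp, ])
    expect_true(all(abs(rowSums(p$probs) - 1) < 1e-6), label = kind)
    acc <- mean(bd$scheme$codes[max.col(p$probs, ties.method = "first")] ==
                  bd$y[!sp])
    expect_gt(acc, 0.95, label = paste(kind, "accuracy"))
  }
})

test_that("RF probabilities are tree-vote fractions", {
  bd <- blob_data(n_per_class = 40, m = 3, sep = 1.2, seed = 31)
  m <- train_backend("RF", bd$x, bd$y, bd$scheme,
                     list(ntree = 101L), seed = 7)
  q <- bd$x[seq(1, 120, by = 13), ]
  p <- predict_proba(m, q)
  trees <- predict(m$fit, q, predict.all = TRUE)$individual
  votes <- t(apply(trees, 1L, function(r)
    tabulate(match(r, bd$scheme$names), 3L))) / 101
  expect_equal(unname(p$probs), unname(votes), tolerance = 1e-12)
})

test_that("WKNN gives certainty when all neighbours share a class", {
  sch <- lulc_scheme(c(A = 1L, B = 2L))
  x <- rbind(matrix(rnorm(20, mean = 0, sd = 0.1), 10, 2),
             matrix(rnorm(20, mean = 50, sd = 0.1), 10, 2))
  colnames(x) <- c("u", "v")
  m <- train_backend("WKNN", x, rep(1:2, each = 10), sch,
                     list(k = 5L), seed = 1)
  p <- predict_proba(m, matrix(c(0, 0), 1, 2,
                               dimnames = list(NULL, c("u", "v"))))
  expect_equal(unname(p$probs[1, "A"]), 1)

  expect_warning(
    train_backend("WKNN", x[c(1, 11), ], c(1L, 2L), sch, list(k = 11L)),
    "truncated")
})

test_that("NB survives zero within-class variance without NaNs", {
  sch <- lulc_scheme(c(A = 1L, B = 2L))
  x <- cbind(const = rep(1, 40), good = c(rnorm(20), rnorm(20, 5)))
  expect_warning(m <- train_backend("NB", x, rep(1:2, each = 20), sch),
                 "zero-variance")
  p <- predict_proba(m, x)
  expect_false(anyNA(p$probs))
  expect_true(all(abs(rowSums(p$probs) - 1) < 1e-6))
})

test_that("refits with the same seed reproduce predictions", {
  bd <- blob_data(n_per_class = 40, m = 3, sep = 2, seed = 41)
  q <- bd$x[seq(1, 120, 7), ]
  for (kind in c("RF", "WKNN", "NB")) {
    p1 <- predict_proba(train_backend(kind, bd$x, bd$y, bd$scheme, seed = 3), q)
    p2 <- predict_proba(train_backend(kind, bd$x, bd$y, bd$scheme, seed = 3), q)
    expect_identical(p1$probs, p2$probs, label = kind)
  }
  for (kind in c("SVM", "ANN")) {
    p1 <- predict_proba(train_backend(kind, bd$x, bd$y, bd$scheme, seed = 3), q)
    p2 <- predict_proba(train_backend(kind, bd$x, bd$y, bd$scheme, seed = 3), q)
    expect_equal(p1$probs, p2$probs, tolerance = 1e-6, label = kind)
  }
})

test_that("probability argmax agrees with native hard predictions", {
  bd <- blob_data(n_per_class = 50, m = 3, sep = 1.5, seed = 51)
  q <- bd$x + matrix(rnorm(length(bd$x), sd = 0.3), nrow(bd$x))
  colnames(q) <- colnames(bd$x)
  mrf <- train_backend("RF", bd$x, bd$y, bd$scheme, seed = 9)
  expect_equal(predict_label(mrf, q),
               bd$scheme$codes[match(as.character(predict(mrf$fit, q)),
                                     bd$scheme$names)])
  msvm <- train_backend("SVM", bd$x, bd$y, bd$scheme, seed = 9)
  native <- as.character(predict(msvm$fit,
                                 lulcfuse:::scale_apply(q, msvm$scaler)))
  # Platt probabilities can disagree with the margin vote near boundaries;
  # require agreement on the overwhelming majority
  expect_gt(mean(predict_label(msvm, q) ==
                   bd$scheme$codes[match(native, bd$scheme$names)]), 0.95)
})

test_that("predict-time features are matched by name, not position", {
  bd <- blob_data(n_per_class = 30, m = 3, seed = 61)
  m <- train_backend("RF", bd$x, bd$y, bd$scheme, seed = 2)
  shuffled <- bd$x[, rev(colnames(bd$x))]
  expect_equal(predict_proba(m, shuffled)$probs,
               predict_proba(m, bd$x)$probs)
  expect_error(predict_proba(m, bd$x[, -1]), "missing: \\[f1\\]")

  # NAs at predict time are imputed with training medians, not propagated
  qna <- bd$x[1:5, ]; qna[2, 3] <- NA
  expect_false(anyNA(predict_proba(m, qna)$probs))
})

test_that("grid search is stratified, seeded, and degenerate-safe", {
  bd <- blob_data(n_per_class = 30, m = 3, sep = 2, seed = 71)
  one <- tune_hyperparameters("RF", bd$x, bd$y, bd$scheme,
                              grid = list(ntree = 51L), folds = 3, seed = 1)
  expect_equal(one$best$ntree, 51L)
  expect_error(
    tune_hyperparameters("RF", bd$x, bd$y, bd$scheme,
                         grid = list(ntree = 11L), folds = 31, seed = 1),
    "smallest class")

  # noisy data: more trees should win
  set.seed(72)
  xn <- bd$x + matrix(rnorm(length(bd$x), sd = 3), nrow(bd$x))
  colnames(xn) <- colnames(bd$x)
  tn <- tune_hyperparameters("RF", xn, bd$y, bd$scheme,
                             grid = list(ntree = c(5L, 200L)),
                             folds = 3, seed = 4)
  expect_equal(tn$best$ntree, 200L)
})
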