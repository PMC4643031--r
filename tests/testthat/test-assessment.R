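test_that("accuracy statistics match hand-computed confusion matrices", {
  sch2 <- lulc_scheme(c(A = 1L, B = 2L))
  cm <- confusion_from_counts(
    matrix(c(40, 10, 10, 40), 2, 2, byrow = TRUE,
           dimnames = list(c("A", "B"), c("A", "B"))), sch2)
  rep_ <- accuracy_report(cm)
  expect_equal(rep_$oa, 80)
  expect_equal(rep_$kappa, 60)      # p_e = 0.5 by symmetry

  nm5 <- lulc_scheme()$names[1:5]
  m5 <- diag(5) * 7
  dimnames(m5) <- list(nm5, nm5)
  ident <- confusion_from_counts(m5, lulc_scheme(stats::setNames(1:5, nm5)))
  ri <- accuracy_report(ident)
  expect_equal(ri$oa, 100)
  expect_equal(ri$kappa, 100)
})

test_that("kappa vanishes for independent margins", {
  sch <- lulc_scheme()
  set.seed(13)
  for (i in 1:5) {
    r <- rexp(9); c_ <- rexp(9)
    m <- outer(r, c_) * 50
    dimnames(m) <- list(sch$names, sch$names)
    expect_lt(abs(accuracy_report(confusion_from_counts(m, sch))$kappa),
              1e-10)
  }
})

test_that("confusion counting equals a brute-force tally, with UNCE row", {
  sch <- lulc_scheme()
  set.seed(14)
  ref <- sample(sch$codes, 500, replace = TRUE)
  pred <- ifelse(runif(500) < 0.1, sch$unclassified,
                 ifelse(runif(500) < 0.7, ref,
                        sample(sch$codes, 500, replace = TRUE)))
  cm <- confusion_matrix(pred, ref, sch)
  for (i in rownames(cm$counts)) for (j in colnames(cm$counts)) {
    pi <- if (i == "UNCE") sch$unclassified else class_code(sch, i)
    expect_equal(unname(cm$counts[i, j]),
                 sum(pred == pi & ref == class_code(sch, j)))
  }
  # column totals = per-class reference counts (UNCE included in columns)
  expect_equal(unname(colSums(cm$counts)),
               unname(as.integer(table(factor(ref, levels = sch$codes)))))

  # all-unclassified predictions: OA 0, everything in the UNCE row
  cm0 <- confusion_matrix(rep(sch$unclassified, 100),
                          sample(sch$codes, 100, replace = TRUE), sch)
  expect_equal(accuracy_report(cm0)$oa, 0)
  expect_equal(sum(cm0$counts["UNCE", ]), 100)

  expect_error(confusion_matrix(pred, c(ref[-1], 77L), sch), "outside")
})

test_that("proportion ratios compare subset to map composition", {
  sch <- lulc_scheme()
  subset <- c(rep(1L, 50), rep(2L, 50))
  full <- c(rep(1L, 25), rep(2L, 25), rep(3L, 50))
  pr <- proportion_ratio(subset, full, sch)
  expect_equal(pr$ratio[1], 2)
  expect_equal(sum(pr$subset_pct), 100)
  expect_true(is.na(pr$ratio[4]))   # class absent from the map

  same <- proportion_ratio(full, full, sch)
  expect_equal(same$ratio[1:3], rep(1, 3))

  # flagging picks out exactly the classes above the threshold
  sub2 <- c(rep(1L, 70), rep(2L, 30))
  full2 <- c(rep(1L, 20), rep(2L, 30), rep(3L, 50))
  pr2 <- proportion_ratio(sub2, full2, sch, flag_threshold = 3)
  expect_equal(pr2$flagged, pr2$ratio > 3 & !is.na(pr2$ratio))
  expect_true(pr2$flagged[1])       # 70% vs 20% -> ratio 3.5
  expect_false(any(pr2$flagged[-1], na.rm = TRUE))
})

test_that("CMP histograms tally bins and threshold fractions", {
  h1 <- cmp_histogram(rep(1, 50), bin_width = 0.1)
  expect_equal(h1$counts, c(rep(0L, 9), 50L))
  set.seed(15)
  v <- runif(1000)
  h <- cmp_histogram(v, bin_width = 0.25)
  expect_equal(h$counts, as.integer(table(cut(v, seq(0, 1, 0.25)))))
  expect_equal(mean(v <= 0.4) + h$frac_above_0.4, 1)
  expect_equal(h$frac_above_0.5, mean(v > 0.5))
  expect_error(cmp_histogram(numeric(0)), "empty")
  expect_error(cmp_histogram(v, bin_width = 0.3), "divide")
})

test_that("CMP-accuracy correlation uses per-class mean probabilities", {
  sch <- lulc_scheme()
  set.seed(16)
  n <- 9000
  # perfectly calibrated ensemble: the reference label is drawn from each
  # pixel's probability vector, with class-specific confidence levels
  focus <- rep(sch$codes, each = n / 9)
  conf <- (0.9 - 0.5 * seq(0, 0.8, length.out = 9))[focus]
  p <- matrix((1 - conf) / 8, n, 9)
  p[cbind(seq_len(n), focus)] <- conf
  ref <- vapply(seq_len(n), function(i)
    sample(sch$codes, 1L, prob = p[i, ]), integer(1))
  pc <- prob_cube(p, sch)
  res <- cmp_accuracy_correlation(pc, ref, sch)
  # brute-force per-class means
  pred <- argmax_label(pc)
  cmp <- cmp_layer(pc)
  for (cl in sch$codes) {
    expect_equal(res$per_class$cmp_reference[cl], mean(cmp[ref == cl]))
    expect_equal(res$per_class$cmp_assigned[cl], mean(cmp[pred == cl]))
  }
  expect_gt(res$r_pa, 0.8)
  expect_gt(res$r_ua, 0.8)

  # constant CMP across classes -> zero variance -> NA, not an error
  pm <- matrix(0.06, n, 9)
  pm[cbind(seq_len(n), ref)] <- 0.52   # always confident in the truth
  resu <- cmp_accuracy_correlation(prob_cube(pm, sch), ref, sch)
  expect_true(is.na(resu$r_pa) && is.na(resu$r_ua))

  expect_error(cmp_accuracy_correlation(pc, rep(1L, n), sch), "3 classes")
})

test_that("sensitivity curves have the right shape and are seed-stable", {
  bd <- blob_data(n_per_class = 40, m = 3, sep = 2.2, seed = 17)
  tr <- rep(c(TRUE, FALSE), times = c(90, 30))
  curve <- sample_size_sensitivity(
    bd$x[tr, ], bd$y[tr], bd$x[!tr, ], bd$y[!tr],
    kinds = c("RF", "WKNN"), fractions = c(0.2, 1.0), replicates = 3,
    scheme = bd$scheme, seed = 19,
    hyperparams = list(RF = list(ntree = 101L)))
  expect_equal(nrow(curve), 2 * 2 * 3)
  # fraction 1.0: no subsampling randomness -> identical replicates
  full <- subset(curve, fraction == 1 & kind == "RF")
  expect_equal(length(unique(full$oa)), 1L)
  # reproducibility
  curve2 <- sample_size_sensitivity(
    bd$x[tr, ], bd$y[tr], bd$x[!tr, ], bd$y[!tr],
    kinds = c("RF", "WKNN"), fractions = c(0.2, 1.0), replicates = 3,
    scheme = bd$scheme, seed = 19,
    hyperparams = list(RF = list(ntree = 101L)))
  expect_equal(curve, curve2)
  sm <- summarize_sensitivity(curve)
  expect_equal(nrow(sm), 4L)
  expect_true(all(c("oa_mean", "oa_sd") %in% names(sm)))
})
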