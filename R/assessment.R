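round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Confusion matrix of predicted against reference labels
#'
#' Cross-tabulates predicted class codes against reference codes.
#' Unclassified predictions occupy a dedicated `UNCE` row: they count
#' in the column totals (producer's-accuracy denominators) but have no
#' user's accuracy. Reference labels must be genuine classes.
#'
#' @param predicted integer codes or a [lulc_map()]; may contain the
#'   scheme's unclassified code.
#' @param reference integer reference codes, same length.
#' @param scheme a [lulc_scheme()].
#' @param include_unclassified keep the `UNCE` row even when empty.
#' @return object of class `confusion_matrix`: integer `counts`
#'   (predicted rows x reference columns) and the scheme.
#' @export
confusion_matrix <- function(predicted, reference, scheme = lulc_scheme(),
                             include_unclassified = NULL) {
  pred <- as_label_vector(predicted)
  ref <- as.integer(reference)
  stopifnot(length(pred) == length(ref))
  if (!all(ref %in% scheme$codes))
    stop("reference contains code(s) outside the scheme: ",
         paste(utils::head(unique(ref[!ref %in% scheme$codes]), 5L),
               collapse = ", "))
  drop <- pred == scheme$nodata | is.na(pred)
  if (any(drop)) {
    warning(sum(drop), " nodata prediction(s) excluded")
    pred <- pred[!drop]; ref <- ref[!drop]
  }
  if (!all(pred %in% c(scheme$codes, scheme$unclassified)))
    stop("predictions contain code(s) outside the scheme")
  has_unce <- any(pred == scheme$unclassified)
  if (is.null(include_unclassified)) include_unclassified <- has_unce
  rows <- c(scheme$names, if (include_unclassified || has_unce) "UNCE")
  pred_f <- factor(class_name(scheme, pred), levels = rows)
  ref_f <- factor(class_name(scheme, ref), levels = scheme$names)
  counts <- table(predicted = pred_f, reference = ref_f)
  structure(list(counts = unclass(counts), scheme = scheme),
            class = "confusion_matrix")
}

#' Build a confusion matrix from a printed count table
#'
#' @param counts integer matrix, predicted classes in rows (optionally
#'   an `UNCE` row), reference classes in columns, named by class.
#' @param scheme a [lulc_scheme()].
#' @return `confusion_matrix`.
#' @export
confusion_from_counts <- function(counts, scheme = lulc_scheme()) {
  counts <- as.matrix(counts)
  if (!all(colnames(counts) %in% scheme$names))
    stop("reference columns outside the scheme")
  if (!all(rownames(counts) %in% c(scheme$names, "UNCE")))
    stop("predicted rows outside the scheme")
  structure(list(counts = counts, scheme = scheme),
            class = "confusion_matrix")
}

#' Read a confusion-matrix CSV (first column = predicted class names)
#'
#' @param path CSV path.
#' @param scheme a [lulc_scheme()].
#' @return `confusion_matrix`.
#' @export
read_confusion_csv <- function(path, scheme = lulc_scheme()) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  confusion_from_counts(m, scheme)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Accuracy statistics from a confusion matrix
#'
#' Computes, in percent: producer's accuracy `PA_j = 100 c_jj / n_+j`
#' (reference-column totals include unclassified predictions), user's
#' accuracy `UA_i = 100 c_ii / n_i+` for classified rows, overall
#' accuracy `OA = 100 trace / N`, and Cohen's kappa
#' `100 (p_o - p_e) / (1 - p_e)` with `p_e = sum_i n_i+ n_+i / N^2`.
#' By default the unclassified row participates in `N` and in the
#' margins (its missing reference column contributes zero to `p_e`);
#' set `kappa_with_unclassified = FALSE` to drop those samples from the
#' kappa computation instead. Values are kept at full precision;
#' `print()` rounds half-up to 0.1 as is conventional in accuracy
#' tables.
#'
#' @param cm a [confusion_matrix()].
#' @param kappa_with_unclassified keep the UNCE row as a predicted
#'   category in the kappa margins (default) or drop those samples.
#' @return object of class `accuracy_report`: `pa`, `ua` (named
#'   vectors, `NA` where undefined), `avg_pa`, `avg_ua`, `oa`, `kappa`.
#' @export
accuracy_report <- function(cm, kappa_with_unclassified = TRUE) {
  m <- cm$counts
  cls <- colnames(m)
  N <- sum(m)
  if (N == 0) stop("empty confusion matrix")
  diagv <- vapply(cls, function(cc)
    if (cc %in% rownames(m)) m[cc, cc] else 0, numeric(1))
  coltot <- colSums(m)
  pa <- ifelse(coltot > 0, 100 * diagv / coltot, NA_real_)
  crow <- intersect(rownames(m), cls)
  rowtot <- rowSums(m)[crow]
  ua <- ifelse(rowtot > 0, 100 * vapply(crow, function(cc) m[cc, cc],
                                        numeric(1)) / rowtot, NA_real_)
  oa <- 100 * sum(diagv) / N
  if (kappa_with_unclassified || !"UNCE" %in% rownames(m)) {
    mk <- m
  } else {
    keep <- rownames(m) != "UNCE"
    mk <- m[keep, , drop = FALSE]
  }
  Nk <- sum(mk)
  dk <- vapply(cls, function(cc)
    if (cc %in% rownames(mk)) mk[cc, cc] else 0, numeric(1))
  po <- sum(dk) / Nk
  rowm <- vapply(cls, function(cc)
    if (cc %in% rownames(mk)) sum(mk[cc, ]) else 0, numeric(1))
  pe <- sum(rowm * colSums(mk)) / Nk^2
  kappa <- 100 * (po - pe) / (1 - pe)
  structure(list(pa = pa, ua = ua,
                 avg_pa = mean(pa, na.rm = TRUE),
                 avg_ua = mean(ua, na.rm = TRUE),
                 oa = oa, kappa = kappa),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("PA (%):\n"); print(round_half_up(x$pa))
  cat("UA (%):\n"); print(round_half_up(x$ua))
  cat(sprintf("Average PA = %.1f%%, Average UA = %.1f%%, OA = %.1f%%, Kappa = %.1f%%\n",
              round_half_up(x$avg_pa), round_half_up(x$avg_ua),
              round_half_up(x$oa), round_half_up(x$kappa)))
  invisible(x)
}

#' Sensitivity of classification accuracy to training sample size
#'
#' For each backend and each training fraction, draws a fresh
#' stratified subsample of the training set (without replacement, at
#' least one point per class), trains the backend, and evaluates OA and
#' kappa on the fixed test set; repeated `replicates` times. Subsamples
#' are drawn independently per replicate and fraction.
#'
#' @param train_x,train_y training features and integer codes.
#' @param test_x,test_y fixed evaluation set.
#' @param kinds character vector of backend kinds.
#' @param fractions training fractions in (0, 1].
#' @param replicates subsample replicates per fraction.
#' @param scheme a [lulc_scheme()].
#' @param seed integer seed controlling all draws.
#' @param hyperparams optional named list (per kind) of overrides.
#' @return `sensitivity_curve`: data.frame with columns `kind`,
#'   `fraction`, `replicate`, `oa`, `kappa`.
#' @export
sample_size_sensitivity <- function(train_x, train_y, test_x, test_y,
                                    kinds = c("RF", "SVM", "WKNN", "ANN", "NB"),
                                    fractions = seq(0.1, 1, by = 0.1),
                                    replicates = 50L,
                                    scheme = lulc_scheme(), seed = 1L,
                                    hyperparams = list()) {
  stopifnot(all(fractions > 0), all(fractions <= 1), replicates >= 1L)
  fractions <- sort(fractions)
  res <- vector("list", 0L)
  idx_by_class <- split(seq_along(train_y), train_y)
  for (r in seq_len(replicates)) {
    for (f in fractions) {
      set.seed(seed + 7907L * r + round(1e4 * f))
      sub <- unlist(lapply(idx_by_class, function(i) {
        n <- max(1L, floor(f * length(i) + 0.5))
        if (n >= length(i)) i else sample(i, n)
      }), use.names = FALSE)
      for (k in kinds) {
        m <- suppressWarnings(train_backend(
          k, train_x[sub, , drop = FALSE], train_y[sub], scheme,
          hyperparams[[k]] %||% list(), seed = seed))
        pred <- predict_label(m, test_x)
        rep_ <- accuracy_report(confusion_matrix(pred, test_y, scheme))
        res[[length(res) + 1L]] <- data.frame(
          kind = k, fraction = f, replicate = r,
          oa = rep_$oa, kappa = rep_$kappa)
      }
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("sensitivity_curve", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise a sensitivity curve (mean and sd per kind and fraction)
#'
#' @param curve a `sensitivity_curve`.
#' @return data.frame with `kind`, `fraction`, `oa_mean`, `oa_sd`,
#'   `kappa_mean`, `kappa_sd`, `n`.
#' @export
summarize_sensitivity <- function(curve) {
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  sp <- split(curve, list(curve$kind, curve$fraction), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    kind = d$kind[1], fraction = d$fraction[1],
    oa_mean = mean(d$oa), oa_sd = stats::sd(d$oa),
    kappa_mean = mean(d$kappa), kappa_sd = stats::sd(d$kappa),
    n = nrow(d))))
  rownames(out) <- NULL
  out[order(out$kind, out$fraction), ]
}

#' Class-proportion ratios in an uncertain subset
#'
#' Compares the class composition of an uncertain subset of pixels
#' (e.g. unclassified under majority vote, or low-CMP under Bayesian
#' averaging) against the composition of the full map. Ratios well
#' above 1 mark classes that are hard to recognise; classes exceeding
#' `flag_threshold` are flagged.
#'
#' @param subset_labels integer codes of the uncertain subset (as voted
#'   by some classifier, or from the full map itself).
#' @param full_labels integer codes (or [lulc_map()]) of the full map.
#' @param scheme a [lulc_scheme()].
#' @param flag_threshold ratio above which a class is flagged.
#' @return data.frame per class: `subset_pct`, `map_pct`, `ratio`,
#'   `flagged`. Proportions are over classified pixels and each sum to
#'   100; ratios are `NA` for classes absent from the full map.
#' @export
proportion_ratio <- function(subset_labels, full_labels,
                             scheme = lulc_scheme(), flag_threshold = 3) {
  sub <- as_label_vector(subset_labels)
  full <- as_label_vector(full_labels)
  sub <- sub[sub %in% scheme$codes]
  full <- full[full %in% scheme$codes]
  if (!length(sub)) stop("uncertain subset contains no classified pixels")
  pct <- function(v) 100 * tabulate(match(v, scheme$codes),
                                    length(scheme$codes)) / length(v)
  sp <- pct(sub); fp <- pct(full)
  ratio <- ifelse(fp > 0, sp / fp, NA_real_)
  data.frame(class = scheme$names, subset_pct = sp, map_pct = fp,
             ratio = ratio,
             flagged = !is.na(ratio) & ratio > flag_threshold)
}

#' Correlation between mean class-membership probability and accuracy
#'
#' For each class computes the mean fused CMP of the test pixels
#' assigned to it (user's-accuracy side) and of the test pixels
#' belonging to it (producer's-accuracy side), then the Pearson
#' correlation of those means against the UA and PA vectors.
#'
#' @param fused_probs [prob_cube()] of fused probabilities for the test
#'   samples.
#' @param reference integer reference codes for the same samples.
#' @param scheme a [lulc_scheme()].
#' @return list: `r_pa`, `r_ua` (`NA` when a mean-CMP vector has zero
#'   variance), and `per_class` data.frame with the class means and
#'   accuracies.
#' @export
cmp_accuracy_correlation <- function(fused_probs, reference,
                                     scheme = lulc_scheme()) {
  stopifnot(inherits(fused_probs, "prob_cube"))
  pred <- argmax_label(fused_probs)
  cmp <- cmp_layer(fused_probs)
  rep_ <- accuracy_report(confusion_matrix(pred, reference, scheme))
  cmp_ua <- vapply(scheme$codes, function(cc)
    mean(cmp[pred == cc]), numeric(1))
  cmp_pa <- vapply(scheme$codes, function(cc)
    mean(cmp[reference == cc]), numeric(1))
  per_class <- data.frame(class = scheme$names,
                          cmp_assigned = cmp_ua, cmp_reference = cmp_pa,
                          ua = rep_$ua[scheme$names],
                          pa = rep_$pa[scheme$names])
  ok_pa <- stats::complete.cases(per_class[, c("cmp_reference", "pa")])
  ok_ua <- stats::complete.cases(per_class[, c("cmp_assigned", "ua")])
  if (sum(ok_pa) < 3L || sum(ok_ua) < 3L)
    stop("correlation needs at least 3 classes with defined accuracy")
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  list(r_pa = safe_cor(per_class$cmp_reference[ok_pa], per_class$pa[ok_pa]),
       r_ua = safe_cor(per_class$cmp_assigned[ok_ua], per_class$ua[ok_ua]),
       per_class = per_class)
}

#' Histogram of a class-membership-probability layer
#'
#' Bins the CMP values of valid pixels into equal-width bins over
#' (0, 1] and reports the fractions above the conventional 0.4 and 0.5
#' confidence thresholds.
#'
#' @param cmp numeric CMP values (vector or matrix; `NA` ignored).
#' @param bin_width bin width; must divide 1 evenly.
#' @return list: `breaks`, `counts`, `frac_above_0.4`, `frac_above_0.5`.
#' @export
cmp_histogram <- function(cmp, bin_width = 0.05) {
  v <- as.vector(cmp)
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty CMP layer")
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("bin_width must divide 1")
  breaks <- seq(0, 1, by = bin_width)
  counts <- as.integer(table(cut(v, breaks, include.lowest = TRUE,
                                 right = TRUE)))
  list(breaks = breaks, counts = counts,
       frac_above_0.4 = mean(v > 0.4),
       frac_above_0.5 = mean(v > 0.5))
}
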