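#' Bayesian-average fusion of classifier probabilities
#'
#' Fuses K classifiers by the per-pixel arithmetic mean of their
#' class-probability vectors:
#' `P(X in C_i) = (1/K) sum_k P_k(X in C_i)`. The mean of simplex
#' vectors is simplex-valid; pixels that are nodata in any input are
#' nodata in the output.
#'
#' @param prob_cubes list of K >= 2 [prob_cube()]s on the same scheme
#'   with equal row counts.
#' @return fused `prob_cube` with `source = "fused"`.
#' @export
bayesian_average <- function(prob_cubes) {
  stopifnot(length(prob_cubes) >= 2L)
  ref <- prob_cubes[[1]]
  for (pc in prob_cubes) {
    stopifnot(inherits(pc, "prob_cube"))
    if (!identical(dim(pc$probs), dim(ref$probs)))
      stop("probability cubes differ in size")
    if (!identical(pc$scheme$codes, ref$scheme$codes))
      stop("probability cubes differ in class scheme")
  }
  acc <- Reduce(`+`, lapply(prob_cubes, function(pc) pc$probs))
  fused <- acc / length(prob_cubes)
  nodata <- Reduce(`|`, lapply(prob_cubes,
                               function(pc) apply(is.na(pc$probs), 1L, any)))
  fused[nodata, ] <- NA_real_
  prob_cube(fused, scheme = ref$scheme, source = "fused")
}

#' Hard labels from a probability cube (argmax rule)
#'
#' The final class of each pixel is the one with the highest
#' probability; exact ties are broken toward the lowest class code and
#' counted in the `ties` attribute. Nodata rows map to the scheme's
#' nodata code.
#'
#' @param probs a [prob_cube()].
#' @param dim optional `c(nrow, ncol)`; when given, a [lulc_map()] is
#'   returned (rows filled column-major), otherwise an integer vector.
#' @param geo georeferencing for the returned map.
#' @return integer codes or a `lulc_map`, with attribute `ties`.
#' @export
argmax_label <- function(probs, dim = NULL,
                         geo = list(xll = 0, yll = 0, cellsize = 1)) {
  stopifnot(inherits(probs, "prob_cube"))
  sch <- probs$scheme
  p <- probs$probs
  nodata <- apply(is.na(p), 1L, any)
  lab <- rep(sch$nodata, nrow(p))
  if (any(!nodata)) {
    pm <- p[!nodata, , drop = FALSE]
    best <- max.col(pm, ties.method = "first")   # first = lowest code
    nties <- sum(rowSums(pm == pm[cbind(seq_len(nrow(pm)), best)]) > 1L)
    lab[!nodata] <- sch$codes[best]
  } else nties <- 0L
  if (is.null(dim)) return(structure(as.integer(lab), ties = nties))
  m <- lulc_map(matrix(as.integer(lab), dim[1], dim[2]), sch, geo)
  attr(m, "ties") <- nties
  m
}

as_label_vector <- function(x) {
  if (inherits(x, "lulc_map")) as.vector(x$labels) else as.integer(x)
}

#' Majority-vote fusion of hard classifications
#'
#' Each pixel takes the class voted by a strict plurality of at least
#' two classifiers; pixels where no class reaches two votes (or where
#' the top count is tied between classes) are left unclassified. The
#' companion vote map records the winning vote count (1 where
#' unclassified, K at full consensus).
#'
#' @param label_maps list of K >= 2 [lulc_map()]s (or integer label
#'   vectors) on identical grids and schemes.
#' @param scheme scheme, taken from the first map when available.
#' @return list with `map` (fused `lulc_map` or vector) and `votes`
#'   (integer matrix or vector of winning counts).
#' @export
majority_vote <- function(label_maps, scheme = NULL) {
  stopifnot(length(label_maps) >= 2L)
  is_map <- inherits(label_maps[[1]], "lulc_map")
  if (is_map) {
    dims <- lapply(label_maps, function(m) dim(m$labels))
    if (length(unique(dims)) != 1L) stop("label maps differ in grid size")
    if (is.null(scheme)) scheme <- label_maps[[1]]$scheme
  } else if (is.null(scheme)) scheme <- lulc_scheme()
  labs <- do.call(cbind, lapply(label_maps, as_label_vector))
  K <- ncol(labs)
  out <- rep(scheme$unclassified, nrow(labs))
  votes <- rep(1L, nrow(labs))
  nodata <- apply(labs == scheme$nodata, 1L, any)
  for (r in which(!nodata)) {
    tb <- tabulate(match(labs[r, ], scheme$codes), length(scheme$codes))
    top <- max(tb)
    if (top >= 2L && sum(tb == top) == 1L) {
      out[r] <- scheme$codes[which.max(tb)]
      votes[r] <- top
    }
  }
  out[nodata] <- scheme$nodata
  votes[nodata] <- NA_integer_
  if (is_map) {
    d <- dim(label_maps[[1]]$labels)
    list(map = lulc_map(matrix(as.integer(out), d[1], d[2]), scheme,
                        label_maps[[1]]$geo),
         votes = matrix(votes, d[1], d[2]))
  } else list(map = as.integer(out), votes = votes)
}

#' Class-membership-probability (CMP) uncertainty layer
#'
#' Per-pixel maximum of the fused class probabilities: a confidence
#' measure in `[1/M, 1]` where M is the number of classes.
#'
#' @param probs a [prob_cube()].
#' @param dim optional `c(nrow, ncol)` to reshape into a matrix.
#' @return numeric vector or matrix of maxima (`NA` at nodata pixels).
#' @export
cmp_layer <- function(probs, dim = NULL) {
  stopifnot(inherits(probs, "prob_cube"))
  v <- suppressWarnings(apply(probs$probs, 1L, max))
  v[!is.finite(v)] <- NA_real_
  if (is.null(dim)) v else matrix(v, dim[1], dim[2])
}

#' Fuse classifier outputs into maps and uncertainty layers
#'
#' Convenience wrapper producing the full fusion result for K
#' classifiers evaluated on a pixel grid.
#'
#' @param prob_cubes list of per-classifier [prob_cube()]s (rows in
#'   column-major grid order).
#' @param method `"bayes"`, `"vote"`, or both.
#' @param dim grid `c(nrow, ncol)`.
#' @param geo georeferencing.
#' @return list with (per requested method) `bayes_map`, `fused_probs`,
#'   `cmp` and/or `vote_map`, `votes`.
#' @export
fuse_classifiers <- function(prob_cubes, method = c("bayes", "vote"),
                             dim, geo = list(xll = 0, yll = 0, cellsize = 1)) {
  method <- match.arg(method, several.ok = TRUE)
  out <- list()
  if ("bayes" %in% method) {
    fused <- bayesian_average(prob_cubes)
    out$fused_probs <- fused
    out$bayes_map <- argmax_label(fused, dim = dim, geo = geo)
    out$cmp <- cmp_layer(fused, dim = dim)
  }
  if ("vote" %in% method) {
    hard <- lapply(prob_cubes, function(pc) {
      lulc_map(matrix(argmax_label(pc), dim[1], dim[2]), pc$scheme, geo)
    })
    mv <- majority_vote(hard)
    out$vote_map <- mv$map
    out$votes <- mv$votes
  }
  out
}
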