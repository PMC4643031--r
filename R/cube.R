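#' Multi-temporal raster cube
#'
#' Container for a per-pixel time series of composited satellite
#' observations: a 4-D array indexed (composite, band, row, col).
#' Required bands are the blue, red, near-infrared and mid-infrared
#' reflectances, the NDVI and EVI vegetation indices, and the per-pixel
#' quality flag `qa` (0 good, 1-2 marginal, 3 cloudy). Dates are
#' day-of-year of each composite and must be strictly increasing;
#' composites supplied out of order are sorted.
#'
#' @param values numeric 4-D array `(composite, band, row, col)`.
#' @param bands character band names matching `dim(values)[2]`.
#' @param dates numeric day-of-year per composite.
#' @param geo georeferencing list (`xll`, `yll`, `cellsize`).
#' @param validate check reflectance/VI/QA domains (on by default).
#' @return object of class `ts_cube`.
#' @export
ts_cube <- function(values, bands, dates,
                    geo = list(xll = 0, yll = 0, cellsize = 1),
                    validate = TRUE) {
  stopifnot(length(dim(values)) == 4L,
            dim(values)[1] == length(dates),
            dim(values)[2] == length(bands))
  required <- c("blue", "red", "nir", "mir", "ndvi", "evi", "qa")
  missing_b <- setdiff(required, bands)
  if (length(missing_b))
    stop("cube is missing required band(s): ",
         paste(missing_b, collapse = ", "))
  if (anyDuplicated(bands)) stop("duplicate band names")
  o <- order(dates)
  dates <- dates[o]
  values <- values[o, , , , drop = FALSE]
  if (any(diff(dates) <= 0)) stop("composite dates must be strictly increasing")
  if (validate) {
    qa <- values[, match("qa", bands), , , drop = FALSE]
    bad <- !(qa %in% c(0, 1, 2, 3) | is.na(qa))
    if (any(bad))
      stop("qa band contains value(s) outside {0,1,2,3}: ",
           paste(utils::head(unique(qa[bad]), 5L), collapse = ", "))
    for (b in c("blue", "red", "nir", "mir")) {
      v <- values[, match(b, bands), , , drop = FALSE]
      if (any(v < 0 | v > 1, na.rm = TRUE))
        stop("reflectance band '", b, "' outside [0,1]")
    }
    for (b in c("ndvi", "evi")) {
      v <- values[, match(b, bands), , , drop = FALSE]
      if (any(v < -1 | v > 1, na.rm = TRUE))
        stop("vegetation index '", b, "' outside [-1,1]")
    }
  }
  structure(list(values = values, bands = bands, dates = dates, geo = geo),
            class = "ts_cube")
}

#' @export
print.ts_cube <- function(x, ...) {
  d <- dim(x$values)
  cat("<ts_cube> ", d[1], " composites x ", d[2], " bands x ",
      d[3], "x", d[4], " pixels; DOY ", min(x$dates), "-", max(x$dates),
      "\n", sep = "")
  invisible(x)
}

#' Extract one band as (composite x pixel) matrix
#'
#' @param cube a [ts_cube()].
#' @param band band name.
#' @param idx optional integer vector of pixel linear indices
#'   (column-major over the row x col grid); default all pixels.
#' @return numeric matrix, composites in rows.
#' @export
cube_band <- function(cube, band, idx = NULL) {
  j <- match(band, cube$bands)
  if (is.na(j)) stop("unknown band: ", band)
  d <- dim(cube$values)
  m <- matrix(cube$values[, j, , ], nrow = d[1])
  if (!is.null(idx)) m <- m[, idx, drop = FALSE]
  m
}

#' Per-sample or per-pixel class-probability container
#'
#' Rows are samples (or pixels in row-major raster order), columns the
#' scheme's classes. Every row must lie on the probability simplex
#' within 1e-6; rows of all-`NA` mark nodata pixels.
#'
#' @param probs numeric matrix, one column per class.
#' @param scheme a [lulc_scheme()].
#' @param source identifier of the producing classifier, or "fused".
#' @return object of class `prob_cube`.
#' @export
prob_cube <- function(probs, scheme = lulc_scheme(), source = "unknown") {
  stopifnot(is.matrix(probs), ncol(probs) == n_classes(scheme))
  colnames(probs) <- scheme$names
  valid <- !apply(is.na(probs), 1L, all)
  if (any(is.na(probs[valid, ])))
    stop("probability rows must be all-NA (nodata) or fully specified")
  if (any(probs[valid, ] < -1e-9 | probs[valid, ] > 1 + 1e-9))
    stop("probabilities outside [0,1]")
  s <- rowSums(probs[valid, , drop = FALSE])
  if (any(abs(s - 1) > 1e-6))
    stop("probability rows must sum to 1 within 1e-6 (worst deviation ",
         format(max(abs(s - 1))), ")")
  structure(list(probs = probs, scheme = scheme, source = source),
            class = "prob_cube")
}

#' @export
print.prob_cube <- function(x, ...) {
  cat("<prob_cube> ", nrow(x$probs), " pixels x ", ncol(x$probs),
      " classes, source: ", x$source, "\n", sep = "")
  invisible(x)
}
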