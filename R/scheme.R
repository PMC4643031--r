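#' Land-cover class scheme
#'
#' A `lulc_scheme` fixes the set of land-use/land-cover classes, their
#' integer codes, and the two reserved codes used in label maps:
#' `unclassified` (pixels where classifier fusion reached no decision)
#' and `nodata` (pixels outside the valid data mask).
#'
#' The default scheme is the nine-class legend used throughout the
#' package: agricultural land (AGRI), bare ground (BARE), closed
#' shrubland (CLSH), deciduous broad-leaved forest (DBLF), evergreen
#' needle-leaved forest (ENLF), grassland (GRAS), open shrubland
#' (OPSH), urban area (URBN) and water (WATR), coded 1..9 in that
#' (alphabetical) order, with `unclassified = 0` and `nodata = 255`.
#' Fixed codes give deterministic lowest-code tie-breaking in argmax
#' operations and compact 8-bit storage.
#'
#' @param classes named integer vector: codes named by class label.
#' @param unclassified integer code reserved for "no decision".
#' @param nodata integer code reserved for invalid pixels.
#' @return An object of class `lulc_scheme` with elements `codes`
#'   (integer vector), `names` (character), `unclassified`, `nodata`.
#' @examples
#' sch <- lulc_scheme()
#' sch$names
#' n_classes(sch)
#' @export
lulc_scheme <- function(classes = NULL, unclassified = 0L, nodata = 255L) {
  if (is.null(classes)) {
    nm <- c("AGRI", "BARE", "CLSH", "DBLF", "ENLF",
            "GRAS", "OPSH", "URBN", "WATR")
    classes <- stats::setNames(seq_along(nm), nm)
  }
  codes <- as.integer(classes)
  nms <- names(classes)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("every class code must be named")
  if (anyDuplicated(codes)) stop("class codes must be unique")
  if (anyDuplicated(nms)) stop("class names must be unique")
  if (any(codes < 0L)) stop("class codes must be non-negative")
  unclassified <- as.integer(unclassified)
  nodata <- as.integer(nodata)
  if (unclassified %in% codes || nodata %in% codes)
    stop("reserved codes must not collide with class codes")
  if (unclassified == nodata)
    stop("unclassified and nodata codes must differ")
  structure(
    list(codes = codes, names = nms,
         unclassified = unclassified, nodata = nodata),
    class = "lulc_scheme")
}

#' @rdname lulc_scheme
#' @param scheme a `lulc_scheme`.
#' @export
n_classes <- function(scheme) length(scheme$codes)

#' Map class names to codes
#'
#' @param scheme a `lulc_scheme`.
#' @param x character vector of class names.
#' @return integer codes.
#' @export
class_code <- function(scheme, x) {
  i <- match(x, scheme$names)
  if (anyNA(i)) {
    bad <- unique(x[is.na(i)])
    stop("unknown class name(s): ", paste(bad, collapse = ", "))
  }
  scheme$codes[i]
}

#' Map class codes to names
#'
#' Reserved codes translate to `"UNCE"` and `"NODATA"`.
#'
#' @param scheme a `lulc_scheme`.
#' @param x integer vector of codes.
#' @return character names.
#' @export
class_name <- function(scheme, x) {
  out <- character(length(x))
  i <- match(x, scheme$codes)
  out[!is.na(i)] <- scheme$names[i[!is.na(i)]]
  out[x == scheme$unclassified] <- "UNCE"
  out[x == scheme$nodata] <- "NODATA"
  if (any(!nzchar(out)))
    stop("code(s) outside scheme: ",
         paste(unique(x[!nzchar(out)]), collapse = ", "))
  out
}

#' @export
print.lulc_scheme <- function(x, ...) {
  cat("<lulc_scheme> ", length(x$codes), " classes: ",
      paste(sprintf("%s=%d", x$names, x$codes), collapse = " "),
      "; unclassified=", x$unclassified, " nodata=", x$nodata, "\n", sep = "")
  invisible(x)
}
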