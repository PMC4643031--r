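#' Land-conversion matrix between two dated maps
#'
#' Cross-tabulates class labels at two dates and converts pixel counts
#' to areas. Pixels unclassified or nodata at either date are excluded
#' from the matrix and reported in the `excluded_area_km2` attribute.
#'
#' @param map_t1,map_t2 [lulc_map()]s (or integer label vectors) on
#'   identical grids and schemes; `map_t1` is the earlier date.
#' @param pixel_area_km2 area of one pixel in km^2. `NULL` derives it
#'   from the map geotransform assuming metre units (a 250 m grid gives
#'   0.0625 km^2).
#' @param scheme scheme (taken from `map_t1` when it is a map).
#' @return object of class `conversion_matrix`: `areas` (km^2, rows =
#'   earlier date), `pixel_area_km2`, `excluded_area_km2`.
#' @export
conversion_matrix <- function(map_t1, map_t2, pixel_area_km2 = NULL,
                              scheme = NULL) {
  if (inherits(map_t1, "lulc_map")) {
    if (!identical(dim(map_t1$labels), dim(map_t2$labels)))
      stop("maps differ in grid size")
    if (is.null(scheme)) scheme <- map_t1$scheme
    if (is.null(pixel_area_km2))
      pixel_area_km2 <- (map_t1$geo$cellsize / 1000)^2
  } else if (is.null(scheme)) scheme <- lulc_scheme()
  if (is.null(pixel_area_km2) || pixel_area_km2 <= 0)
    stop("pixel_area_km2 must be positive")
  l1 <- as_label_vector(map_t1); l2 <- as_label_vector(map_t2)
  stopifnot(length(l1) == length(l2))
  ok <- l1 %in% scheme$codes & l2 %in% scheme$codes
  f1 <- factor(class_name(scheme, l1[ok]), levels = scheme$names)
  f2 <- factor(class_name(scheme, l2[ok]), levels = scheme$names)
  counts <- unclass(table(f1, f2))
  names(dimnames(counts)) <- NULL
  structure(list(areas = counts * pixel_area_km2,
                 pixel_area_km2 = pixel_area_km2,
                 excluded_area_km2 = sum(!ok) * pixel_area_km2,
                 scheme = scheme),
            class = "conversion_matrix")
}

#' Build a conversion matrix from printed area values
#'
#' @param areas numeric matrix in km^2, earlier date in rows; row and
#'   column names must be class names of the scheme. Classes absent
#'   from the table are retained as zero rows/columns so the matrix
#'   shape is stable.
#' @param scheme a [lulc_scheme()].
#' @param pixel_area_km2 nominal pixel area (bookkeeping only).
#' @return `conversion_matrix`.
#' @export
conversion_from_areas <- function(areas, scheme = lulc_scheme(),
                                  pixel_area_km2 = 0.0625) {
  areas <- as.matrix(areas)
  if (!all(rownames(areas) %in% scheme$names) ||
      !all(colnames(areas) %in% scheme$names))
    stop("area table classes outside the scheme")
  full <- matrix(0, n_classes(scheme), n_classes(scheme),
                 dimnames = list(scheme$names, scheme$names))
  full[rownames(areas), colnames(areas)] <- areas
  structure(list(areas = full, pixel_area_km2 = pixel_area_km2,
                 excluded_area_km2 = 0, scheme = scheme),
            class = "conversion_matrix")
}

#' Read a conversion-matrix CSV (first column = class at earlier date)
#'
#' @param path CSV path.
#' @param scheme a [lulc_scheme()].
#' @return `conversion_matrix`.
#' @export
read_conversion_csv <- function(path, scheme = lulc_scheme()) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  conversion_from_areas(m, scheme)
}

#' @export
print.conversion_matrix <- function(x, ...) {
  print(round(x$areas, 1))
  invisible(x)
}

#' Net conversion between classes
#'
#' Signed net flow out of `from_class` into the set `to_classes`:
#' forward conversion minus the reverse, in km^2. A positive value
#' means `from_class` lost area to `to_classes` on balance.
#'
#' @param cm a `conversion_matrix`.
#' @param from_class class name.
#' @param to_classes one or more class names (e.g. both forest classes).
#' @return signed area in km^2.
#' @export
net_conversion <- function(cm, from_class, to_classes) {
  stopifnot(inherits(cm, "conversion_matrix"))
  sch <- cm$scheme
  if (!from_class %in% sch$names || !all(to_classes %in% sch$names))
    stop("class name(s) outside the scheme")
  if (from_class %in% to_classes)
    stop("from_class must not appear in to_classes")
  sum(cm$areas[from_class, to_classes]) -
    sum(cm$areas[to_classes, from_class])
}

#' Per-class area at each date and percent change
#'
#' Row sums give the class areas at the earlier date, column sums at
#' the later date.
#'
#' @param cm a `conversion_matrix`.
#' @return data.frame: `class`, `area_t1`, `area_t2`, `pct_change`
#'   (`NA` for classes absent at the earlier date).
#' @export
class_area_change <- function(cm) {
  stopifnot(inherits(cm, "conversion_matrix"))
  a1 <- rowSums(cm$areas)
  a2 <- colSums(cm$areas)
  data.frame(class = cm$scheme$names,
             area_t1 = as.numeric(a1), area_t2 = as.numeric(a2),
             pct_change = ifelse(a1 > 0, 100 * (a2 - a1) / a1, NA_real_))
}
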