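#' Raster grid I/O (ESRI ASCII grid)
#'
#' Rasters are exchanged as ESRI ASCII grids (`.asc`): a plain-text,
#' georeferenced, single-band format readable by GDAL, GRASS and QGIS.
#' Internally a grid is a numeric matrix whose first row is the
#' northernmost row; georeferencing is carried as
#' `list(xll, yll, cellsize)` (lower-left corner, square cells).
#'
#' @param path file path.
#' @param values numeric matrix (row 1 = north).
#' @param geo list with `xll`, `yll`, `cellsize`.
#' @param nodata value written for `NA` cells.
#' @param digits significant digits written (floats round-trip within
#'   1e-6 at the default; integers round-trip exactly).
#' @return `read_asc` returns `list(values, geo, nodata)`.
#' @name asc_io
NULL

#' @rdname asc_io
#' @export
write_asc <- function(values, path, geo = list(xll = 0, yll = 0, cellsize = 1),
                      nodata = -9999, digits = 10L) {
  stopifnot(is.matrix(values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", format(geo$xll, digits = 15)),
    paste("yllcorner", format(geo$yll, digits = 15)),
    paste("cellsize", format(geo$cellsize, digits = 15)),
    paste("NODATA_value", format(nodata, digits = 15))), con)
  v <- values
  v[is.na(v)] <- nodata
  lines <- apply(v, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname asc_io
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys))
    stop("malformed ASCII grid header in ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  dat <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  if (length(dat) != nr * nc)
    stop("grid body of ", path, " has ", length(dat),
         " values, expected ", nr * nc)
  m <- matrix(dat, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  list(values = m,
       geo = list(xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
                  cellsize = vals[["cellsize"]]),
       nodata = nodata)
}

#' Land-cover label map
#'
#' A `lulc_map` pairs an integer label matrix with its class scheme and
#' georeferencing. Labels must be class codes or the scheme's reserved
#' `unclassified` / `nodata` codes.
#'
#' @param labels integer matrix of class codes.
#' @param scheme a [lulc_scheme()].
#' @param geo georeferencing list (`xll`, `yll`, `cellsize`).
#' @return object of class `lulc_map`.
#' @export
lulc_map <- function(labels, scheme = lulc_scheme(),
                     geo = list(xll = 0, yll = 0, cellsize = 1)) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  ok <- labels %in% c(scheme$codes, scheme$unclassified, scheme$nodata)
  if (!all(ok))
    stop("labels contain code(s) outside the scheme: ",
         paste(utils::head(unique(labels[!ok]), 5L), collapse = ", "))
  structure(list(labels = labels, scheme = scheme, geo = geo),
            class = "lulc_map")
}

#' @export
print.lulc_map <- function(x, ...) {
  tab <- table(factor(class_name(x$scheme, as.vector(x$labels)),
                      levels = c(x$scheme$names, "UNCE", "NODATA")))
  cat("<lulc_map> ", nrow(x$labels), "x", ncol(x$labels), " pixels\n", sep = "")
  print(tab)
  invisible(x)
}

#' Write / read a label map
#'
#' Round trips are bit-exact for label maps, including unclassified and
#' nodata codes (the scheme's `nodata` code doubles as the grid's
#' NODATA tag).
#'
#' @param map a [lulc_map()].
#' @param path `.asc` output path.
#' @param scheme scheme used to validate codes on read.
#' @return `read_map` returns a `lulc_map`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "lulc_map"))
  # re-validate: maps may have been edited in place
  ok <- map$labels %in% c(map$scheme$codes, map$scheme$unclassified,
                          map$scheme$nodata)
  if (!all(ok)) stop("refusing to write map with out-of-scheme codes")
  write_asc(map$labels, path, geo = map$geo, nodata = map$scheme$nodata,
            digits = 10L)
}

#' @rdname write_map
#' @export
read_map <- function(path, scheme = lulc_scheme()) {
  g <- read_asc(path)
  lab <- g$values
  lab[is.na(lab)] <- scheme$nodata
  lulc_map(matrix(as.integer(round(lab)), nrow(lab), ncol(lab)),
           scheme = scheme, geo = g$geo)
}

#' Read a multi-band raster time series into a cube
#'
#' Reads one `.asc` grid per (composite, band) and assembles a
#' [ts_cube()]. All grids must share dimensions and georeferencing.
#'
#' @param paths character matrix of file paths, `length(dates)` rows by
#'   `length(band_names)` columns.
#' @param band_names band names in column order; must cover the cube's
#'   required bands.
#' @param dates numeric day-of-year per composite (row order).
#' @return a [ts_cube()].
#' @export
read_raster_stack <- function(paths, band_names, dates) {
  stopifnot(is.matrix(paths), ncol(paths) == length(band_names),
            nrow(paths) == length(dates))
  ref <- NULL
  vals <- NULL
  for (i in seq_len(nrow(paths))) {
    for (j in seq_len(ncol(paths))) {
      g <- read_asc(paths[i, j])
      if (is.null(ref)) {
        ref <- list(dim = dim(g$values), geo = g$geo)
        vals <- array(NA_real_, c(nrow(paths), ncol(paths), ref$dim))
      } else if (!identical(dim(g$values), ref$dim) ||
                 !isTRUE(all.equal(g$geo, ref$geo))) {
        stop("grid mismatch: ", paths[i, j],
             " does not match the first raster's grid")
      }
      vals[i, j, , ] <- g$values
    }
  }
  ts_cube(vals, bands = band_names, dates = dates, geo = ref$geo)
}

#' Write a cube to a directory of ASCII grids plus a JSON manifest
#'
#' @param cube a [ts_cube()].
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_cube <- function(cube, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- matrix("", length(cube$dates), length(cube$bands))
  for (i in seq_along(cube$dates)) {
    for (j in seq_along(cube$bands)) {
      f <- sprintf("doy%03d_%s.asc", cube$dates[i], cube$bands[j])
      write_asc(cube$values[i, j, , ], file.path(dir, f), geo = cube$geo)
      files[i, j] <- f
    }
  }
  manifest <- list(bands = cube$bands, dates = cube$dates,
                   files = files, geo = cube$geo)
  mp <- file.path(dir, "cube.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' @rdname write_cube
#' @export
read_cube <- function(dir) {
  mp <- file.path(dir, "cube.json")
  if (!file.exists(mp)) stop("no cube.json manifest in ", dir)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  paths <- matrix(file.path(dir, man$files),
                  nrow = length(man$dates), ncol = length(man$bands))
  read_raster_stack(paths, man$bands, as.numeric(man$dates))
}

#' Read labelled reference samples from CSV
#'
#' The CSV must have columns `row`, `col` (1-based pixel coordinates)
#' or `x`, `y` (georeferenced; converted using `geo`), a `class_name`
#' column, and optionally a `split` column (`train`/`test`). Duplicated
#' coordinates are retained with a warning.
#'
#' @param path CSV path.
#' @param scheme a [lulc_scheme()].
#' @param geo georeferencing used to convert `x`/`y` to pixel indices
#'   when `row`/`col` are absent.
#' @param nrows grid rows, required for the x/y conversion.
#' @return a `sample_set`: data.frame with `row`, `col`, `class`
#'   (integer code), `class_name`, `split` (possibly `NA`).
#' @export
read_samples <- function(path, scheme = lulc_scheme(), geo = NULL,
                         nrows = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"class_name" %in% names(df))
    stop("samples CSV needs a class_name column")
  if (all(c("row", "col") %in% names(df))) {
    rr <- as.integer(df$row); cc <- as.integer(df$col)
  } else if (all(c("x", "y") %in% names(df))) {
    if (is.null(geo) || is.null(nrows))
      stop("x/y samples need geo and nrows to convert to pixel indices")
    cc <- as.integer(floor((df$x - geo$xll) / geo$cellsize)) + 1L
    rr <- nrows - as.integer(floor((df$y - geo$yll) / geo$cellsize))
  } else stop("samples CSV needs row/col or x/y columns")
  cls <- class_code(scheme, df$class_name)   # errors on unknown names
  if (anyDuplicated(cbind(rr, cc)))
    warning("duplicated sample coordinates retained")
  out <- data.frame(row = rr, col = cc, class = cls,
                    class_name = df$class_name,
                    split = if ("split" %in% names(df)) df$split else NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_set", "data.frame")
  out
}
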