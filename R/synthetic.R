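# separable Gaussian blur with edge replication; returns unit-sd field
smooth_field <- function(nr, nc, corr_len) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_len >= 1) {
    half <- max(1L, ceiling(3 * corr_len))
    k <- stats::dnorm(seq(-half, half), sd = corr_len)
    k <- k / sum(k)
    conv1 <- function(m) {   # filter columns with replicated edges
      pad <- rbind(m[rep(1L, half), , drop = FALSE], m,
                   m[rep(nrow(m), half), , drop = FALSE])
      out <- apply(pad, 2L, function(v)
        stats::filter(v, k, sides = 2L))
      out[(half + 1):(half + nrow(m)), , drop = FALSE]
    }
    z <- conv1(z)
    z <- t(conv1(t(z)))
  }
  (z - mean(z)) / stats::sd(z)
}

#' Default per-class seasonal parameters for scene simulation
#'
#' Each land-cover class is given an NDVI seasonal trajectory
#' (asymmetric Gaussian: base, amplitude, peak day-of-year and rising/
#' falling widths in days), a surface brightness (red reflectance
#' level) and an elevation affinity (metres added to the base terrain).
#' The contrasts mimic the spectral behaviour of the classes: evergreen
#' forest has a high base and small amplitude, deciduous forest a large
#' amplitude, water a negative NDVI at low brightness, urban and bare
#' ground flat low-VI trajectories at high brightness, and open
#' shrubland sits between bare ground and closed shrubland (the classic
#' confusion pair).
#'
#' @return data.frame keyed by class name.
#' @export
default_class_params <- function() {
  data.frame(
    class = c("AGRI", "BARE", "CLSH", "DBLF", "ENLF",
              "GRAS", "OPSH", "URBN", "WATR"),
    ndvi_base = c(0.25, 0.10, 0.28, 0.22, 0.55, 0.18, 0.14, 0.12, -0.10),
    ndvi_amp  = c(0.45, 0.06, 0.30, 0.52, 0.15, 0.38, 0.15, 0.04, 0.02),
    peak_doy  = c(210, 200, 190, 185, 190, 200, 195, 200, 200),
    width_l   = c(25, 40, 45, 35, 50, 30, 40, 45, 45),
    width_r   = c(30, 40, 50, 40, 55, 35, 45, 45, 45),
    brightness = c(0.08, 0.20, 0.07, 0.06, 0.05, 0.10, 0.15, 0.25, 0.03),
    elev_affinity = c(0, 200, 150, 250, 400, 100, 100, 0, -100),
    stringsAsFactors = FALSE)
}

#' Scene-simulation configuration
#'
#' @param grid_size pixels per side of the square scene.
#' @param class_params per-class parameter table
#'   (see [default_class_params()]).
#' @param noise_sd Gaussian noise sd added to the NDVI trajectory.
#' @param cloud_prob per-composite probability of cloud contamination
#'   (QA 3, NDVI biased downward by up to 50%).
#' @param marginal_prob probability of a marginal composite (QA 1-2,
#'   slightly noisier).
#' @param corr_len spatial correlation length of the label fields, in
#'   pixels.
#' @param dates day-of-year of the composites (16-day MODIS-like grid).
#' @param cellsize_m pixel size in metres.
#' @param seed default RNG seed.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(grid_size = 96L,
                         class_params = default_class_params(),
                         noise_sd = 0.02, cloud_prob = 0.15,
                         marginal_prob = 0.1,
                         corr_len = 6, dates = seq(1, 353, by = 16),
                         cellsize_m = 250, seed = 1L) {
  stopifnot(cloud_prob >= 0, cloud_prob <= 1, noise_sd >= 0,
            corr_len >= 1, all(class_params$ndvi_amp >= 0))
  structure(list(grid_size = as.integer(grid_size),
                 class_params = class_params, noise_sd = noise_sd,
                 cloud_prob = cloud_prob, marginal_prob = marginal_prob,
                 corr_len = corr_len, dates = dates,
                 cellsize_m = cellsize_m, seed = seed),
            class = "scene_config")
}

#' Simulate a multispectral scene with known truth
#'
#' Generates (deterministically for a given seed):
#' * a spatially autocorrelated label map: one smoothed Gaussian random
#'   field per class, iteratively offset so every class holds a
#'   comparable share of the scene, with the pixel label given by the
#'   field argmax (contiguous patches resembling a mosaic landscape);
#' * per-pixel NDVI trajectories from the class seasonal curves plus
#'   Gaussian noise, with composites independently cloud-contaminated
#'   (QA 3, NDVI biased downward by a uniform fraction up to 50%);
#' * band reflectances back-solved from the NDVI definition at the
#'   class brightness (blue fixed at half the red reflectance, MIR near
#'   red), so that [compute_ndvi()]/[compute_evi()] on the simulated
#'   bands approximately recover the generating index;
#' * a DEM as a smoothed random surface shifted by the class elevation
#'   affinity.
#'
#' @param config a [scene_config()].
#' @param seed RNG seed (defaults to the config's).
#' @return list: `cube` ([ts_cube()]), `dem` (matrix, metres), `truth`
#'   ([lulc_map()]).
#' @export
simulate_scene <- function(config = scene_config(), seed = config$seed) {
  set.seed(seed)
  n <- config$grid_size
  cp <- config$class_params
  M <- nrow(cp)
  dup <- duplicated(cp[, setdiff(names(cp), "class")])
  if (any(dup))
    warning("classes with identical parameters are inseparable by construction: ",
            paste(cp$class[dup], collapse = ", "))
  scheme <- lulc_scheme(stats::setNames(seq_len(M), cp$class))

  # label map: argmax over per-class fields, offsets tuned to near-equal shares
  fields <- vapply(seq_len(M), function(i) smooth_field(n, n, config$corr_len),
                   matrix(0, n, n))
  fmat <- matrix(fields, n * n, M)
  offset <- rep(0, M)
  target <- 1 / M
  for (it in 1:40) {
    lab <- max.col(sweep(fmat, 2L, offset, "+"), ties.method = "first")
    share <- tabulate(lab, M) / (n * n)
    offset <- offset - 0.3 * log(pmax(share, 1e-4) / target)
  }
  lab <- max.col(sweep(fmat, 2L, offset, "+"), ties.method = "first")
  truth <- lulc_map(matrix(scheme$codes[lab], n, n), scheme,
                    geo = list(xll = 0, yll = 0, cellsize = config$cellsize_m))

  # DEM: smooth regional surface + class affinity + local roughness
  dem <- 800 + 300 * smooth_field(n, n, 3 * config$corr_len) +
    matrix(cp$elev_affinity[lab], n, n) +
    30 * smooth_field(n, n, max(1, config$corr_len / 3))

  # NDVI trajectories
  nt <- length(config$dates)
  npix <- n * n
  tmat <- matrix(config$dates, npix, nt, byrow = TRUE)
  v <- matrix(NA_real_, npix, nt)
  for (i in seq_len(M)) {
    px <- lab == i
    if (!any(px)) next
    v[px, ] <- asym_gauss(tmat[px, , drop = FALSE], cp$ndvi_base[i],
                          cp$ndvi_amp[i], cp$peak_doy[i],
                          cp$width_l[i], cp$width_r[i])
  }
  v <- v + matrix(stats::rnorm(npix * nt, sd = config$noise_sd), npix, nt)
  qa <- matrix(0, npix, nt)
  marg <- matrix(stats::runif(npix * nt) < config$marginal_prob, npix, nt)
  qa[marg] <- sample(1:2, sum(marg), replace = TRUE)
  v[marg] <- v[marg] + stats::rnorm(sum(marg), sd = 0.01)
  cloud <- matrix(stats::runif(npix * nt) < config$cloud_prob, npix, nt)
  qa[cloud] <- 3
  v[cloud] <- v[cloud] * (1 - stats::runif(sum(cloud), 0, 0.5))
  v <- pmin(pmax(v, -0.95), 0.93)

  # back-solve reflectances at the class brightness
  red <- matrix(cp$brightness[lab], npix, nt) +
    matrix(stats::rnorm(npix * nt, sd = 0.005), npix, nt)
  red <- pmin(pmax(red, 0.01), 0.6)
  nir <- red * (1 + v) / (1 - v)
  nir <- pmin(pmax(nir, 0), 1)
  blue <- 0.5 * red
  mir <- pmin(pmax(red + matrix(stats::rnorm(npix * nt, sd = 0.01),
                                npix, nt), 0), 1)
  ndvi <- compute_ndvi(red, nir)
  evi <- compute_evi(blue, red, nir)

  bands <- c("blue", "red", "nir", "mir", "ndvi", "evi", "qa")
  vals <- array(NA_real_, c(nt, length(bands), n, n))
  put <- function(j, m) for (t in seq_len(nt)) vals[t, j, , ] <<- matrix(m[, t], n, n)
  put(1, blue); put(2, red); put(3, nir); put(4, mir)
  put(5, ndvi); put(6, evi); put(7, qa)
  cube <- ts_cube(vals, bands, config$dates,
                  geo = list(xll = 0, yll = 0, cellsize = config$cellsize_m))
  list(cube = cube, dem = dem, truth = truth, scheme = scheme)
}

#' Stratified reference points from a truth map
#'
#' Samples `n_per_class` pixels per class whose square neighbourhood of
#' side `homogeneity_window` is entirely single-class, emulating the
#' removal of reference points in spatially heterogeneous areas.
#' `homogeneity_window = 1` disables the filter.
#'
#' @param truth a [lulc_map()].
#' @param n_per_class points per class.
#' @param homogeneity_window odd window side in pixels.
#' @param seed RNG seed.
#' @return a `sample_set` data.frame (`row`, `col`, `class`,
#'   `class_name`, `split = NA`).
#' @export
sample_reference_points <- function(truth, n_per_class = 100L,
                                    homogeneity_window = 3L, seed = 1L) {
  stopifnot(inherits(truth, "lulc_map"), homogeneity_window %% 2 == 1)
  set.seed(seed)
  lab <- truth$labels
  nr <- nrow(lab); nc <- ncol(lab)
  h <- (homogeneity_window - 1L) / 2L
  homog <- matrix(TRUE, nr, nc)
  if (h > 0L) {
    homog[] <- FALSE
    inner_r <- (1L + h):(nr - h); inner_c <- (1L + h):(nc - h)
    ok <- matrix(TRUE, length(inner_r), length(inner_c))
    for (dr in -h:h) for (dc in -h:h) {
      ok <- ok & (lab[inner_r + dr, inner_c + dc] ==
                    lab[inner_r, inner_c])
    }
    homog[inner_r, inner_c] <- ok
  }
  sch <- truth$scheme
  rows <- list()
  for (i in seq_along(sch$codes)) {
    cand <- which(homog & lab == sch$codes[i])
    if (length(cand) < n_per_class)
      stop("class ", sch$names[i], " has only ", length(cand),
           " homogeneous pixels; ", n_per_class, " requested")
    pick <- sample(cand, n_per_class)
    rows[[i]] <- data.frame(
      row = ((pick - 1L) %% nr) + 1L,
      col = ((pick - 1L) %/% nr) + 1L,
      class = sch$codes[i], class_name = sch$names[i],
      split = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sample_set", "data.frame")
  out
}

#' Write a sample set to CSV
#'
#' @param samples a `sample_set`.
#' @param path output path.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples)[, c("row", "col", "class_name",
                                              "split")],
                   path, row.names = FALSE)
  invisible(path)
}
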