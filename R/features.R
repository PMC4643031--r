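#' Normalized Difference Vegetation Index
#'
#' `ndvi = (nir - red) / (nir + red)`, clipped to `[-1, 1]`. Pixels
#' with a zero denominator are returned as `NA` (nodata).
#'
#' @param red,nir reflectances in `[0, 1]` (vectors or matrices).
#' @return NDVI with the same shape as the inputs.
#' @examples
#' compute_ndvi(red = 0.1, nir = 0.5)  # 0.667
#' @export
compute_ndvi <- function(red, nir) {
  den <- nir + red
  out <- ifelse(den == 0, NA_real_, (nir - red) / den)
  pmin(pmax(out, -1), 1)
}

#' Enhanced Vegetation Index
#'
#' `evi = G (nir - red) / (nir + C1 red - C2 blue + L)` with the
#' standard MODIS coefficients G = 2.5, C1 = 6, C2 = 7.5, L = 1, clipped
#' to `[-1, 1]`. A denominator at or below `1e-6` yields `NA`.
#'
#' @param blue,red,nir reflectances in `[0, 1]`.
#' @return EVI with the same shape as the inputs.
#' @export
compute_evi <- function(blue, red, nir) {
  den <- nir + 6 * red - 7.5 * blue + 1
  out <- ifelse(den <= 1e-6, NA_real_, 2.5 * (nir - red) / den)
  pmin(pmax(out, -1), 1)
}

#' Quality-flag weights for envelope fitting
#'
#' Composite quality flags are converted to fitting weights: full
#' weight for QA 0 (good), half weight for QA 1-2 (marginal), and a
#' minimal weight of 0.1 for QA 3 (cloud-contaminated).
#'
#' @param qa integer vector/matrix with values in `{0, 1, 2, 3}`.
#' @return numeric weights, same shape.
#' @export
qa_to_weight <- function(qa) {
  bad <- !(qa %in% c(0, 1, 2, 3) | is.na(qa))
  if (any(bad))
    stop("qa value(s) outside {0,1,2,3}: ",
         paste(utils::head(unique(qa[bad]), 5L), collapse = ", "))
  w <- c(`0` = 1, `1` = 0.5, `2` = 0.5, `3` = 0.1)[as.character(qa)]
  out <- as.numeric(w)
  attributes(out) <- attributes(qa)[c("dim")]
  out
}

#' Asymmetric Gaussian seasonal model
#'
#' The single-season vegetation-index model used for envelope fitting
#' and scene simulation: a Gaussian bump with independent widths on the
#' rising (`sl`) and falling (`sr`) limbs,
#' `base + amp * exp(-((t - mu) / s)^2 / 2)` with `s = sl` for
#' `t <= mu` and `s = sr` otherwise.
#'
#' @param t day-of-year (vector or matrix).
#' @param base background VI level.
#' @param amp seasonal amplitude (peak minus base).
#' @param mu day-of-year of the peak.
#' @param sl,sr widths (days) of the rising and falling limbs.
#' @return VI values, same shape as `t`.
#' @export
asym_gauss <- function(t, base, amp, mu, sl, sr) {
  s <- ifelse(t <= mu, sl, sr)
  base + amp * exp(-0.5 * ((t - mu) / s)^2)
}

fit_ag_once <- function(t, y, w) {
  ymin <- min(y); ymax <- max(y)
  start <- list(base = ymin, amp = max(ymax - ymin, 1e-3),
                mu = t[which.max(y)],
                sl = diff(range(t)) / 6, sr = diff(range(t)) / 6)
  lower <- c(base = -1, amp = 0, mu = min(t), sl = 3, sr = 3)
  upper <- c(base = 1, amp = 2, mu = max(t), sl = 400, sr = 400)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ asym_gauss(t, base, amp, mu, sl, sr),
                      start = start, weights = w,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) return(as.list(stats::coef(fit)))
  # fall back to direct weighted least squares when LM fails to start
  obj <- function(p) {
    p <- pmin(pmax(p, lower), upper)
    sum(w * (y - asym_gauss(t, p[1], p[2], p[3], p[4], p[5]))^2)
  }
  op <- stats::optim(unlist(start), obj, method = "Nelder-Mead",
                     control = list(maxit = 2000))
  p <- pmin(pmax(op$par, lower), upper)
  as.list(stats::setNames(p, names(lower)))
}

#' Fit an upper-envelope seasonal curve to a vegetation-index series
#'
#' Fits an asymmetric Gaussian (independent widths on the rising and
#' falling limbs) to one season of a VI time series by weighted least
#' squares, then performs upper-envelope iterations: points falling
#' below the fitted curve have their weights halved and the curve is
#' refit, pulling it onto the upper envelope of the high-quality
#' observations (cloud-depressed values are discounted both by their QA
#' weight and by the envelope passes).
#'
#' @param vi numeric VI series (one value per composite; `NA` allowed).
#' @param dates day-of-year per composite.
#' @param weights observation weights, typically [qa_to_weight()].
#' @param envelope_iterations number of below-curve reweighting passes.
#' @return object of class `vi_envelope`: `fitted` (series at the input
#'   dates, `NA` where the pixel could not be fit), `params` (base,
#'   amp, mu, sl, sr), and `predict(t)`.
#' @export
fit_upper_envelope <- function(vi, dates, weights = rep(1, length(vi)),
                               envelope_iterations = 2L) {
  stopifnot(length(vi) == length(dates), length(weights) == length(vi))
  ok <- !is.na(vi) & !is.na(weights)
  if (sum(ok) < 5L) {   # fewer valid points than model parameters
    return(structure(list(fitted = rep(NA_real_, length(vi)), params = NULL,
                          predict = function(t) rep(NA_real_, length(t))),
                     class = "vi_envelope"))
  }
  if (sum(ok) < 12L)
    warning("fewer than 12 valid composites; envelope fit may be unstable")
  t <- dates[ok]; y <- vi[ok]; w <- weights[ok]
  if (all(w <= min(qa_to_weight(3L)))) {
    warning("all observations at minimal weight; fit proceeds on clouded data")
  }
  if (diff(range(y)) < 1e-9) {       # constant series: exact flat fit
    p <- list(base = y[1], amp = 0, mu = mean(t),
              sl = diff(range(t)) / 6, sr = diff(range(t)) / 6)
  } else {
    p <- fit_ag_once(t, y, w)
    for (i in seq_len(envelope_iterations)) {
      resid <- y - asym_gauss(t, p$base, p$amp, p$mu, p$sl, p$sr)
      w2 <- w
      w2[resid < 0] <- w2[resid < 0] * 0.5
      p <- fit_ag_once(t, y, w2)
    }
  }
  pred <- function(tt) asym_gauss(tt, p$base, p$amp, p$mu, p$sl, p$sr)
  structure(list(fitted = pred(dates), params = p, predict = pred),
            class = "vi_envelope")
}

#' Phenology metrics from a smoothed seasonal curve
#'
#' Extracts the standard seasonality parameters of a single growing season
#' from a smoothed VI curve: the season starts/ends where the curve
#' first/last crosses `base + season_fraction * amplitude` (linear
#' interpolation on a daily grid), the mid-season date is the curve
#' maximum, the rates of increase/decrease are the slopes between the
#' start/end crossings and the half-amplitude crossings (scaled to VI
#' units per 16-day composite), and the seasonal integrals are the
#' trapezoidal area under the curve (large) and above the base (small)
#' between start and end.
#'
#' @param smoothed a `vi_envelope` from [fit_upper_envelope()], or a
#'   numeric smoothed series sampled at `dates`.
#' @param dates day-of-year of the composites.
#' @param season_fraction fraction of amplitude defining season
#'   start/end (default 0.2).
#' @param min_amplitude amplitude floor below which the pixel is
#'   flagged as having no season and all metrics are `NA`.
#' @return named numeric vector with elements `start_doy`, `mid_doy`,
#'   `end_doy`, `season_length`, `base`, `peak`, `amplitude`,
#'   `rate_increase`, `rate_decrease`, `integral_large`,
#'   `integral_small`, plus attribute `no_season` (logical).
#' @export
extract_phenology <- function(smoothed, dates, season_fraction = 0.2,
                              min_amplitude = 0.05) {
  nm <- c("start_doy", "mid_doy", "end_doy", "season_length", "base",
          "peak", "amplitude", "rate_increase", "rate_decrease",
          "integral_large", "integral_small")
  empty <- structure(stats::setNames(rep(NA_real_, length(nm)), nm),
                     no_season = TRUE)
  tt <- seq(min(dates), max(dates), by = 1)
  if (inherits(smoothed, "vi_envelope")) {
    if (is.null(smoothed$params)) return(empty)
    y <- smoothed$predict(tt)
  } else {
    if (anyNA(smoothed)) return(empty)
    y <- stats::approx(dates, smoothed, xout = tt)$y
  }
  base <- min(y); peak <- max(y); amp <- peak - base
  if (!is.finite(amp) || amp < min_amplitude) return(empty)
  imax <- which.max(y)
  mid <- tt[imax]

  cross_up <- function(level) {   # first upward crossing before the peak
    seg <- y[seq_len(imax)]
    i <- which(seg[-1] >= level & seg[-length(seg)] < level)
    if (!length(i)) return(tt[1])
    i <- i[1]
    tt[i] + (level - seg[i]) / (seg[i + 1] - seg[i])
  }
  cross_down <- function(level) { # last downward crossing after the peak
    seg <- y[imax:length(y)]
    i <- which(seg[-length(seg)] >= level & seg[-1] < level)
    if (!length(i)) return(tt[length(tt)])
    i <- i[length(i)]
    tt[imax - 1 + i] + (seg[i] - level) / (seg[i] - seg[i + 1])
  }
  lev_edge <- base + season_fraction * amp
  lev_half <- base + 0.5 * amp
  t_start <- cross_up(lev_edge)
  t_end <- cross_down(lev_edge)
  t_half_l <- cross_up(lev_half)
  t_half_r <- cross_down(lev_half)
  # slopes between season edge and half-amplitude, per 16-day composite
  rate_inc <- if (t_half_l > t_start)
    (lev_half - lev_edge) / (t_half_l - t_start) * 16 else NA_real_
  rate_dec <- if (t_end > t_half_r)
    (lev_half - lev_edge) / (t_end - t_half_r) * 16 else NA_real_

  inside <- tt >= t_start & tt <= t_end
  trapz <- function(x, v) sum(diff(x) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  int_large <- trapz(tt[inside], y[inside])
  int_small <- trapz(tt[inside], y[inside] - base)
  structure(stats::setNames(
    c(t_start, mid, t_end, t_end - t_start, base, peak, amp,
      rate_inc, rate_dec, int_large, int_small), nm),
    no_season = FALSE)
}

#' Growing-season statistics per pixel and band
#'
#' Computes mean, standard deviation, minimum, maximum and range of
#' each reflectance band and vegetation index over the composites whose
#' day-of-year falls inside the growing-season window.
#'
#' @param cube a [ts_cube()].
#' @param window numeric `c(first_doy, last_doy)` of the growing
#'   season; the default DOY 97-297 spans April-October.
#' @param bands bands to summarise.
#' @param idx optional pixel linear indices (column-major); default all.
#' @return numeric matrix, one row per pixel, columns named
#'   `<band>_<stat>`; rows with no valid composite in the window are
#'   all-`NA`.
#' @export
seasonal_statistics <- function(cube, window = c(97, 297),
                                bands = c("blue", "red", "nir", "mir",
                                          "ndvi", "evi"),
                                idx = NULL) {
  sel <- cube$dates >= window[1] & cube$dates <= window[2]
  stats_nm <- c("mean", "sd", "min", "max", "range")
  npix <- if (is.null(idx)) prod(dim(cube$values)[3:4]) else length(idx)
  out <- matrix(NA_real_, npix,
                length(bands) * length(stats_nm),
                dimnames = list(NULL, paste(rep(bands, each = 5),
                                            stats_nm, sep = "_")))
  if (!any(sel)) return(out)
  for (b in bands) {
    m <- cube_band(cube, b, idx)[sel, , drop = FALSE]
    n_ok <- colSums(!is.na(m))
    mu <- colMeans(m, na.rm = TRUE)
    sdv <- apply(m, 2L, stats::sd, na.rm = TRUE)
    sdv[n_ok == 1L] <- 0
    mn <- suppressWarnings(apply(m, 2L, min, na.rm = TRUE))
    mx <- suppressWarnings(apply(m, 2L, max, na.rm = TRUE))
    none <- n_ok == 0L
    mu[none] <- sdv[none] <- mn[none] <- mx[none] <- NA_real_
    out[, paste0(b, "_", stats_nm)] <- cbind(mu, sdv, mn, mx, mx - mn)
  }
  out
}

#' Slope and aspect from a digital elevation model
#'
#' Horn's 3x3 finite-difference method with edge replication at the
#' borders. Slope is returned in degrees; aspect in degrees clockwise
#' from north (the downslope direction), with flat cells assigned the
#' sentinel `-1`.
#'
#' @param dem numeric elevation matrix in metres (row 1 = north).
#' @param cellsize cell size in metres.
#' @return list with matrices `elevation`, `slope`, `aspect`.
#' @export
terrain_derivatives <- function(dem, cellsize = 250) {
  if (all(is.na(dem))) stop("DEM is entirely nodata")
  nr <- nrow(dem); nc <- ncol(dem)
  pad <- dem[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]  # edge replication
  sh <- function(dr, dc) pad[seq_len(nr) + 1 + dr, seq_len(nc) + 1 + dc]
  a <- sh(-1, -1); b <- sh(-1, 0); cc <- sh(-1, 1)
  d <- sh(0, -1);                  f <- sh(0, 1)
  g <- sh(1, -1);  h <- sh(1, 0);  i <- sh(1, 1)
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cellsize)
  dzdn <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cellsize)  # northward
  slope <- atan(sqrt(dzdx^2 + dzdn^2)) * 180 / pi
  aspect <- (atan2(-dzdx, -dzdn) * 180 / pi) %% 360
  aspect[sqrt(dzdx^2 + dzdn^2) < 1e-9] <- -1
  list(elevation = dem, slope = slope, aspect = aspect)
}

pheno_feature_names <- c("pheno_start", "pheno_mid", "pheno_end",
                         "pheno_length", "pheno_base", "pheno_peak",
                         "pheno_amplitude", "pheno_rate_inc",
                         "pheno_rate_dec", "pheno_int_large",
                         "pheno_int_small")

#' Assemble classifier feature tables (combinations C1, C2, C3)
#'
#' Builds the per-pixel predictor sets used by the classifier harness:
#' * **C1** - growing-season statistics (mean, sd, min, max, range) of
#'   the four reflectance bands and two vegetation indices, plus
#'   elevation, slope and aspect: 33 features.
#' * **C2** - eleven phenology metrics from the EVI upper-envelope fit,
#'   plus the three terrain features: 14 features.
#' * **C3** - the union of C1 and C2 (terrain not duplicated): 44.
#'
#' Pixels whose envelope fit reports no season have their phenology
#' metrics imputed (amplitude, rates and integrals 0; dates at the
#' window midpoint; base and peak at the pixel's median VI) so the
#' table stays rectangular; the affected rows are marked in the
#' `no_season` attribute. Any remaining missing values are imputed with
#' the column median and the table is guaranteed NA-free.
#'
#' @param cube a [ts_cube()].
#' @param dem elevation matrix matching the cube grid.
#' @param combo one of `"C1"`, `"C2"`, `"C3"`.
#' @param idx optional pixel linear indices (column-major over the
#'   grid); default every pixel.
#' @param window growing-season DOY window for the C1 statistics.
#' @param cellsize_m DEM cell size in metres for slope computation.
#' @param season_fraction,min_amplitude passed to [extract_phenology()].
#' @return numeric feature matrix with stable column names and
#'   attributes `combo` and `no_season`.
#' @export
assemble_features <- function(cube, dem, combo = c("C1", "C2", "C3"),
                              idx = NULL, window = c(97, 297),
                              cellsize_m = 250, season_fraction = 0.2,
                              min_amplitude = 0.05) {
  combo <- match.arg(combo)
  d <- dim(cube$values)
  if (!identical(dim(dem), d[3:4]))
    stop("DEM grid does not match the cube grid")
  if (is.null(idx)) idx <- seq_len(d[3] * d[4])
  terr <- terrain_derivatives(dem, cellsize = cellsize_m)
  tmat <- cbind(elevation = terr$elevation[idx],
                slope = terr$slope[idx],
                aspect = terr$aspect[idx])
  no_season <- rep(FALSE, length(idx))

  parts <- list()
  if (combo %in% c("C1", "C3"))
    parts$stats <- seasonal_statistics(cube, window = window, idx = idx)
  if (combo %in% c("C2", "C3")) {
    evi <- cube_band(cube, "evi", idx)
    qa <- cube_band(cube, "qa", idx)
    ph <- matrix(NA_real_, length(idx), length(pheno_feature_names),
                 dimnames = list(NULL, pheno_feature_names))
    mid_doy <- mean(window)
    for (p in seq_along(idx)) {
      env <- suppressWarnings(
        fit_upper_envelope(evi[, p], cube$dates, qa_to_weight(qa[, p])))
      m <- extract_phenology(env, cube$dates,
                             season_fraction = season_fraction,
                             min_amplitude = min_amplitude)
      if (isTRUE(attr(m, "no_season"))) {
        no_season[p] <- TRUE
        med <- stats::median(evi[, p], na.rm = TRUE)
        if (!is.finite(med)) med <- 0
        m[] <- c(mid_doy, mid_doy, mid_doy, 0, med, med, 0, 0, 0, 0, 0)
      }
      ph[p, ] <- m
    }
    parts$pheno <- ph
  }
  parts$terrain <- tmat
  out <- do.call(cbind, parts)
  colnames(out) <- unlist(lapply(parts, colnames), use.names = FALSE)
  # median imputation keeps the matrix rectangular at raster edges
  for (j in seq_len(ncol(out))) {
    nas <- is.na(out[, j])
    if (any(nas)) {
      med <- stats::median(out[, j], na.rm = TRUE)
      out[nas, j] <- if (is.finite(med)) med else 0
    }
  }
  structure(out, combo = combo, no_season = no_season)
}
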