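test_that("vegetation indices match closed-form values and handle degeneracy", {
  expect_equal(compute_ndvi(red = 0.3, nir = 0.3), 0)
  expect_equal(compute_ndvi(red = 0.1, nir = 0.5), 0.4 / 0.6, tolerance = 1e-12)
  expect_true(is.na(compute_ndvi(red = 0, nir = 0)))

  expect_equal(compute_evi(blue = 0.1, red = 0.2, nir = 0.2), 0)
  expect_equal(compute_evi(blue = 0.05, red = 0.1, nir = 0.4),
               2.5 * 0.3 / (0.4 + 0.6 - 0.375 + 1), tolerance = 1e-12)
  # denominator forced to ~0: nir + 6 red - 7.5 blue + 1 = 0
  expect_true(is.na(compute_evi(blue = 0.28, red = 0.01, nir = 0.04)))
})

test_that("QA flags map to envelope weights", {
  expect_equal(qa_to_weight(c(0, 1, 2, 3)), c(1, 0.5, 0.5, 0.1))
  expect_error(qa_to_weight(7), "7")
})

test_that("upper-envelope fit recovers a noiseless seasonal curve", {
  dates <- seq(1, 353, by = 16)
  clean <- asym_gauss(dates, base = 0.2, amp = 0.4, mu = 190, sl = 30, sr = 45)
  env <- fit_upper_envelope(clean, dates)
  expect_lt(sqrt(mean((env$fitted - clean)^2)), 1e-3)

  # one cloud-contaminated composite is discounted by its weight
  dirty <- clean
  dirty[12] <- 0
  qa <- rep(0, 23); qa[12] <- 3
  env2 <- fit_upper_envelope(dirty, dates, qa_to_weight(qa))
  expect_lt(abs(env2$fitted[12] - clean[12]), 0.05)

  expect_equal(fit_upper_envelope(rep(0.3, 23), dates)$fitted, rep(0.3, 23))
  # too few valid points -> nodata pixel
  few <- rep(NA_real_, 23); few[1:4] <- 0.2
  expect_true(all(is.na(
    suppressWarnings(fit_upper_envelope(few, dates))$fitted)))
})

test_that("phenology metrics locate a symmetric season and its integrals", {
  dates <- seq(1, 353, by = 16)
  env <- fit_upper_envelope(
    asym_gauss(dates, base = 0.15, amp = 0.5, mu = 200, sl = 35, sr = 35),
    dates)
  m <- extract_phenology(env, dates)
  expect_false(attr(m, "no_season"))
  expect_lt(abs(m[["mid_doy"]] - 200), 2)
  # symmetric curve: start and end equidistant from the peak
  expect_lt(abs((200 - m[["start_doy"]]) - (m[["end_doy"]] - 200)), 16)
  expect_equal(m[["season_length"]], m[["end_doy"]] - m[["start_doy"]])
  expect_equal(m[["amplitude"]], m[["peak"]] - m[["base"]], tolerance = 1e-9)
  expect_lte(m[["integral_small"]], m[["integral_large"]])

  flat <- extract_phenology(rep(0.3, 23), dates)
  expect_true(attr(flat, "no_season"))

  # triangular season: area above base has a closed form
  tri <- rep(0.1, 353)
  doy <- 1:353
  up <- doy >= 150 & doy <= 200
  dn <- doy > 200 & doy <= 250
  tri[up] <- 0.1 + 0.5 * (doy[up] - 150) / 50
  tri[dn] <- 0.1 + 0.5 * (250 - doy[dn]) / 50
  mt <- extract_phenology(tri[seq(1, 353, 1)], doy, season_fraction = 0.02)
  true_area <- 0.5 * 100 * 0.5            # triangle above base
  expect_lt(abs(mt[["integral_small"]] - true_area) / true_area, 0.02)
})

test_that("seasonal statistics equal a brute-force masked recomputation", {
  sc <- small_scene()
  idx <- c(1L, 5L, 777L, 2000L)
  st <- seasonal_statistics(sc$cube, window = c(97, 297), idx = idx)
  sel <- sc$cube$dates >= 97 & sc$cube$dates <= 297
  for (b in c("red", "ndvi")) {
    m <- cube_band(sc$cube, b, idx)[sel, , drop = FALSE]
    for (p in seq_along(idx)) {
      v <- m[, p]; v <- v[!is.na(v)]
      expect_equal(unname(st[p, paste0(b, "_mean")]), mean(v))
      expect_equal(unname(st[p, paste0(b, "_sd")]), sd(v))
      expect_equal(unname(st[p, paste0(b, "_range")]), max(v) - min(v))
    }
  }
  expect_equal(st[, "red_range"], st[, "red_max"] - st[, "red_min"])

  # constant band and empty window
  v <- array(0.4, c(3, 7, 2, 2)); v[, 7, , ] <- 0
  cb <- ts_cube(v, c("blue", "red", "nir", "mir", "ndvi", "evi", "qa"),
                c(101, 117, 133))
  s2 <- seasonal_statistics(cb, c(97, 297))
  expect_equal(unname(s2[, "red_sd"]), rep(0, 4))
  expect_equal(unname(s2[, "red_mean"]), rep(0.4, 4))
  expect_true(all(is.na(seasonal_statistics(cb, c(1, 50)))))
})

test_that("Horn slope/aspect match analytic planes", {
  flat <- matrix(500, 8, 8)
  tf <- terrain_derivatives(flat, cellsize = 250)
  expect_equal(tf$slope, matrix(0, 8, 8))
  expect_equal(tf$aspect, matrix(-1, 8, 8))

  # plane dipping due south at 45 degrees (z drops by one cell per row)
  south <- matrix(rep(seq(8000, by = -250, length.out = 8), each = 8),
                  8, 8, byrow = TRUE)
  ts_ <- terrain_derivatives(south, cellsize = 250)
  inner <- 2:7
  expect_equal(ts_$slope[inner, inner], matrix(45, 6, 6), tolerance = 1e-9)
  expect_equal(ts_$aspect[inner, inner], matrix(180, 6, 6), tolerance = 1e-9)

  east <- matrix(seq(8000, by = -100, length.out = 8), 8, 8, byrow = TRUE)
  te <- terrain_derivatives(east, cellsize = 250)
  expect_equal(te$aspect[inner, inner], matrix(90, 6, 6), tolerance = 1e-9)

  expect_error(terrain_derivatives(matrix(NA_real_, 3, 3)), "nodata")
})

test_that("feature assembly yields the documented C1/C2/C3 sets", {
  sc <- small_scene()
  idx <- seq(1, 48 * 48, by = 97)   # two dozen pixels
  c1 <- assemble_features(sc$cube, sc$dem, "C1", idx = idx)
  expect_equal(ncol(c1), 33L)
  expect_false(anyNA(c1))
  c2 <- assemble_features(sc$cube, sc$dem, "C2", idx = idx)
  expect_equal(ncol(c2), 14L)
  expect_false(anyNA(c2))
  c3 <- assemble_features(sc$cube, sc$dem, "C3", idx = idx)
  expect_equal(ncol(c3), 44L)
  expect_setequal(colnames(c3), union(colnames(c1), colnames(c2)))
  expect_false(anyDuplicated(colnames(c3)) > 0)
  expect_error(assemble_features(sc$cube, sc$dem, "C9"), "arg")

  # composite order must not matter: scramble and compare
  perm <- sample(seq_along(sc$cube$dates))
  cube2 <- ts_cube(sc$cube$values[perm, , , ], sc$cube$bands,
                   sc$cube$dates[perm], sc$cube$geo)
  c1b <- assemble_features(cube2, sc$dem, "C1", idx = idx)
  expect_equal(c1b, c1)
})
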