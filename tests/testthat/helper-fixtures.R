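# shared fixtures, built once per test run

fixture_path <- function(f) {
  p <- system.file("extdata", f, package = "lulcfuse")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata", f)
  p
}

.scene_cache <- new.env(parent = emptyenv())

# memoized small scene shared by tests that only need *a* valid scene
small_scene <- function(grid = 48L, seed = 101L) {
  key <- paste0("g", grid, "s", seed)
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- simulate_scene(scene_config(grid_size = grid,
                                                       seed = seed))
  .scene_cache[[key]]
}

# random simplex rows
random_simplex <- function(n, m, seed = 1L) {
  set.seed(seed)
  x <- matrix(stats::rexp(n * m), n, m)
  x / rowSums(x)
}

# well-separated Gaussian blobs for classifier checks
blob_data <- function(n_per_class = 60L, m = 3L, sep = 6, p = 4L, seed = 1L) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(m * p), m, p) * sep
  x <- do.call(rbind, lapply(seq_len(m), function(i)
    sweep(matrix(stats::rnorm(n_per_class * p), n_per_class, p), 2L,
          centers[i, ], "+")))
  colnames(x) <- paste0("f", seq_len(p))
  nm <- LETTERS[seq_len(m)]
  list(x = x, y = rep(seq_len(m), each = n_per_class),
       scheme = lulc_scheme(stats::setNames(seq_len(m), nm)))
}
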