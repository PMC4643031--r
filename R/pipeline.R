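#' Feature rows for a set of sample points
#'
#' @param samples a `sample_set` (`row`/`col` pixel coordinates).
#' @param cube a [ts_cube()].
#' @param dem elevation matrix on the cube grid.
#' @param combo feature combination (`"C1"`, `"C2"`, `"C3"`).
#' @param ... passed to [assemble_features()].
#' @return numeric feature matrix, one row per sample.
#' @export
features_at <- function(samples, cube, dem, combo = "C1", ...) {
  nr <- dim(cube$values)[3]
  idx <- (samples$col - 1L) * nr + samples$row
  assemble_features(cube, dem, combo = combo, idx = idx, ...)
}

#' Validate an experiment configuration
#'
#' @param config named list (possibly from [yaml::read_yaml()]).
#' @return the config with defaults filled; stops on invalid entries.
#' @export
validate_config <- function(config) {
  defaults <- list(
    seed = 1L, combo = "C1",
    kinds = c("RF", "SVM", "WKNN"),
    fusion = c("bayes", "vote"),
    train_fraction = 0.7,
    n_per_class = 100L, homogeneity_window = 3L,
    cmp_thresholds = c(0.3, 0.4), ratio_flag = 3,
    scene = list(), hyperparams = list(),
    classify_full_map = FALSE, change_seed = NULL, out_dir = NULL)
  if (is.null(config$kinds) && !is.null(config$classifiers))
    config$kinds <- config$classifiers
  cfg <- utils::modifyList(defaults, config)
  bad_kind <- setdiff(toupper(cfg$kinds), c("RF", "SVM", "WKNN", "ANN", "NB"))
  if (length(bad_kind))
    stop("validation error: unknown classifier kind(s): ",
         paste(bad_kind, collapse = ", "))
  if (!length(cfg$kinds)) stop("validation error: empty classifier list")
  cfg$kinds <- toupper(cfg$kinds)
  if (!cfg$combo %in% c("C1", "C2", "C3"))
    stop("validation error: combo must be C1, C2 or C3")
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    stop("validation error: train_fraction must be in (0,1)")
  cfg
}

#' Run the full classification experiment on a simulated scene
#'
#' Pipeline: simulate scene -> sample reference points -> stratified
#' split -> feature assembly -> train each backend -> predict test
#' probabilities -> fuse (Bayesian average and/or majority vote) ->
#' accuracy assessment and uncertainty diagnostics; optionally classify
#' the full scene and, when `change_seed` is set, repeat for a second
#' date and compute the conversion matrix. A machine-readable manifest
#' (inputs, seeds, stage timings) accompanies the outputs.
#'
#' @param config named list or path to a YAML file; see
#'   [validate_config()] for recognised fields.
#' @return list with the trained models, per-classifier and fused
#'   accuracy reports, fusion layers, optional maps and change results,
#'   and the run manifest.
#' @export
run_experiment <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    s <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    list(result = out, secs = as.numeric(difftime(Sys.time(), s, "secs")))
  }
  timings <- list()

  sc_cfg <- do.call(scene_config, utils::modifyList(cfg$scene,
                                                    list(seed = cfg$seed)))
  sim <- stage("simulate", simulate_scene(sc_cfg))
  timings$simulate <- sim$secs
  scene <- sim$result
  scheme <- scene$scheme

  smp <- stage("sample", {
    s <- sample_reference_points(scene$truth, cfg$n_per_class,
                                 cfg$homogeneity_window, seed = cfg$seed)
    stratified_split(s, cfg$train_fraction, seed = cfg$seed)
  })
  timings$sample <- smp$secs
  samples <- smp$result

  feat <- stage("features",
                features_at(samples, scene$cube, scene$dem, cfg$combo,
                            cellsize_m = sc_cfg$cellsize_m))
  timings$features <- feat$secs
  X <- feat$result
  tr <- samples$split == "train"

  models <- list(); probs <- list(); reports <- list()
  for (k in cfg$kinds) {
    fit <- stage(paste0("train_", k),
                 suppressWarnings(train_backend(
                   k, X[tr, , drop = FALSE], samples$class[tr], scheme,
                   cfg$hyperparams[[k]] %||% list(), seed = cfg$seed)))
    timings[[paste0("train_", k)]] <- fit$secs
    models[[k]] <- fit$result
    probs[[k]] <- predict_proba(models[[k]], X[!tr, , drop = FALSE])
    pred <- scheme$codes[max.col(probs[[k]]$probs, ties.method = "first")]
    reports[[k]] <- accuracy_report(
      confusion_matrix(pred, samples$class[!tr], scheme))
  }

  out <- list(config = cfg, scheme = scheme, samples = samples,
              models = models, member_probs = probs,
              member_reports = reports)
  if ("bayes" %in% cfg$fusion) {
    fused <- bayesian_average(probs)
    pred <- argmax_label(fused)
    out$fused_probs <- fused
    out$bayes_report <- accuracy_report(
      confusion_matrix(pred, samples$class[!tr], scheme))
    out$cmp_correlation <- tryCatch(
      cmp_accuracy_correlation(fused, samples$class[!tr], scheme),
      error = function(e) NULL)
  }
  if ("vote" %in% cfg$fusion) {
    hard <- lapply(probs, function(p)
      scheme$codes[max.col(p$probs, ties.method = "first")])
    mv <- majority_vote(hard, scheme)
    out$vote_report <- accuracy_report(
      confusion_matrix(mv$map, samples$class[!tr], scheme))
    out$vote_counts <- mv$votes
  }

  if (isTRUE(cfg$classify_full_map)) {
    full <- stage("classify_full", {
      Xf <- assemble_features(scene$cube, scene$dem, cfg$combo,
                              cellsize_m = sc_cfg$cellsize_m)
      pf <- lapply(models, predict_proba, features = Xf)
      fuse_classifiers(pf, cfg$fusion, dim = dim(scene$truth$labels),
                       geo = scene$truth$geo)
    })
    timings$classify_full <- full$secs
    out$full_map <- full$result
    if (!is.null(cfg$change_seed)) {
      chg <- stage("change", {
        scene2 <- simulate_scene(sc_cfg, seed = cfg$change_seed)
        Xf2 <- assemble_features(scene2$cube, scene2$dem, cfg$combo,
                                 cellsize_m = sc_cfg$cellsize_m)
        pf2 <- lapply(models, predict_proba, features = Xf2)
        f2 <- fuse_classifiers(pf2, "bayes", dim = dim(scene2$truth$labels),
                               geo = scene2$truth$geo)
        m1 <- out$full_map$bayes_map %||% out$full_map$vote_map
        conversion_matrix(m1, f2$bayes_map)
      })
      timings$change <- chg$secs
      out$conversion <- chg$result
    }
  }

  out$manifest <- list(
    package_version = as.character(utils::packageVersion("lulcfuse")),
    seed = cfg$seed, combo = cfg$combo, kinds = cfg$kinds,
    fusion = cfg$fusion, n_per_class = cfg$n_per_class,
    train_fraction = cfg$train_fraction,
    scene = cfg$scene, timings = timings,
    total_secs = as.numeric(difftime(Sys.time(), t0, "secs")))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(out$manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write_map(scene$truth, file.path(cfg$out_dir, "truth.asc"))
    if (!is.null(out$full_map$bayes_map))
      write_map(out$full_map$bayes_map, file.path(cfg$out_dir, "bayes.asc"))
    if (!is.null(out$full_map$vote_map))
      write_map(out$full_map$vote_map, file.path(cfg$out_dir, "vote.asc"))
  }
  out
}
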