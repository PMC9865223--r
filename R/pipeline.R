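#' Run configuration
#'
#' Validated bundle of everything a pipeline run needs. Either build it
#' in code or load it from YAML/JSON with [read_run_config()]. A run on
#' simulated data needs only `out_dir` and (optionally) scene settings;
#' a run on existing files needs `paths_by_phase` and `band_map`.
#'
#' @param out_dir output directory for stage products and the manifest.
#' @param seed integer seed used by every stochastic stage.
#' @param paths_by_phase named list phase -> multi-page TIFF path
#'   (omit when simulating).
#' @param band_map named list band -> page index (defaults to
#'   [veg_bands()] order).
#' @param scale_factor raw-value divisor on read (default 1).
#' @param mask_page optional validity-mask page index passed to
#'   [read_stack()].
#' @param plots_csv path of a plot table CSV (plot_id, class, row, col);
#'   omit when simulating.
#' @param train_fraction plot-level training fraction (default 0.6).
#' @param scene a [scene_config()] for the simulate stage.
#' @param ensemble an [ensemble_config()] for the random-forest
#'   comparator.
#' @param candidates optional named list: target class -> list of
#'   [band_combination()] for the screening stage; `NULL` uses the four
#'   built-in candidate sets.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, paths_by_phase = NULL,
                       band_map = NULL, scale_factor = 1, mask_page = NULL,
                       plots_csv = NULL, train_fraction = 0.6,
                       scene = scene_config(seed = seed),
                       ensemble = ensemble_config(seed = seed),
                       candidates = NULL) {
  if (missing(out_dir) || !nzchar(out_dir))
    stop("config field 'out_dir' is required")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("config field 'train_fraction' must be in (0, 1)")
  if (is.null(band_map))
    band_map <- stats::setNames(as.list(seq_along(veg_bands())), veg_bands())
  stopifnot(inherits(scene, "scene_config"),
            inherits(ensemble, "ensemble_config"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 paths_by_phase = paths_by_phase, band_map = band_map,
                 scale_factor = scale_factor, mask_page = mask_page,
                 plots_csv = plots_csv, train_fraction = train_fraction,
                 scene = scene, ensemble = ensemble,
                 candidates = candidates),
            class = "run_config")
}

#' Read and write run configurations (YAML or JSON)
#'
#' @param path config file; `.yml`/`.yaml` is parsed as YAML, anything
#'   else as JSON.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  scn <- do.call(scene_config, c(raw$scene, list()))
  ens <- do.call(ensemble_config, c(raw$ensemble, list()))
  run_config(out_dir = raw$out_dir,
             seed = if (is.null(raw$seed)) 1L else raw$seed,
             paths_by_phase = raw$paths_by_phase,
             band_map = raw$band_map,
             scale_factor = if (is.null(raw$scale_factor)) 1
                            else raw$scale_factor,
             mask_page = raw$mask_page,
             plots_csv = raw$plots_csv,
             train_fraction = if (is.null(raw$train_fraction)) 0.6
                              else raw$train_fraction,
             scene = scn, ensemble = ens)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- unclass(config)
  payload$scene <- unclass(payload$scene)
  payload$ensemble <- unclass(payload$ensemble)
  payload$candidates <- NULL  # combinations are built in code
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

.builtin_candidates <- function() {
  list(
    pine_oak_mixed = list(
      band_combination("RE4", "FEB", "SWIR1", "FEB",
                       target_class = "pine_oak_mixed"),
      band_combination("RE4", "DEC", "SWIR1", "DEC",
                       target_class = "pine_oak_mixed")),
    quercus_wutaishanica = list(
      band_combination("NIR", "JUN", "NIR", "OCT",
                       target_class = "quercus_wutaishanica"),
      band_combination("RE4", "JUN", "RE4", "OCT",
                       target_class = "quercus_wutaishanica")),
    scrub_grass = list(
      band_combination("RE2", "JUN", "RE2", "AUG",
                       target_class = "scrub_grass"),
      band_combination("RE3", "JUN", "RE3", "AUG",
                       target_class = "scrub_grass"),
      band_combination("NIR", "JUN", "NIR", "AUG",
                       target_class = "scrub_grass"),
      band_combination("RE4", "JUN", "RE4", "AUG",
                       target_class = "scrub_grass")),
    shaw = list(
      band_combination("RE2", "JUN", "RE2", "OCT", target_class = "shaw"),
      band_combination("RE3", "JUN", "RE3", "OCT", target_class = "shaw"),
      band_combination("NIR", "JUN", "NIR", "OCT", target_class = "shaw"),
      band_combination("RE4", "JUN", "RE4", "OCT", target_class = "shaw")))
}

# classes still in the pool when each index is screened
.screening_scopes <- function() {
  list(pine_oak_mixed = c("pine_oak_mixed", "quercus_wutaishanica",
                          "scrub_grass", "larix_principis", "shaw"),
       quercus_wutaishanica = c("quercus_wutaishanica", "scrub_grass",
                                "larix_principis", "shaw"),
       scrub_grass = c("scrub_grass", "larix_principis", "shaw"),
       shaw = c("shaw", "larix_principis"))
}

.stage_deps <- c(simulate = "", indices = "simulate", screen = "simulate",
                 train = "simulate", classify = "train",
                 evaluate = "classify")

#' Run the classification pipeline
#'
#' Executes the requested stages in order, writing each stage's products
#' and a log line to `config$out_dir`, and finishes with a JSON manifest
#' listing every output with its MD5 checksum. Stages:
#'
#' * `simulate` -- synthetic scene to per-phase TIFFs + label TIFF +
#'   plots CSV (skipped when `paths_by_phase`/`plots_csv` point at real
#'   files).
#' * `indices` -- read the stack, compute the optimal feature set, write
#'   it (TIFF + sidecar and per-sample CSV).
#' * `screen` -- standard-deviation-sum screening of the candidate band
#'   combinations per target class; report CSV.
#' * `train` -- plot-level train/verify split, knowledge-tree
#'   calibration (JSON) and random-forest fit.
#' * `classify` -- tree classification of the full scene (label CSV) and
#'   of the verification pixels.
#' * `evaluate` -- confusion matrix and accuracy report for the tree and
#'   the forest on the verification split.
#'
#' Deterministic stages reproduce bit-for-bit under an identical config
#' and seed.
#'
#' @param config a [run_config()].
#' @param stages ordered subset of
#'   `c("simulate","indices","screen","train","classify","evaluate")`.
#' @return the manifest (named list), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "indices", "screen",
                                    "train", "classify", "evaluate")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, names(.stage_deps), several.ok = TRUE)
  for (s in stages) {
    dep <- .stage_deps[[s]]
    if (nzchar(dep) && !dep %in% stages &&
        !.stage_outputs_exist(config, dep))
      stop("stage '", s, "' needs stage '", dep,
           "' (run it first or include it)")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  state <- new.env(parent = emptyenv())
  outputs <- list()
  t_all <- Sys.time()
  for (s in stages) {
    t0 <- Sys.time()
    outs <- switch(s,
      simulate = .stage_simulate(config, state),
      indices = .stage_indices(config, state),
      screen = .stage_screen(config, state),
      train = .stage_train(config, state),
      classify = .stage_classify(config, state),
      evaluate = .stage_evaluate(config, state))
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    cat(sprintf("[%s] stage %-9s %6.2fs  %s\n",
                format(Sys.time(), "%H:%M:%S"), s, dt,
                paste(basename(unlist(outs)), collapse = " ")),
        file = log_path, append = TRUE)
    outputs[[s]] <- outs
  }
  cfg_path <- file.path(config$out_dir, "run_config.json")
  write_run_config(config, cfg_path)
  files <- c(unlist(outputs, use.names = FALSE), cfg_path)
  manifest <- list(
    seed = config$seed,
    stages = stages,
    config_md5 = unname(tools::md5sum(cfg_path)),
    elapsed_s = as.numeric(difftime(Sys.time(), t_all, units = "secs")),
    outputs = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

.stage_outputs_exist <- function(config, stage) {
  probe <- switch(stage,
    simulate = file.path(config$out_dir, "plots.csv"),
    indices = file.path(config$out_dir, "optimal_features.csv"),
    train = file.path(config$out_dir, "knowledge_tree.json"),
    classify = file.path(config$out_dir, "tree_labels.csv"),
    "")
  # real-data runs satisfy 'simulate' through config paths
  if (stage == "simulate" && !is.null(config$paths_by_phase) &&
      !is.null(config$plots_csv)) return(TRUE)
  nzchar(probe) && file.exists(probe)
}

.stage_simulate <- function(config, state) {
  sim <- simulate_scene(default_profiles(), config$scene)
  state$stack <- sim$stack
  state$labels <- sim$labels
  state$plots <- sim$plots
  paths <- write_stack(sim$stack, config$out_dir, prefix = "scene")
  plots_path <- file.path(config$out_dir, "plots.csv")
  utils::write.csv(sim$plots, plots_path, row.names = FALSE)
  labels_path <- file.path(config$out_dir, "labels.csv")
  utils::write.csv(data.frame(row = as.vector(row(sim$labels)),
                              col = as.vector(col(sim$labels)),
                              class = as.vector(sim$labels)),
                   labels_path, row.names = FALSE)
  c(unname(paths), plots_path, labels_path)
}

.load_inputs <- function(config, state) {
  if (is.null(state$stack)) {
    if (!is.null(config$paths_by_phase)) {
      state$stack <- read_stack(config$paths_by_phase, config$band_map,
                                scale_factor = config$scale_factor,
                                mask_page = config$mask_page)
    } else {
      paths <- stats::setNames(
        file.path(config$out_dir, paste0("scene_", veg_phases(), ".tif")),
        veg_phases())
      if (!all(file.exists(paths)))
        stop("no stack available: provide paths_by_phase or run 'simulate'")
      state$stack <- read_stack(paths, config$band_map,
                                mask_page = length(veg_bands()) + 1L)
    }
  }
  if (is.null(state$plots)) {
    pth <- if (!is.null(config$plots_csv)) config$plots_csv
           else file.path(config$out_dir, "plots.csv")
    if (!file.exists(pth))
      stop("no plot table available: provide plots_csv or run 'simulate'")
    state$plots <- sample_plots(utils::read.csv(pth,
                                                stringsAsFactors = FALSE))
  }
  state
}

.stage_indices <- function(config, state) {
  .load_inputs(config, state)
  state$features <- optimal_feature_set(state$stack)
  tif <- file.path(config$out_dir, "optimal_features.tif")
  write_feature_set(state$features, tif)
  csv <- file.path(config$out_dir, "optimal_features.csv")
  utils::write.csv(feature_table(state$features, state$plots), csv,
                   row.names = FALSE)
  c(tif, paste0(tif, ".json"), csv)
}

.stage_screen <- function(config, state) {
  .load_inputs(config, state)
  samples <- extract_samples(state$stack, state$plots)
  cands <- if (is.null(config$candidates)) .builtin_candidates()
           else config$candidates
  scopes <- .screening_scopes()
  out <- character(0)
  defs <- list()
  for (target in names(cands)) {
    cl <- lapply(cands[[target]], function(cmb) {
      if (is.null(cmb$classes_to_identify))
        cmb$classes_to_identify <- scopes[[target]]
      cmb
    })
    rep_ <- select_combination(cl, samples)
    path <- file.path(config$out_dir,
                      paste0("screening_", target, ".csv"))
    utils::write.csv(rep_, path, row.names = FALSE)
    out <- c(out, path)
    win <- cl[[which(rep_$selected)]]
    tmpl <- switch(target, pine_oak_mixed = "DIFFERENCE",
                   quercus_wutaishanica = "NORMALIZED_COMPLEMENT",
                   scrub_grass = "DIFFERENCE", shaw = "RELATIVE_CHANGE")
    nm <- switch(target, pine_oak_mixed = "UTM-DMI",
                 quercus_wutaishanica = "MTM-NDQI",
                 scrub_grass = "MTM-DSI", shaw = "MTM-RSI")
    defs[[target]] <- instantiate_index(win, tmpl, nm)
  }
  defs_path <- file.path(config$out_dir, "index_definitions.json")
  write_index_definitions(defs, defs_path)
  c(out, defs_path)
}

.stage_train <- function(config, state) {
  .load_inputs(config, state)
  if (is.null(state$features))
    state$features <- optimal_feature_set(state$stack)
  state$split <- split_train_verify(state$plots, config$train_fraction,
                                    seed = config$seed)
  ft <- feature_table(state$features, state$plots)
  train_ft <- ft[ft$plot_id %in%
                   state$split$plot_id[state$split$role == "train"], ]
  state$tree <- build_knowledge_tree(train_ft)
  state$forest <- train_ensemble(
    train_ft[, names(state$features$layers), drop = FALSE],
    train_ft$class, config$ensemble)
  split_path <- file.path(config$out_dir, "split.csv")
  utils::write.csv(state$split, split_path, row.names = FALSE)
  tree_path <- file.path(config$out_dir, "knowledge_tree.json")
  write_tree_json(state$tree, tree_path)
  c(split_path, tree_path)
}

.stage_classify <- function(config, state) {
  if (is.null(state$tree)) {
    tree_path <- file.path(config$out_dir, "knowledge_tree.json")
    if (!file.exists(tree_path))
      stop("stage 'classify' needs stage 'train'")
    state$tree <- read_tree_json(tree_path)
  }
  .load_inputs(config, state)
  if (is.null(state$features))
    state$features <- optimal_feature_set(state$stack)
  lbl <- classify_tree(state$tree, state$features)
  state$tree_labels <- lbl
  path <- file.path(config$out_dir, "tree_labels.csv")
  utils::write.csv(data.frame(row = as.vector(row(lbl)),
                              col = as.vector(col(lbl)),
                              class = as.vector(lbl)),
                   path, row.names = FALSE)
  path
}

.stage_evaluate <- function(config, state) {
  if (is.null(state$tree_labels))
    stop("stage 'evaluate' needs stage 'classify'")
  .load_inputs(config, state)
  if (is.null(state$split)) {
    split_path <- file.path(config$out_dir, "split.csv")
    if (!file.exists(split_path))
      stop("stage 'evaluate' needs stage 'train'")
    state$split <- utils::read.csv(split_path, stringsAsFactors = FALSE)
  }
  verify <- plots_in_role(state$plots, state$split, "verify")
  ft <- feature_table(state$features, verify)
  pred_tree <- classify_tree(state$tree, ft)
  cm_tree <- confusion_matrix(pred_tree, ft$class, veg_classes())
  rep_tree <- accuracy_report(cm_tree)
  p1 <- file.path(config$out_dir, "accuracy_tree.csv")
  write_accuracy_report(rep_tree, p1)
  txt <- file.path(config$out_dir, "accuracy_tree.txt")
  writeLines(format(rep_tree), txt)
  out <- c(p1, txt)
  if (!is.null(state$forest)) {  # forest exists only for in-session train
    pred_rf <- classify_ensemble(state$forest,
                                 ft[, names(state$features$layers),
                                    drop = FALSE])
    cm_rf <- confusion_matrix(as.character(pred_rf), ft$class,
                              veg_classes())
    p2 <- file.path(config$out_dir, "accuracy_rf.csv")
    write_accuracy_report(accuracy_report(cm_rf), p2)
    out <- c(out, p2)
  }
  state$report_tree <- rep_tree
  out
}
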