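#' Read and validate a pipeline run configuration
#'
#' Run configurations are YAML files with nested sections mirroring the
#' stage constructors; every key is schema-checked before any stage runs
#' and unknown keys are rejected (a typo should fail fast, not silently
#' fall back to a default).
#'
#' @param path YAML file path, or a named list already in memory.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  schema <- list(
    seed = NULL,
    output_dir = NULL,
    backend = NULL,
    scene = c("H", "W", "C", "K", "region_model", "theta_min", "noise_sd",
              "min_region"),
    oracle = c("flip_rate", "band_width", "dilate"),
    sampling = c("per_class"),
    ipg = c("iterations", "selections_per_class", "min_votes", "lr", "grad_clip"),
    thresholds = c("tau_h", "tau_l", "kappa_h"),
    train = c("lr", "momentum", "weight_decay", "epochs", "batch_size", "widths")
  )
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(schema)) {
    if (!is.null(schema[[sec]]) && !is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), schema[[sec]])
      if (length(bad)) {
        stop("unknown key(s) in section '", sec, "': ", paste(bad, collapse = ", "))
      }
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "ipg-output"
  cfg$backend <- match.arg(cfg$backend %||% "oracle", "oracle")
  cfg$scene <- do.call(scene_spec, c(cfg$scene, list(seed = cfg$seed)))
  cfg$oracle <- cfg$oracle %||% list()
  cfg$sampling <- utils::modifyList(list(per_class = 5L), cfg$sampling %||% list())
  thr <- do.call(thresholds, cfg$thresholds %||% list())
  cfg$ipg <- do.call(ipg_config,
                     c(cfg$ipg, list(thresholds = thr, seed = cfg$seed)))
  cfg$train <- do.call(train_config, c(cfg$train, list(seed = cfg$seed)))
  structure(cfg, class = "run_config")
}

manifest_path <- function(cfg) file.path(cfg$output_dir, "manifest.json")

write_manifest <- function(cfg, stage, elapsed) {
  mf <- if (file.exists(manifest_path(cfg))) {
    jsonlite::read_json(manifest_path(cfg))
  } else {
    list(seed = cfg$seed,
         package_version = as.character(utils::packageVersion("ipghsi")),
         r_version = R.version.string, stages = list())
  }
  mf$stages[[stage]] <- list(elapsed_sec = round(elapsed, 3),
                             at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(mf, manifest_path(cfg), auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

stage_files <- function(cfg) {
  d <- cfg$output_dir
  list(cube = file.path(d, "cube.csv"), truth = file.path(d, "truth.csv"),
       bundle = file.path(d, "oracle"), seeds = file.path(d, "seeds.csv"),
       ledger = file.path(d, "ledger.csv"), voted = file.path(d, "voted.csv"),
       log = file.path(d, "iterations.csv"), pred = file.path(d, "prediction.csv"),
       metrics = file.path(d, "metrics.json"))
}

require_stage <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop("missing artefact '", path, "'; run `", produced_by, "` first")
  }
}

#' Pipeline commands
#'
#' File-to-file stage commands backing the command-line interface
#' (`inst/cli/ipg.R`): `cmd_simulate()` writes the synthetic scene and its
#' oracle bundle, `cmd_ipg()` the pseudo-label ledger and voted map,
#' `cmd_train()` the full prediction map, `cmd_evaluate()` the metric
#' report; `cmd_all()` chains them. Each command is idempotent for a given
#' config and seed and appends its timing to a run manifest.
#'
#' @param cfg A [read_run_config()] configuration.
#' @return The principal object of the stage, invisibly.
#' @export
cmd_simulate <- function(cfg) {
  t0 <- proc.time()[3]
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  f <- stage_files(cfg)
  scene <- generate_scene(cfg$scene)
  write_cube(scene$cube, f$cube)
  write_labels(scene$truth, f$truth)
  bundle <- do.call(export_oracle, c(list(scene), cfg$oracle))
  write_oracle_bundle(bundle, f$bundle)
  seeds <- sample_seed_labels(scene$truth, cfg$sampling$per_class, cfg$seed)
  utils::write.csv(seeds, f$seeds, row.names = FALSE)
  write_manifest(cfg, "simulate", proc.time()[3] - t0)
  invisible(scene)
}

#' @rdname cmd_simulate
#' @export
cmd_ipg <- function(cfg) {
  t0 <- proc.time()[3]
  f <- stage_files(cfg)
  require_stage(f$cube, "ipg simulate")
  cube <- read_cube(f$cube)
  seeds <- utils::read.csv(f$seeds)
  class(seeds) <- c("seed_labels", "data.frame")
  backend <- oracle_segmenter(read_oracle_bundle(f$bundle))
  fit <- ipg(cube, seeds, backend, cfg$ipg)
  write_ledger(fit, f$ledger)
  write_labels(fit$voted$labels, f$voted)
  utils::write.csv(fit$log, f$log, row.names = FALSE)
  write_manifest(cfg, "ipg", proc.time()[3] - t0)
  invisible(fit)
}

#' @rdname cmd_simulate
#' @export
cmd_train <- function(cfg) {
  t0 <- proc.time()[3]
  f <- stage_files(cfg)
  require_stage(f$ledger, "ipg ipg")
  cube <- read_cube(f$cube)
  seeds <- utils::read.csv(f$seeds)
  ledger <- utils::read.csv(f$ledger)
  ts <- build_training_set(seeds, ledger)
  model <- hsi_cnn(extract_patches(cube, ts, 9L), cfg$train)
  pred <- predict(model, cube)
  write_labels(pred$labels, f$pred)
  write_manifest(cfg, "train", proc.time()[3] - t0)
  invisible(list(model = model, pred = pred))
}

#' @rdname cmd_simulate
#' @export
cmd_evaluate <- function(cfg) {
  t0 <- proc.time()[3]
  f <- stage_files(cfg)
  require_stage(f$pred, "ipg train")
  truth <- read_labels(f$truth)
  pred <- read_labels(f$pred)
  seeds <- utils::read.csv(f$seeds)
  ledger <- utils::read.csv(f$ledger)
  ts <- build_training_set(seeds, ledger)
  eval_px <- which(truth > 0L, arr.ind = TRUE)
  keep <- !(paste(eval_px[, 1], eval_px[, 2]) %in% paste(ts$row, ts$col))
  eval_px <- eval_px[keep, , drop = FALSE]
  report <- metric_report(confusion_matrix(truth, pred, eval_px))
  write_metric_report(report, f$metrics)
  write_manifest(cfg, "evaluate", proc.time()[3] - t0)
  invisible(report)
}

#' @rdname cmd_simulate
#' @export
cmd_all <- function(cfg) {
  cmd_simulate(cfg)
  cmd_ipg(cfg)
  cmd_train(cfg)
  invisible(cmd_evaluate(cfg))
}
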