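#' Assemble a pipeline run configuration
#'
#' Validates and normalises the configuration for [run_pipeline()]. Can be
#' given a YAML file path or a named list; unknown fields are rejected so
#' typos fail fast (exit/contract behaviour for the command-line wrapper).
#'
#' @param config Named list or path to a YAML file.
#' @return A list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    task = "diagnosis", seed = 1, preset = "tiny", out_dir = "gazedx-run",
    fold_safe = FALSE, K = 16,
    n_frames = 61, stim_shape = c(72, 128),
    n_asd = 10, n_td = 10, n_moderate = 5,
    geo_mean_asd = 49.37, geo_sd_asd = 24.14,
    geo_mean_td = 35.97, geo_sd_td = 18.58,
    geo_mean_moderate = 48.21, geo_sd_moderate = 23.82,
    geo_mean_high = 50.98, geo_sd_high = 25.00,
    noise_sd_deg = 0.15, epochs = 20, learning_rate = 1e-4)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  # when the diagnostic-group %Geo is overridden but the severity strata are
  # not, inherit the strata from the group so the cohort stays coherent
  for (fld in c("geo_mean", "geo_sd")) {
    if (any(c(paste0(fld, "_asd")) %in% names(config))) {
      for (str in c("moderate", "high")) {
        key <- paste0(fld, "_", str)
        if (!key %in% names(config)) cfg[[key]] <- cfg[[paste0(fld, "_asd")]]
      }
    }
  }
  if (!cfg$task %in% c("diagnosis", "severity"))
    stop("task must be 'diagnosis' or 'severity'")
  if (!cfg$preset %in% c("tiny", "paper"))
    stop("preset must be 'tiny' or 'paper'")
  structure(cfg, class = "run_config")
}

#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates the stage sequence: simulate a cohort, detect and filter
#' fixations, apply the trial-inclusion rule, build per-frame DoF maps,
#' fine-tune the saliency network, extract and cascade fixation features,
#' classify under LOOCV and evaluate. All artefacts (metadata, fixation
#' table, truth table, per-fold CV results, metrics JSON, loss trace) plus a
#' manifest with per-file checksums are written to the run directory.
#' Rerunning with the same configuration reproduces the deterministic
#' artefacts bit for bit.
#'
#' @param config A [run_config()], named list, or YAML path.
#' @return Invisibly, a list with `metrics`, `cv`, `manifest_path`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf("[gazedx %s] %s",
                                             format(Sys.time(), "%H:%M:%S"),
                                             sprintf(...)))

  log_stage("simulate: %d ASD + %d TD, %d frames", cfg$n_asd, cfg$n_td,
            cfg$n_frames)
  stimulus <- make_stimulus(cfg$n_frames, cfg$stim_shape, seed = cfg$seed)
  geometry <- stimulus_geometry(stimulus)
  if (cfg$task == "severity" && cfg$n_td > 0)
    stop("severity task requires an ASD-only cohort (set n_td = 0)")
  spec <- cohort_spec(n_asd = cfg$n_asd, n_td = cfg$n_td,
                      n_moderate = cfg$n_moderate,
                      geo_mean_asd = cfg$geo_mean_asd,
                      geo_sd_asd = cfg$geo_sd_asd,
                      geo_mean_td = cfg$geo_mean_td,
                      geo_sd_td = cfg$geo_sd_td,
                      geo_mean_moderate = cfg$geo_mean_moderate,
                      geo_sd_moderate = cfg$geo_sd_moderate,
                      geo_mean_high = cfg$geo_mean_high,
                      geo_sd_high = cfg$geo_sd_high,
                      noise_sd_deg = cfg$noise_sd_deg, seed = cfg$seed)
  cohort <- make_cohort(spec, stimulus, geometry)
  utils::write.csv(cohort$truth, file.path(cfg$out_dir, "truth.csv"),
                   row.names = FALSE)

  log_stage("detect-fixations: I-VT + merge/discard")
  fcfg <- fixation_filter_config(
    min_trial_fixation_s = min(15, 0.25 * stimulus$duration_s))
  recs <- lapply(cohort$recordings, process_recording, cfg = fcfg,
                 geometry = geometry, n_frames = stimulus$n_frames,
                 duration_s = stimulus$duration_s)
  included <- vapply(recs, trial_inclusion, logical(1), cfg = fcfg)
  log_stage("inclusion: %d/%d recordings kept", sum(included), length(recs))
  recs <- recs[included]
  write_fixations_tsv(recs, file.path(cfg$out_dir, "fixations.tsv"))
  meta <- data.frame(
    participant_id = vapply(recs, `[[`, "", "participant_id"),
    group = vapply(recs, `[[`, "", "group"),
    severity = vapply(recs, `[[`, "", "severity"))
  utils::write.csv(meta, file.path(cfg$out_dir, "metadata.csv"),
                   row.names = FALSE)

  log_stage("train + classify: preset '%s', task %s", cfg$preset, cfg$task)
  res <- classify_cohort(recs, stimulus, task = cfg$task,
                         model_cfg = model_config(cfg$preset),
                         train_cfg = training_config(
                           epochs = cfg$epochs,
                           learning_rate = cfg$learning_rate,
                           seed = cfg$seed),
                         K = cfg$K, geometry = geometry,
                         fold_safe = cfg$fold_safe)
  utils::write.csv(res$cv, file.path(cfg$out_dir, "cv_folds.csv"),
                   row.names = FALSE)
  if (!is.null(res$model))
    utils::write.csv(res$model$trace,
                     file.path(cfg$out_dir, "loss_trace.csv"),
                     row.names = FALSE)

  log_stage("evaluate")
  m <- res$metrics
  metrics <- list(task = cfg$task, K = res$best_K,
                  n_folds = nrow(res$cv),
                  accuracy = m$accuracy, sensitivity = m$sensitivity,
                  specificity = m$specificity, auc = m$auc)
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- setdiff(list.files(cfg$out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("gazedx")),
    seed = cfg$seed, config = unclass(cfg),
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(cfg$out_dir, f)))))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  log_stage("done: %s", cfg$out_dir)
  invisible(list(metrics = metrics, cv = res$cv,
                 manifest_path = manifest_path, out_dir = cfg$out_dir))
}
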