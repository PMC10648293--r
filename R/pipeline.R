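# End-to-end orchestration: simulate -> features -> normalize -> select ->
# train -> evaluate, from one configuration object, with every stage's
# randomness derived from one master seed and all artifacts written under a
# run directory with a manifest.

#' Build a pipeline configuration
#'
#' One object driving the full run. The generator section is a
#' [generatorConfig()]; the remaining entries configure synchronization,
#' feature extraction, MRMR, the split plan and the preset list.
#'
#' @param generator a [generatorConfig()]
#' @param sync_tolerance_s synchronization tolerance, seconds
#' @param psc_delay_ms,tfa_band,tfa_window_ms feature-extraction parameters
#' @param mrmr_k MRMR selection size
#' @param presets model presets to enter
#' @param n_test held-out test patients
#' @param cv_folds cross-validation folds
#' @param grouped_cv patient-grouped folds instead of trial-level folds
#' @param fit_on_all fit the normalizer on the consolidated cohort
#' @param nerves nerves to model (default all four)
#' @param seed master seed: the generator and split seeds are derived from
#'   it as named substreams
#' @return a `PipelineConfig` list
#' @export
pipelineConfig <- function(generator = generatorConfig(),
                           sync_tolerance_s = 60,
                           psc_delay_ms = 2, tfa_band = c(10, 500),
                           tfa_window_ms = 20,
                           mrmr_k = 10, presets = modelPresets(),
                           n_test = 2, cv_folds = 5, grouped_cv = FALSE,
                           fit_on_all = FALSE,
                           nerves = monitoredNerves(),
                           seed = 1L) {
  generator$seed <- as.integer(seed) * 7L + 1L     # generator substream
  cfg <- list(generator = generator, sync_tolerance_s = sync_tolerance_s,
              psc_delay_ms = psc_delay_ms, tfa_band = tfa_band,
              tfa_window_ms = tfa_window_ms, mrmr_k = mrmr_k,
              presets = presets, n_test = n_test, cv_folds = cv_folds,
              grouped_cv = grouped_cv, fit_on_all = fit_on_all,
              nerves = nerves, seed = as.integer(seed),
              split_seed = as.integer(seed) * 11L + 3L)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; the
#' `generator` key holds [generatorConfig()] arguments (including a nested
#' `concentration_profile`).
#'
#' @param path YAML file path
#' @return a `PipelineConfig`
#' @export
loadPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  gen_args <- raw$generator
  gen_args$seed <- NULL
  gen <- do.call(generatorConfig, gen_args %||% list())
  raw$generator <- NULL
  do.call(pipelineConfig, c(list(generator = gen), raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Generates the synthetic cohort, writes session JSON and anesthesia CSV
#' files, synchronizes trials, assembles and writes the feature table,
#' runs the model tournament per nerve, and writes `report.json` plus a
#' `manifest.json` (configuration hash, package version, seeds). Rerunning
#' with the same configuration reproduces a byte-identical report.
#'
#' @param config a [pipelineConfig()] or a YAML path accepted by
#'   [loadPipelineConfig()]
#' @param out_dir run directory (created if needed)
#' @param quiet suppress progress messages
#' @return invisibly, a list with the feature table, the per-nerve
#'   `EvalReport`s and the paths written
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir = tempfile("run"),
                        quiet = FALSE) {
  if (is.character(config)) config <- loadPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "sessions"), showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  say("stage simulate: ", config$generator$n_patients, " patients")
  cohort <- .stage("simulate", generateCohort(config$generator))
  .stage("write_sessions", for (s in cohort) {
    writeSession(s, file.path(out_dir, "sessions",
                              paste0(patientId(s), ".json")))
    writeAnesthesiaCsv(sessionAnesthesia(s),
                       file.path(out_dir, "sessions",
                                 paste0(patientId(s), "_anesthesia.csv")))
  })

  say("stage synchronize")
  synced <- .stage("synchronize", {
    out <- lapply(cohort, synchronizeTrials,
                  tolerance = config$sync_tolerance_s)
    names(out) <- vapply(cohort, patientId, character(1))
    out
  })

  say("stage features")
  table <- .stage("features", assembleFeatureTable(
    synced, psc_delay_ms = config$psc_delay_ms,
    tfa_band = config$tfa_band, tfa_window_ms = config$tfa_window_ms))
  write.csv(table, file.path(out_dir, "features.csv"), row.names = FALSE)

  plan <- makeSplitPlan(unique(table$patient_id), n_test = config$n_test,
                        cv_folds = config$cv_folds,
                        seed = config$split_seed,
                        grouped_cv = config$grouped_cv)
  say("stage evaluate: ", length(config$nerves), " nerve(s), ",
      length(config$presets), " presets")
  reports <- .stage("evaluate", {
    r <- lapply(config$nerves, function(nv)
      modelTournament(table, nv, plan, presets = config$presets,
                      k = config$mrmr_k, fit_on_all = config$fit_on_all))
    names(r) <- config$nerves
    r
  })

  report_doc <- lapply(reports, function(r) list(
    nerve = r$nerve, winner = r$winner,
    validation = r$validation, rmse_test = r$rmse_test,
    selected_features = r$selected_features,
    train_patients = plan$train_patients,
    test_patients = plan$test_patients))
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_doc, report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  cfg_path <- file.path(out_dir, "config.json")
  cfg_plain <- unclass(config)
  cfg_plain$generator <- unclass(cfg_plain$generator)
  jsonlite::write_json(cfg_plain, cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("ssepml")),
    master_seed = config$seed,
    generator_seed = config$generator$seed, split_seed = config$split_seed,
    n_rows = nrow(table),
    outputs = c("sessions/", "features.csv", "report.json", "config.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(table = table, reports = reports, out_dir = out_dir,
                 plan = plan, report_path = report_path))
}
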