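## Delimited-text I/O for sessions, results and configurations.

#' Write a session to delimited text
#'
#' Writes `<prefix>_gaze.csv` (trial_id, t_ms, x_deg, y_deg, pupil_valid),
#' `<prefix>_trials.csv` (the trial table) and `<prefix>_truth.json`
#' (ground-truth parameters and per-trial latent state, the structured
#' sidecar).
#'
#' @param session a `sim_session`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of the files written.
#' @export
write_session <- function(session, dir, prefix = "session") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fg <- file.path(dir, paste0(prefix, "_gaze.csv"))
  ft <- file.path(dir, paste0(prefix, "_trials.csv"))
  fj <- file.path(dir, paste0(prefix, "_truth.json"))
  utils::write.csv(session$gaze, fg, row.names = FALSE)
  utils::write.csv(session$trials, ft, row.names = FALSE)
  cfg <- unclass(session$config)
  cfg$fix_scatter <- as.list(cfg$fix_scatter)
  truth <- list(profile = unclass(session$profile),
                condition = session$condition, mode = session$mode,
                config = cfg,
                ground_truth = session$ground_truth)
  jsonlite::write_json(truth, fj, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  c(fg, ft, fj)
}

#' Read a session written by [write_session()]
#'
#' @param dir directory holding the files.
#' @param prefix file-name prefix used at write time.
#' @return a `sim_session`-compatible list (usable by
#'   [preprocess_session()]).
#' @export
read_session <- function(dir, prefix = "session") {
  gaze <- utils::read.csv(file.path(dir, paste0(prefix, "_gaze.csv")))
  gaze$pupil_valid <- as.logical(gaze$pupil_valid)
  trials <- utils::read.csv(file.path(dir, paste0(prefix, "_trials.csv")),
                            stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(dir, paste0(prefix, "_truth.json")),
                               simplifyVector = TRUE)
  prof <- truth$profile
  cfg <- truth$config
  cfg$fix_scatter <- unlist(cfg$fix_scatter)
  class(cfg) <- "generator_config"
  structure(list(trials = trials, gaze = gaze,
                 ground_truth = as.data.frame(truth$ground_truth),
                 profile = structure(prof, class = "participant_profile"),
                 config = cfg, condition = truth$condition,
                 mode = truth$mode),
            class = "sim_session")
}

#' Serialize / restore a pipeline configuration
#'
#' JSON round trip of a [pipeline_config()]; every numeric survives
#' losslessly (full double precision is written).
#'
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$generator <- unclass(x$generator)
  # named vectors must become JSON objects, not nameless arrays
  x$generator$fix_scatter <- as.list(x$generator$fix_scatter)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- x$generator
  gen$fix_scatter <- unlist(gen$fix_scatter)
  gen$seed <- as.integer(gen$seed)
  class(gen) <- "generator_config"
  pipeline_config(
    experiment = x$experiment, n_participants = x$n_participants,
    trait_range = unlist(x$trait_range), generator = gen,
    threshold = x$threshold, min_duration_ms = x$min_duration_ms,
    min_amplitude = x$min_amplitude,
    fix_window_radius = x$fix_window_radius, n_window = x$n_window,
    k = x$k, bcea_formula = x$bcea_formula, n_bins = x$n_bins,
    bin_frac = x$bin_frac, binning_mode = x$binning_mode,
    prior_scale = x$prior_scale, seed = x$seed,
    out_dir = if (is.null(x$out_dir)) NULL else x$out_dir)
}

#' Write the report bundle of a pipeline run
#'
#' Per-participant results, group statistics and the trial-level rejection
#' log as CSV, plus the full configuration as JSON (provenance header of
#' the bundle).
#'
#' @param report a `saccadapt_report`.
#' @param dir output directory.
#' @return character vector of files written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "participants.csv")
  f2 <- file.path(dir, "group_stats.csv")
  f3 <- file.path(dir, "rejections.csv")
  f4 <- file.path(dir, "config.json")
  utils::write.csv(report$participants, f1, row.names = FALSE)
  if (!is.null(report$group_stats))
    utils::write.csv(report$group_stats, f2, row.names = FALSE)
  utils::write.csv(report$rejections, f3, row.names = FALSE)
  write_pipeline_config(report$config, f4)
  c(f1, f2, f3, f4)
}
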