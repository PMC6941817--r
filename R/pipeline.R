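# Pipeline orchestration: generate -> track -> predict -> simulate ->
# evaluate as composable stages driven by one validated configuration, with
# manifests and a single seed fanned out to per-stage substreams.

config_known <- function() list(
  top = c("stages", "out", "seed", "log_level", "kinematics", "optics",
          "track", "predict", "simulate", "evaluate"),
  kinematics = setdiff(names(formals(worm_kinematics)), "seed"),
  optics = names(formals(worm_optics)),
  track = c("alpha", "min_area", "head_window", "v_alpha", "refine"),
  predict = c("s", "horizon"),
  simulate = c("s", "TR", "TE", "n_lines", "n_readout", "horizon", "mode",
               "resolution_ratio", "start_frame", "voxel_um"),
  evaluate = c("paradigm", "s_values", "horizons", "ratios")
)

check_keys <- function(x, section) {
  bad <- setdiff(names(x), config_known()[[section]])
  if (length(bad) > 0)
    stop("unknown configuration key(s) in ", section, ": ",
         paste(bad, collapse = ", "))
  x
}

#' Build and validate a pipeline run configuration
#'
#' Accepts a named list or the path of a YAML file. Unknown keys are
#' rejected; sequence parameters are validated up front (e.g. TE < TR fails
#' here, before any stage runs). The configuration round-trips losslessly
#' through [yaml::write_yaml].
#'
#' @param x named list or YAML file path
#' @return validated `run_config` list
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  check_keys(x, "top")
  cfg <- list(
    stages = x$stages %||% c("generate", "track", "predict", "simulate",
                             "evaluate"),
    out = x$out %||% "wormmri_run",
    seed = as.integer(x$seed %||% 1L),
    log_level = x$log_level %||% "info",
    kinematics = check_keys(x$kinematics %||% list(), "kinematics"),
    optics = check_keys(x$optics %||% list(), "optics"),
    track = check_keys(x$track %||% list(), "track"),
    predict = check_keys(x$predict %||% list(s = 0.9, horizon = 12L),
                         "predict"),
    simulate = check_keys(x$simulate %||% list(), "simulate"),
    evaluate = check_keys(x$evaluate %||% list(paradigm = "horizon"),
                          "evaluate")
  )
  known_stages <- c("generate", "track", "predict", "simulate", "evaluate")
  if (!all(cfg$stages %in% known_stages))
    stop("unknown stage(s): ",
         paste(setdiff(cfg$stages, known_stages), collapse = ", "))
  # validate sequence parameters before any stage runs
  sim <- cfg$simulate
  do.call(sequence_params, sim[setdiff(names(sim), "s")])
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_stage <- function(cfg, stage, msg) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full processing pipeline
#'
#' Executes the requested stages in order (generate, track, predict,
#' simulate, evaluate), writing each stage's artifacts and a manifest (all
#' parameters including the seed) under the configured output directory.
#' Re-running with the same configuration reproduces the same artifacts.
#'
#' @param config a [run_config], a named list, or a YAML file path
#' @return invisibly, a list with the artifact paths and in-memory results
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "wormmri",
                   version = as.character(utils::packageVersion("wormmri")),
                   seed = config$seed,
                   stages = config$stages)
  res <- list()
  kin <- do.call(worm_kinematics,
                 c(config$kinematics, list(seed = config$seed)))
  dataset <- NULL
  if ("generate" %in% config$stages) {
    log_stage(config, "generate", "synthesising video dataset")
    optics <- do.call(worm_optics, config$optics)
    dataset <- generate_dataset(kin, optics)
    write_dataset(dataset, file.path(out, "dataset"))
    res$dataset_dir <- file.path(out, "dataset")
    manifest$kinematics <- unclass(kin)
  } else {
    dataset <- read_dataset(file.path(out, "dataset"))
  }
  track <- NULL
  if ("track" %in% config$stages) {
    log_stage(config, "track", "detecting and tracking the worm")
    track <- do.call(track_video, c(list(dataset), config$track))
    write.csv(track$summary, file.path(out, "track.csv"), row.names = FALSE)
    skel_df <- do.call(rbind, lapply(seq_along(track$frames), function(i) {
      o <- track$frames[[i]]
      if (!isTRUE(o$present)) return(NULL)
      data.frame(frame = i - 1L, node = seq_len(nrow(o$skel$path)) - 1L,
                 x_um = o$skel$path[, 1], y_um = o$skel$path[, 2],
                 s = o$skel$s)
    }))
    write.csv(skel_df, file.path(out, "skeleton.csv"), row.names = FALSE)
    res$track <- track
  }
  if ("predict" %in% config$stages) {
    if (is.null(track)) stop("predict stage requires the track stage")
    log_stage(config, "predict", "scoring POI predictions")
    rep <- evaluate_prediction(dataset, track,
                               s = config$predict$s %||% 0.9,
                               delta_k = config$predict$horizon %||% 12L)
    write.csv(as.data.frame(rep), file.path(out, "errors.csv"),
              row.names = FALSE)
    manifest$mean_prediction_error_um <- attr(rep, "mean_prediction_error")
    res$prediction_errors <- rep
  }
  if ("simulate" %in% config$stages) {
    log_stage(config, "simulate", "running gradient-echo acquisition")
    sim <- config$simulate
    params <- do.call(sequence_params, sim[setdiff(names(sim), "s")])
    if (params$mode == "prediction" && is.null(track))
      stop("simulate stage in prediction mode requires the track stage")
    ks <- run_gre(dataset, params, s = sim$s %||% 0.52, track = track)
    rec <- reconstruct(ks)
    rundir <- file.path(out, "run")
    dir.create(rundir, showWarnings = FALSE)
    write.csv(Re(ks$k), file.path(rundir, "kspace_real.csv"),
              row.names = FALSE)
    write.csv(Im(ks$k), file.path(rundir, "kspace_imag.csv"),
              row.names = FALSE)
    write.csv(unclass(rec), file.path(rundir, "recon.csv"),
              row.names = FALSE)
    png::writePNG(clamp(unclass(rec) / max(max(rec), 1e-12), 0, 1),
                  file.path(rundir, "recon.png"))
    manifest$simulate <- c(unclass(params), list(s = ks$s,
                                                 voxel_um = ks$voxel_um))
    res$kspace <- ks
    res$recon <- rec
  }
  if ("evaluate" %in% config$stages) {
    if (is.null(track)) stop("evaluate stage requires the track stage")
    log_stage(config, "evaluate", "scoring simulation paradigm")
    ev <- config$evaluate
    par <- ev$paradigm %||% "horizon"
    report <- switch(
      par,
      body_position = simulation_body_position(
        list(dataset), list(track),
        s_values = ev$s_values %||% c(0.02, 0.5, 1.0)),
      resolution = simulation_resolution(
        list(dataset), list(track), ratios = ev$ratios %||% c(1, 2, 4)),
      horizon = simulation_horizon(
        list(dataset), list(track), s_values = ev$s_values %||% 0.52,
        horizons = ev$horizons %||% 1:10),
      stop("unknown evaluation paradigm: ", par))
    write.csv(as.data.frame(report), file.path(out, "report.csv"),
              row.names = FALSE)
    res$report <- report
  }
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  res$manifest <- file.path(out, "manifest.yaml")
  invisible(res)
}
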