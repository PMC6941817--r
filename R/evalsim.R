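# Simulation paradigms: score reconstructions of the moving worm against the
# true slice with the structural similarity measure, across body positions,
# MR:optical resolution ratios and prediction horizons, and classify
# imageability from the motion / prediction / repetition timescales.

# run one acquisition + reconstruction + scoring
score_run <- function(dataset, track, s, mode, horizon, params_base = list(),
                      np_frame = NULL) {
  params <- do.call(sequence_params,
                    c(list(mode = mode, horizon = horizon), params_base))
  ks <- run_gre(dataset, params, s,
                track = if (mode == "prediction") track else NULL,
                np_frame = np_frame)
  tru <- true_slice_image(dataset, s, voxel_um = ks$voxel_um,
                          n = params$n_lines)
  ssim(tru, reconstruct(ks))$s_xy
}

new_paradigm_report <- function(df, paradigm) {
  df <- df[order(df$video, df$s, df$horizon, df$mode), ]
  rownames(df) <- NULL
  structure(df, class = c("paradigm_report", "data.frame"),
            paradigm = paradigm)
}

#' @export
print.paradigm_report <- function(x, ...) {
  cat(sprintf("<paradigm_report: %s> %d runs\n", attr(x, "paradigm"), nrow(x)))
  agg <- stats::aggregate(ssim ~ mode, data = as.data.frame(x), FUN = mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  mean s_xy (%s): %.3f\n", agg$mode[i], agg$ssim[i]))
  invisible(x)
}

#' Body-position paradigm: imaging quality along the worm
#'
#' Acquires head (s = 0.02), mid-body (s = 0.5) and tail (s = 1) slices at
#' horizon 1, with and without prediction (the no-prediction gradient center
#' is fixed at the slice position of the acquisition start frame), and
#' scores each reconstruction against the true slice.
#'
#' @param datasets list of `video_dataset` objects (one per video)
#' @param tracks optional list of matching `worm_track`s (computed if NULL)
#' @param s_values slice coordinates
#' @param horizon prediction horizon in frames
#' @param params_base named list of extra [sequence_params] arguments
#' @return `paradigm_report` data.frame: video, s, horizon, mode, ratio, ssim
#' @export
simulation_body_position <- function(datasets, tracks = NULL,
                                     s_values = c(0.02, 0.5, 1.0),
                                     horizon = 1L, params_base = list()) {
  datasets <- if (inherits(datasets, "video_dataset")) list(datasets) else datasets
  if (is.null(tracks)) tracks <- lapply(datasets, track_video)
  rows <- list()
  for (vi in seq_along(datasets)) {
    f0 <- do.call(sequence_params, c(list(mode = "static"), params_base))$start_frame
    for (s in s_values) for (mode in c("prediction", "no_prediction")) {
      sx <- score_run(datasets[[vi]], tracks[[vi]], s, mode, horizon,
                      params_base, np_frame = if (mode == "no_prediction") f0)
      rows[[length(rows) + 1]] <- data.frame(
        video = vi, s = s, horizon = horizon, mode = mode, ratio = NA_real_,
        ssim = sx)
    }
  }
  new_paradigm_report(do.call(rbind, rows), "body position")
}

#' Resolution paradigm: MR:optical pixel ratio
#'
#' Images the mid-body slice s = 0.72 at horizon 1 for MR:optical resolution
#' ratios (r MR voxels per optical pixel; larger r = finer MR voxels), with
#' and without prediction.
#'
#' @inheritParams simulation_body_position
#' @param s slice coordinate
#' @param ratios numeric MR:optical ratios
#' @return `paradigm_report`
#' @export
simulation_resolution <- function(datasets, tracks = NULL, s = 0.72,
                                  ratios = c(1, 2, 4), horizon = 1L,
                                  params_base = list()) {
  datasets <- if (inherits(datasets, "video_dataset")) list(datasets) else datasets
  if (is.null(tracks)) tracks <- lapply(datasets, track_video)
  rows <- list()
  for (vi in seq_along(datasets)) {
    for (r in ratios) for (mode in c("prediction", "no_prediction")) {
      pb <- c(params_base, list(resolution_ratio = r))
      f0 <- do.call(sequence_params, c(list(mode = "static"), pb))$start_frame
      sx <- score_run(datasets[[vi]], tracks[[vi]], s, mode, horizon, pb,
                      np_frame = if (mode == "no_prediction") f0)
      rows[[length(rows) + 1]] <- data.frame(
        video = vi, s = s, horizon = horizon, mode = mode, ratio = r,
        ssim = sx)
    }
  }
  new_paradigm_report(do.call(rbind, rows), "resolution ratio")
}

#' Horizon paradigm: imaging quality versus prediction horizon
#'
#' Sweeps prediction horizons (default 1..10 frames) for one or more slices.
#' In the no-prediction arm the gradient center is fixed at the ground-truth
#' slice position `horizon` frames after the acquisition start.
#'
#' @inheritParams simulation_body_position
#' @param s_values slice coordinate(s); 0.52 reproduces the single-slice
#'   sweep, `c(0.1, 0.3, 0.5, 0.9)` the four-slice statistical grid
#' @param horizons integer vector of horizons
#' @return `paradigm_report`
#' @export
simulation_horizon <- function(datasets, tracks = NULL, s_values = 0.52,
                               horizons = 1:10, params_base = list()) {
  datasets <- if (inherits(datasets, "video_dataset")) list(datasets) else datasets
  if (is.null(tracks)) tracks <- lapply(datasets, track_video)
  rows <- list()
  for (vi in seq_along(datasets)) {
    for (s in s_values) for (dk in horizons) {
      for (mode in c("prediction", "no_prediction")) {
        sx <- score_run(datasets[[vi]], tracks[[vi]], s, mode, dk,
                        params_base)
        rows[[length(rows) + 1]] <- data.frame(
          video = vi, s = s, horizon = dk, mode = mode, ratio = NA_real_,
          ssim = sx)
      }
    }
  }
  new_paradigm_report(do.call(rbind, rows), "prediction horizon")
}

#' Overall improvement factor of prediction over no prediction
#'
#' Ratio of the mean structural similarity with prediction to the mean
#' without, over all conditions of a paradigm report (per-video means first,
#' then across videos).
#' @param report a `paradigm_report`
#' @return list with `ratio`, `mean_prediction`, `mean_no_prediction`
#' @export
improvement_ratio <- function(report) {
  df <- as.data.frame(report)
  per <- stats::aggregate(ssim ~ video + mode, data = df, FUN = mean)
  mp <- mean(per$ssim[per$mode == "prediction"])
  mn <- mean(per$ssim[per$mode == "no_prediction"])
  list(ratio = mp / mn, mean_prediction = mp, mean_no_prediction = mn)
}

#' Classify MR imageability from the relevant timescales
#'
#' Compares the characteristic time of sample motion `t_motion`, the
#' prediction calculation time `t_pred`, and the repetition time `TR`:
#' if the sample moves faster than one repetition (t_motion <= TR) it is not
#' imageable without motion artifacts; if it is slower but the prediction
#' cannot be computed within one repetition (t_pred >= TR) it is imageable
#' with restrictions on the usable contrast timings; if the prediction also
#' fits inside a repetition (t_pred < TR < t_motion) it is imageable without
#' contrast restrictions.
#'
#' @param t_motion characteristic motion time in ms
#' @param t_pred prediction computation time in ms
#' @param TR repetition time in ms
#' @return one of `"not_imageable"`, `"imageable_contrast_restricted"`,
#'   `"imageable_unrestricted"`
#' @export
#' @examples
#' classify_imageability(t_motion = 500, t_pred = 76, TR = 83)
classify_imageability <- function(t_motion, t_pred, TR) {
  if (any(c(t_motion, t_pred, TR) <= 0)) stop("timescales must be positive")
  if (t_motion <= TR) return("not_imageable")
  if (t_pred >= TR) return("imageable_contrast_restricted")
  "imageable_unrestricted"
}
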