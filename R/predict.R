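# Coordinate prediction: future COG by linear extrapolation, future POI
# position along the current center line via s_c = s - v * dk, and the mean
# prediction error against ground truth.

#' Predict the future COG by linear extrapolation
#'
#' Least-squares line through the last (up to five) smoothed COG positions,
#' evaluated `delta_k` frames ahead; with `method = "two_point"` only the
#' slope between the two most recent positions is used. A single history
#' point is returned unchanged.
#'
#' @param history m x 2 matrix of COG positions, one row per frame, most
#'   recent last (at most the last 5 rows are used)
#' @param delta_k prediction horizon in frames (>= 0)
#' @param method `"least_squares"` (default) or `"two_point"`
#' @return length-2 numeric: predicted position
#' @export
predict_cog <- function(history, delta_k, method = c("least_squares",
                                                     "two_point")) {
  method <- match.arg(method)
  history <- rbind(history)
  m <- nrow(history)
  if (m < 1) stop("empty COG history")
  if (m == 1) return(as.numeric(history[1, ]))
  use <- history[max(1, m - 4):m, , drop = FALSE]
  n <- nrow(use)
  if (method == "two_point") {
    slope <- use[n, ] - use[n - 1, ]
    return(as.numeric(use[n, ] + delta_k * slope))
  }
  k <- seq_len(n)
  kc <- k - mean(k)
  slope <- c(sum(kc * use[, 1]), sum(kc * use[, 2])) / sum(kc^2)
  icpt <- colMeans(use) - slope * mean(k)
  as.numeric(icpt + slope * (n + delta_k))
}

#' Predict the future center-line coordinate of a point of interest
#'
#' Assuming body segments follow their predecessors along the current shape
#' at speed v, a POI now at coordinate s will be located, `delta_k` frames
#' ahead, at the position of coordinate s_c = s - v * delta_k on the current
#' center line. Predictions past the head are clamped to the topmost point
#' s = 0; predictions past the tail (backward motion) are clamped to 1 and
#' flagged.
#'
#' @param skel current `skeleton`
#' @param s POI coordinate in `[0, 1]`
#' @param v worm speed in s-units per frame (>= 0)
#' @param delta_k prediction horizon in frames (>= 0)
#' @return `poi_prediction`: list with `s`, `s_c`, `delta_k`, `position`
#'   (1 x 2 um on the current skeleton), `clamped`
#' @export
predict_poi <- function(skel, s, v, delta_k) {
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  stopifnot(v >= 0, delta_k >= 0)
  s_c <- s - v * delta_k
  clamped <- s_c < 0 || s_c > 1
  s_c <- clamp(s_c, 0, 1)
  structure(list(s = s, s_c = s_c, delta_k = delta_k,
                 position = locate_poi(skel, s_c), clamped = clamped),
            class = "poi_prediction")
}

#' @export
print.poi_prediction <- function(x, ...) {
  cat(sprintf("<poi_prediction> s = %.3f -> s_c = %.3f (dk = %d)%s\n",
              x$s, x$s_c, x$delta_k, if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' Score POI predictions against the ground truth
#'
#' For every frame k whose horizon target k + delta_k lies inside the video,
#' the POI position predicted from the detected track at k is compared with
#' the true (ground-truth pose) position of the same material coordinate at
#' k + delta_k; the Euclidean distances and their mean (the mean prediction
#' error) are reported in micrometres.
#'
#' @param dataset a `video_dataset` (ground truth)
#' @param track the matching `worm_track`
#' @param s POI coordinate in `[0, 1]`
#' @param delta_k prediction horizon in frames (>= 1)
#' @return `prediction_error_report`: data.frame (frame, distance_um) with
#'   attribute `mean_prediction_error`
#' @export
evaluate_prediction <- function(dataset, track, s, delta_k) {
  n <- length(dataset$poses)
  if (delta_k >= n) stop("video shorter than the prediction horizon")
  rows <- list()
  for (k in seq_len(n - delta_k)) {
    st <- track$frames[[k]]
    if (!isTRUE(st$present)) next
    pred <- predict_poi(st$skel, s, st$v, delta_k)
    tru <- pose_point(dataset$poses[[k + delta_k]], s)
    rows[[length(rows) + 1]] <- data.frame(
      frame = k - 1L,
      distance_um = sqrt(sum((pred$position - tru)^2)))
  }
  if (length(rows) == 0) stop("no frames with a detected worm to evaluate")
  df <- do.call(rbind, rows)
  structure(df, class = c("prediction_error_report", "data.frame"),
            mean_prediction_error = mean(df$distance_um),
            s = s, delta_k = delta_k)
}

#' @export
print.prediction_error_report <- function(x, ...) {
  cat(sprintf(
    "<prediction_error_report> s = %.2f, dk = %d: mean error %.1f um over %d frames\n",
    attr(x, "s"), attr(x, "delta_k"), attr(x, "mean_prediction_error"),
    nrow(x)))
  invisible(x)
}
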