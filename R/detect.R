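# Worm detection: preprocessing, background estimation, segmentation,
# center-of-gravity tracking, head detection, skeletonization and the
# normalized center-line coordinate s (head = 0, tail = 1).

#' Downsample a raw frame by block averaging
#'
#' Grayscale preprocessing of the detection chain: resolution decreased by a
#' fixed factor (default 9); each output pixel is the mean of its source
#' block, edge blocks being partial. Intensity range `[0, 1]` is preserved.
#' @param raw frame matrix
#' @param factor integer downsampling factor
#' @return `preprocessed_frame`: matrix with attribute `scale_factor`
#' @export
preprocess <- function(raw, factor = 9L) {
  if (nrow(raw) < factor || ncol(raw) < factor)
    stop("frame smaller than the downsampling block")
  raw <- unclass(raw)
  grp_r <- ceiling(seq_len(nrow(raw)) / factor)
  cnt_r <- tabulate(grp_r)
  tmp <- rowsum(raw, grp_r) / cnt_r
  grp_c <- ceiling(seq_len(ncol(raw)) / factor)
  cnt_c <- tabulate(grp_c)
  out <- t(rowsum(t(tmp), grp_c) / cnt_c)
  dimnames(out) <- NULL
  attr(out, "scale_factor") <- as.integer(factor)
  out
}

#' Temporal background estimation
#'
#' Static-background estimate over a sequence of (preprocessed) frames.
#' `method = "median"` is the per-pixel temporal median, exact wherever the
#' worm covers a pixel in fewer than half of the frames. A worm crawling at
#' ~0.11 body lengths per second retraces its own track and can cover
#' mid-track pixels in well over half of a 10 s video, so the default is an
#' upper temporal quantile (the worm is darker than the background), followed
#' by one refinement pass that re-averages each pixel over only the frames
#' where it is not covered by the provisionally segmented worm.
#'
#' @param frames list of equally sized matrices (>= 3)
#' @param method "quantile" (default) or "median"
#' @param prob quantile used by the default method
#' @param refine run the masked re-averaging pass (default TRUE)
#' @return background matrix
#' @note Any temporal estimator needs each pixel to be worm-free in part of
#'   the video. A pixel stays covered for up to body_length / speed seconds
#'   (about 9 s at the default kinematics), so videos much shorter than
#'   that leave permanently covered pixels whose background is unknowable.
#' @export
estimate_background <- function(frames, method = c("quantile", "median"),
                                prob = 0.975, refine = TRUE) {
  method <- match.arg(method)
  if (length(frames) < 3) stop("need at least 3 frames to estimate background")
  arr <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
  if (method == "median") return(apply(arr, c(1, 2), median))
  bg <- apply(arr, c(1, 2), stats::quantile, probs = prob, names = FALSE)
  if (!refine) return(bg)
  # refinement: average per pixel over frames where the worm is absent
  br <- EBImage::makeBrush(5, "disc")
  acc <- matrix(0, nrow(bg), ncol(bg))
  cnt <- matrix(0, nrow(bg), ncol(bg))
  for (i in seq_along(frames)) {
    d <- abs(unclass(frames[[i]]) - bg)
    th <- EBImage::otsu(EBImage::Image(d), range = c(0, max(max(d), 1e-6)))
    if (th >= max(0.02, 5 * median(d))) {
      cov <- EBImage::dilate(EBImage::Image(d > 0.5 * th), br) > 0.5
      free <- !matrix(cov, nrow(bg))
    } else {
      free <- matrix(TRUE, nrow(bg), ncol(bg))  # no credible worm: all free
    }
    acc[free] <- acc[free] + frames[[i]][free]
    cnt[free] <- cnt[free] + 1
  }
  ok <- cnt > 0
  bg[ok] <- acc[ok] / cnt[ok]
  bg
}

#' Segment the worm in one preprocessed frame
#'
#' Otsu threshold on the absolute background-difference image with a
#' hysteresis extension: the largest strongly thresholded component is grown
#' into the weakly thresholded mask (fraction `weak` of the Otsu level),
#' which recovers the thin tapered tail whose per-pixel contrast drops below
#' the global threshold. Holes are filled. Signals worm-absent when the
#' component is smaller than `min_area` pixels.
#' @param frame preprocessed frame
#' @param bg background from [estimate_background]
#' @param min_area minimum component area (downsampled pixels); default is
#'   about a quarter of the expected worm area of the default optics
#' @param weak weak-threshold fraction of the Otsu level for the hysteresis
#'   growth step
#' @param min_contrast minimum Otsu level (in difference-image intensity)
#'   for a credible worm; on a worm-free frame the threshold sits inside
#'   the noise distribution and fails this gate
#' @return `worm_mask`: list with logical `mask`, `present`, `area`
#' @export
segment_worm <- function(frame, bg, min_area = 30, weak = 0.4,
                         min_contrast = 0.02) {
  if (!all(dim(frame) == dim(bg))) stop("frame/background shape mismatch")
  d <- abs(unclass(frame) - bg)
  th <- EBImage::otsu(EBImage::Image(d), range = c(0, max(max(d), 1e-6)))
  if (th < max(min_contrast, 5 * median(d)))
    return(structure(list(mask = matrix(FALSE, nrow(d), ncol(d)),
                          present = FALSE, area = 0L),
                     class = "worm_mask"))
  m <- d > th
  lab <- EBImage::bwlabel(m)
  if (max(lab) == 0)
    return(structure(list(mask = m & FALSE, present = FALSE, area = 0L),
                     class = "worm_mask"))
  areas <- tabulate(lab[lab > 0])
  big <- which.max(areas)
  strong <- matrix(lab == big, nrow(d))
  wlab <- EBImage::bwlabel(d > weak * th)
  keep <- unique(wlab[strong])
  keep <- keep[keep > 0]
  m <- matrix(wlab %in% keep, nrow(d))
  m <- EBImage::fillHull(EBImage::Image(m)) > 0.5
  m <- matrix(m, nrow(d))
  structure(list(mask = m, present = sum(m) >= min_area,
                 area = as.integer(sum(m))),
            class = "worm_mask")
}

#' Smoothed center of gravity of the segmented worm
#'
#' Raw COG is the mean of foreground pixel-center coordinates; smoothing is
#' first-order (exponential) over time: alpha * raw + (1 - alpha) * previous.
#' @param mask a `worm_mask` (or logical matrix)
#' @param prev previous smoothed COG (length-2, same units) or NULL
#' @param alpha smoothing weight in `(0, 1]`; 1 disables smoothing
#' @param dsf micrometres per downsampled pixel (9 * pixel_size); COG is
#'   returned in micrometres as (x, y)
#' @return length-2 numeric (x_um, y_um)
#' @export
compute_cog <- function(mask, prev = NULL, alpha = 0.5, dsf = 27) {
  m <- if (inherits(mask, "worm_mask")) mask$mask else mask
  if (!any(m)) stop("empty mask")
  ij <- which(m, arr.ind = TRUE)
  raw <- c((mean(ij[, 2]) - 0.5) * dsf, (mean(ij[, 1]) - 0.5) * dsf)
  if (is.null(prev)) raw else alpha * raw + (1 - alpha) * prev
}

#' Choose the head endpoint from accumulated difference images
#'
#' The head region moves at much higher frequency than the rest of the body,
#' so the skeleton endpoint whose neighbourhood accumulates more absolute
#' inter-frame difference over the recent window is the head. When the two
#' endpoint scores differ by less than 10% the choice is low-confidence and
#' falls back to the endpoint nearest the previous head.
#'
#' @param window list of the last (up to 10) preprocessed frames, oldest
#'   first (>= 2)
#' @param endpoints 2 x 2 matrix of endpoint (row, col) 1-based pixel indices
#' @param prev_head previous head (row, col) or NULL
#' @param radius neighbourhood radius in downsampled pixels
#' @return list with `index` (1 or 2: which endpoint is the head),
#'   `confident`, `scores`
#' @export
detect_head <- function(window, endpoints, prev_head = NULL, radius = 4) {
  if (length(window) < 2) stop("need at least 2 frames of history")
  D <- Reduce(`+`, lapply(seq_len(length(window) - 1), function(i) {
    abs(unclass(window[[i + 1]]) - unclass(window[[i]]))
  }))
  nr <- nrow(D); nc <- ncol(D)
  score <- function(pt) {
    rr <- max(1, pt[1] - radius):min(nr, pt[1] + radius)
    cc <- max(1, pt[2] - radius):min(nc, pt[2] + radius)
    sum(D[rr, cc])
  }
  s1 <- score(endpoints[1, ]); s2 <- score(endpoints[2, ])
  confident <- abs(s1 - s2) >= 0.1 * max(s1, s2, 1e-12)
  if (!confident && !is.null(prev_head)) {
    d1 <- sum((endpoints[1, ] - prev_head)^2)
    d2 <- sum((endpoints[2, ] - prev_head)^2)
    idx <- if (d1 <= d2) 1L else 2L
  } else {
    idx <- if (s1 >= s2) 1L else 2L
  }
  list(index = idx, confident = confident, scores = c(s1, s2))
}

# Extend both path ends along their local direction until leaving the mask
# (sampled at sub-pixel steps; extension capped at 3 pixels per end).
extend_to_mask <- function(xy, mask, dsf, cap_px = 3) {
  mnum <- matrix(as.numeric(mask), nrow(mask))
  step <- 0.25 * dsf
  ext_end <- function(p_end, p_in) {
    d <- p_end - p_in
    nd <- sqrt(sum(d^2))
    if (nd == 0) return(NULL)
    d <- d / nd
    best <- NULL
    for (k in seq_len(ceiling(cap_px * dsf / step))) {
      q <- p_end + d * step * k
      r <- q[2] / dsf + 0.5; c <- q[1] / dsf + 0.5
      v <- bilinear_sample(mnum, r, c, fill = 0)[1, 1]
      if (v < 0.5) break
      best <- q
    }
    best
  }
  n <- nrow(xy)
  a <- ext_end(xy[1, ], xy[min(4, n), ])
  b <- ext_end(xy[n, ], xy[max(1, n - 3), ])
  if (!is.null(a)) xy <- rbind(a, xy)
  if (!is.null(b)) xy <- rbind(xy, b)
  dimnames(xy) <- NULL
  xy
}

#' Skeletonize a worm mask into an ordered center-line path
#'
#' Morphological thinning to a one-pixel 8-connected skeleton, longest
#' geodesic path extraction (which drops side spurs), ordering from the
#' endpoint nearest the head, and the normalized coordinate
#' s = cumulative arc length / total arc length. Path coordinates are
#' lightly smoothed (moving average, interior nodes) to suppress pixel-grid
#' quantization before measuring arc length.
#'
#' @param mask a `worm_mask` or logical matrix
#' @param head head position as (row, col) 1-based pixel index, or NULL to
#'   leave the orientation arbitrary
#' @param dsf micrometres per downsampled pixel
#' @param smooth half-window of the coordinate moving average (0 = off)
#' @return `skeleton`: list with `path` (n x 2 um, head first), `pixels`
#'   (n x 2 row/col), `s`, `arclen` (um), `length_um`
#' @export
skeletonize <- function(mask, head = NULL, dsf = 27, smooth = 2L) {
  m <- if (inherits(mask, "worm_mask")) mask$mask else mask
  if (!any(m)) stop("empty mask")
  # crop to bounding box for speed
  ij <- which(m, arr.ind = TRUE)
  r0 <- max(1, min(ij[, 1]) - 1); r1 <- min(nrow(m), max(ij[, 1]) + 1)
  c0 <- max(1, min(ij[, 2]) - 1); c1 <- min(ncol(m), max(ij[, 2]) + 1)
  sub <- m[r0:r1, c0:c1, drop = FALSE]
  sk <- thin_mask(sub)
  px <- skeleton_path(sk)
  if (is.null(px) || nrow(px) < 3) stop("degenerate skeleton")
  # sanity: longest path must dominate the expected length from the mask
  dt <- EBImage::distmap(EBImage::Image(sub))
  exp_len <- sum(sub) / max(2 * mean(dt[sub]), 1)
  if (nrow(px) < 0.5 * exp_len)
    stop("skeleton irreducibly branched: longest path below half the expected length")
  px[, 1] <- px[, 1] + r0 - 1L
  px[, 2] <- px[, 2] + c0 - 1L
  if (!is.null(head)) {
    d_first <- sum((px[1, ] - head)^2)
    d_last <- sum((px[nrow(px), ] - head)^2)
    if (d_last < d_first) px <- px[nrow(px):1, , drop = FALSE]
  }
  # world coordinates (x = col, y = row), micrometres
  xy <- cbind((px[, 2] - 0.5) * dsf, (px[, 1] - 0.5) * dsf)
  if (smooth > 0 && nrow(xy) > 2 * smooth + 2) {
    k <- 2L * smooth + 1L
    sm <- apply(xy, 2, function(v) stats::filter(v, rep(1 / k, k), sides = 2))
    keep <- !is.na(sm[, 1])
    xy[keep, ] <- sm[keep, ]
  }
  # thinning retracts the path from the tips by about the local half-width;
  # extend both ends along the end direction until the mask boundary
  xy <- extend_to_mask(xy, m, dsf)
  cum <- cum_arclength(xy)
  L <- cum[length(cum)]
  structure(list(path = xy, pixels = px, s = cum / L,
                 arclen = cum, length_um = L),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d nodes, length %.1f um\n",
              nrow(x$path), x$length_um))
  invisible(x)
}

#' Position on a skeleton at normalized coordinate s
#' @param skel a `skeleton`
#' @param s coordinate(s) in `[0, 1]` (head = 0, tail = 1)
#' @return length(s) x 2 matrix of (x, y) micrometres
#' @export
locate_poi <- function(skel, s) {
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
  interp_polyline(skel$path, skel$arclen, s * skel$length_um)
}

#' Local frame of a skeleton at coordinate s
#' @inheritParams locate_poi
#' @return list with `point`, `tangent` (unit, head to tail), `normal`
#' @export
skeleton_frame <- function(skel, s) {
  p <- interp_polyline(skel$path, skel$arclen, s * skel$length_um)
  tg <- polyline_tangent(skel$path, skel$arclen, s * skel$length_um,
                         h = max(skel$length_um / 50, 1))
  list(point = p, tangent = tg, normal = rot90cw(tg))
}

#' Sub-pixel refinement of a center line against the raw frame
#'
#' The skeleton from the downsampled mask carries pixel-grid noise of a few
#' micrometres. Each node is shifted along its local normal to the
#' darkness-weighted centroid of the raw-resolution intensity profile
#' (background minus intensity, measured across the body), which recovers
#' the center line to roughly raw-pixel accuracy. Shifts are capped at half
#' a downsampled pixel; the path is then lightly smoothed and its arc length
#' recomputed.
#'
#' @param skel a `skeleton` (path in micrometres)
#' @param raw raw frame matrix
#' @param pixel_size micrometres per raw pixel
#' @param halfspan_um profile half-length across the body in micrometres
#' @param bg_level background intensity (default: median of the frame)
#' @return the refined `skeleton`
#' @export
refine_centerline <- function(skel, raw, pixel_size, halfspan_um = 60,
                              bg_level = NULL) {
  raw <- unclass(raw)
  if (is.null(bg_level)) bg_level <- median(raw)
  n <- nrow(skel$path)
  tg <- polyline_tangent(skel$path, skel$arclen, skel$arclen,
                         h = max(skel$length_um / 60, 1))
  nrm <- rot90cw(tg)
  steps <- seq(-halfspan_um, halfspan_um, by = pixel_size / 2)
  m <- length(steps)
  px <- rep(skel$path[, 1], each = m) + rep(nrm[, 1], each = m) * steps
  py <- rep(skel$path[, 2], each = m) + rep(nrm[, 2], each = m) * steps
  val <- bilinear_points(raw, py / pixel_size + 0.5, px / pixel_size + 0.5,
                         fill = bg_level)
  w <- matrix(pmax(bg_level - val, 0), m, n)
  w <- w^2   # emphasise the dark core
  tot <- colSums(w)
  shift <- ifelse(tot > 0, colSums(w * steps) / pmax(tot, 1e-12), 0)
  cap <- 0.6 * max(pixel_size * 9 / 2, 1)
  shift <- clamp(shift, -cap, cap)
  skel$path <- skel$path + nrm * shift
  k <- 3L
  sm <- apply(skel$path, 2, function(v) stats::filter(v, rep(1 / k, k), sides = 2))
  keep <- !is.na(sm[, 1])
  skel$path[keep, ] <- sm[keep, ]
  skel$arclen <- cum_arclength(skel$path)
  skel$length_um <- max(skel$arclen)
  skel$s <- skel$arclen / skel$length_um
  skel
}

#' Worm speed in normalized s-units per frame
#'
#' Derived from the COG displacement and the current body shape: for an
#' inextensible body whose segments follow their predecessors along the
#' center line at sliding speed V, the COG velocity equals (V / L) times the
#' head-to-tail chord vector. The per-frame COG displacement (least-squares
#' slope over the last up to 5 smoothed positions) is therefore projected on
#' the chord and scaled by L / |chord|, which is exact for both sliding and
#' pure translation and well-conditioned for bent postures. The result is
#' normalized by the skeleton length L, matching the units of the coordinate
#' prediction s_c = s - v * dk; apparent backward motion is clamped to 0.
#'
#' @param cog_history matrix of smoothed COG positions (um), one row per
#'   frame, most recent last; up to the last 5 rows are used
#' @param skel current `skeleton`
#' @return v in s-units per frame (>= 0)
#' @export
estimate_velocity <- function(cog_history, skel) {
  m <- nrow(cog_history)
  if (is.null(m) || m < 2) return(0)
  use <- cog_history[max(1, m - 4):m, , drop = FALSE]
  k <- seq_len(nrow(use)) - mean(seq_len(nrow(use)))
  disp <- c(sum(k * use[, 1]), sum(k * use[, 2])) / sum(k^2)
  u <- skel$path[1, ] - skel$path[nrow(skel$path), ]  # head - tail chord
  max(0, sum(disp * u) / sum(u^2))
}

#' Track a worm through a whole video
#'
#' Runs the full detection chain on every frame: block-mean downsampling,
#' temporal-median background, difference-image segmentation, thinning to an
#' ordered center line, difference-mass head detection, smoothed COG and the
#' normalized-speed estimate used by the coordinate predictor.
#'
#' @param dataset a `video_dataset` (or list with `frames` and `optics`)
#' @param factor downsampling factor
#' @param alpha COG smoothing weight
#' @param min_area worm-present area gate (downsampled pixels)
#' @param head_window number of recent frames for the head difference images
#' @param v_alpha exponential smoothing weight of the speed estimate over
#'   time (the instantaneous COG speed genuinely oscillates with the
#'   undulation cycle; the predictor wants the mean sliding speed)
#' @param refine run the raw-resolution sub-pixel center-line refinement
#'   ([refine_centerline]) on every frame
#' @return `worm_track`: per-frame list `frames` (each with `skel`, `cog`,
#'   `head_um`, `v`, `present`, `head_confident`, and `carried` = TRUE on
#'   frames whose state was carried over a transient detection dropout)
#'   plus `summary` data.frame
#' @export
track_video <- function(dataset, factor = 9L, alpha = 0.5, min_area = 30,
                        head_window = 10L, v_alpha = 0.2, refine = TRUE) {
  frames <- dataset$frames
  if (is.null(frames)) stop("dataset has no rendered frames")
  ps <- dataset$optics$pixel_size
  dsf <- factor * ps
  pre <- lapply(frames, preprocess, factor = factor)
  bg <- estimate_background(pre)
  bg_raw <- median(unclass(frames[[1]]))
  n <- length(pre)
  out <- vector("list", n)
  cog_hist <- matrix(NA_real_, 0, 2)
  prev_cog <- NULL
  prev_head_px <- NULL
  prev_v <- NULL
  carried <- 0L
  for (i in seq_len(n)) {
    wm <- segment_worm(pre[[i]], bg, min_area = min_area)
    sk0 <- NULL
    if (wm$present)
      sk0 <- tryCatch(skeletonize(wm, head = prev_head_px, dsf = dsf),
                      error = function(e) NULL)
    if (is.null(sk0)) {
      # transient dropout (e.g. a self-touching posture whose mask loops):
      # carry the previous state for up to 3 frames, flagged
      prev_ok <- i > 1 && isTRUE(out[[i - 1]]$present)
      if (prev_ok && carried < 3L) {
        out[[i]] <- out[[i - 1]]
        out[[i]]$carried <- TRUE
        carried <- carried + 1L
      } else {
        out[[i]] <- list(present = FALSE)
      }
      next
    }
    carried <- 0L
    ends <- sk0$pixels[c(1, nrow(sk0$pixels)), , drop = FALSE]
    win <- pre[max(1, i - head_window + 1):i]
    hd <- if (length(win) >= 2) {
      detect_head(win, ends, prev_head = prev_head_px)
    } else list(index = 1L, confident = FALSE)
    skel <- sk0
    if (hd$index == 2L) {
      skel$path <- skel$path[nrow(skel$path):1, , drop = FALSE]
      skel$pixels <- skel$pixels[nrow(skel$pixels):1, , drop = FALSE]
      skel$arclen <- cum_arclength(skel$path)
      skel$s <- skel$arclen / skel$length_um
    }
    if (refine)
      skel <- refine_centerline(skel, frames[[i]], ps,
                                bg_level = bg_raw)
    prev_head_px <- skel$pixels[1, ]
    cog <- compute_cog(wm, prev = prev_cog, alpha = alpha, dsf = dsf)
    prev_cog <- cog
    cog_hist <- rbind(cog_hist, cog)
    v_raw <- estimate_velocity(cog_hist, skel)
    v <- if (is.null(prev_v)) v_raw else v_alpha * v_raw + (1 - v_alpha) * prev_v
    prev_v <- v
    out[[i]] <- list(present = TRUE, skel = skel, cog = cog,
                     head_um = skel$path[1, ], v = v, v_raw = v_raw,
                     head_confident = isTRUE(hd$confident))
  }
  summ <- do.call(rbind, lapply(seq_len(n), function(i) {
    o <- out[[i]]
    if (!isTRUE(o$present))
      return(data.frame(frame = i - 1L, present = FALSE, cog_x = NA, cog_y = NA,
                        head_x = NA, head_y = NA, v = NA, skel_length_um = NA))
    data.frame(frame = i - 1L, present = TRUE,
               cog_x = o$cog[1], cog_y = o$cog[2],
               head_x = o$head_um[1], head_y = o$head_um[2],
               v = o$v, skel_length_um = o$skel$length_um)
  }))
  structure(list(frames = out, summary = summ, dsf = dsf,
                 alpha = alpha, factor = factor),
            class = "worm_track")
}

#' @export
print.worm_track <- function(x, ...) {
  ok <- sum(x$summary$present)
  cat(sprintf("<worm_track> %d frames (%d with worm), mean v = %.5f s/frame\n",
              nrow(x$summary), ok, mean(x$summary$v, na.rm = TRUE)))
  invisible(x)
}
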