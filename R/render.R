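#' Optics of the synthetic recording
#'
#' @param pixel_size micrometres per raw pixel (default 3, so a 1.2 mm worm
#'   spans ~400 pixels)
#' @param nrow,ncol image size in pixels
#' @param bg_level mean background intensity
#' @param bg_contrast amplitude of the static smooth background texture
#' @param worm_depth how much darker than the background the worm body is
#' @param noise_sd standard deviation of the per-frame additive noise
#' @param edge_um width (um) of the soft intensity edge of the worm tube
#' @return object of class `worm_optics`
#' @export
worm_optics <- function(pixel_size = 3, nrow = 384, ncol = 1024,
                        bg_level = 0.85, bg_contrast = 0.04,
                        worm_depth = 0.55, noise_sd = 0.02,
                        edge_um = 6) {
  stopifnot(pixel_size > 0, nrow >= 9, ncol >= 9)
  structure(list(pixel_size = pixel_size, nrow = as.integer(nrow),
                 ncol = as.integer(ncol), bg_level = bg_level,
                 bg_contrast = bg_contrast, worm_depth = worm_depth,
                 noise_sd = noise_sd, edge_um = edge_um),
            class = "worm_optics")
}

#' Static background texture of one video
#'
#' Smooth random field: a coarse seeded grid upsampled bilinearly, shared by
#' all frames of a video (fixed camera, constant illumination).
#' @param optics a [worm_optics]
#' @param seed integer seed
#' @return nrow x ncol matrix in `[0, 1]`
#' @export
render_background <- function(optics, seed = 1L) {
  set.seed(substream(seed, 3L))
  gh <- max(2L, ceiling(optics$nrow / 64)); gw <- max(2L, ceiling(optics$ncol / 64))
  g <- matrix(rnorm((gh + 1) * (gw + 1)), gh + 1, gw + 1)
  rpos <- (seq_len(optics$nrow) - 0.5) / 64 + 0.5
  cpos <- (seq_len(optics$ncol) - 0.5) / 64 + 0.5
  tex <- bilinear_sample(g, rpos, cpos, fill = 0)
  clamp(optics$bg_level + optics$bg_contrast * tex / max(abs(tex), 1e-9), 0, 1)
}

#' Render one video frame from a ground-truth pose
#'
#' Draws the worm as a dark tube of the pose's half-width profile around the
#' centerline on a bright static background, with a soft edge and optional
#' per-frame additive Gaussian noise. World-to-pixel mapping: pixel (r, c)
#' (0-based) center sits at ((c + 0.5), (r + 0.5)) * pixel_size micrometres.
#'
#' @param pose a `centerline_pose` (an empty pose with 0 points renders the
#'   bare background)
#' @param optics a [worm_optics]
#' @param background static background matrix from [render_background]
#' @param noise_seed seed for the per-frame noise (NULL with noise_sd = 0
#'   gives a deterministic noiseless frame)
#' @return `frame_image`: matrix in `[0, 1]` with attribute `pixel_size`
#' @export
render_frame <- function(pose, optics, background = NULL, noise_seed = NULL) {
  if (is.null(background)) background <- render_background(optics)
  ps <- optics$pixel_size
  img <- background
  npts <- if (is.null(pose$points)) 0L else nrow(pose$points)
  if (npts > 0) {
    px_c <- pose$points[, 1] / ps - 0.5   # 0-based pixel coords
    px_r <- pose$points[, 2] / ps - 0.5
    if (any(px_r < 0 | px_r > optics$nrow - 1 | px_c < 0 | px_c > optics$ncol - 1))
      stop("centerline maps outside the image bounds; enlarge the field of view")
    # resample centerline densely and stamp a min-distance field locally
    cum <- pose$arclen
    at <- seq(0, max(cum), by = ps)
    samp <- interp_polyline(pose$points, cum, at)
    wid <- stats::approx(cum, pose$width, xout = at)$y
    rmax_px <- ceiling((max(wid) + optics$edge_um) / ps) + 1L
    dmin <- matrix(Inf, optics$nrow, optics$ncol)
    wnear <- matrix(0, optics$nrow, optics$ncol)
    for (i in seq_along(at)) {
      cr <- samp[i, 2] / ps - 0.5; cc <- samp[i, 1] / ps - 0.5
      r0 <- max(0L, floor(cr - rmax_px)); r1 <- min(optics$nrow - 1L, ceiling(cr + rmax_px))
      c0 <- max(0L, floor(cc - rmax_px)); c1 <- min(optics$ncol - 1L, ceiling(cc + rmax_px))
      rr <- r0:r1; cc2 <- c0:c1
      dd <- outer((rr - cr)^2, (cc2 - cc)^2, `+`)
      sub <- dmin[rr + 1L, cc2 + 1L, drop = FALSE]
      upd <- dd < sub
      if (any(upd)) {
        sub[upd] <- dd[upd]
        dmin[rr + 1L, cc2 + 1L] <- sub
        wsub <- wnear[rr + 1L, cc2 + 1L, drop = FALSE]
        wsub[upd] <- wid[i]
        wnear[rr + 1L, cc2 + 1L] <- wsub
      }
    }
    # soft tube profile in distance units of um
    act <- is.finite(dmin)
    d_um <- sqrt(dmin[act]) * ps
    prof <- clamp((wnear[act] + optics$edge_um / 2 - d_um) / optics$edge_um, 0, 1)
    img[act] <- img[act] - optics$worm_depth * prof
  }
  if (optics$noise_sd > 0) {
    if (!is.null(noise_seed)) set.seed(noise_seed)
    img <- img + matrix(rnorm(length(img), 0, optics$noise_sd),
                        nrow(img), ncol(img))
  }
  img <- clamp(img, 0, 1)
  attr(img, "pixel_size") <- ps
  class(img) <- c("frame_image", class(img))
  img
}

#' Rasterize the ground-truth worm tube on the downsampled detection grid
#'
#' Oracle mask for segmentation scoring: a downsampled pixel belongs to the
#' tube when its center lies within the local half-width of the centerline.
#' @param pose a `centerline_pose`
#' @param optics a [worm_optics]
#' @param factor downsampling factor of the detection grid
#' @return logical matrix of the downsampled frame size
#' @export
rasterize_tube <- function(pose, optics, factor = 9) {
  dsf <- factor * optics$pixel_size
  nr <- ceiling(optics$nrow / factor); nc <- ceiling(optics$ncol / factor)
  qx <- (seq_len(nc) - 0.5) * dsf
  qy <- (seq_len(nr) - 0.5) * dsf
  # restrict to bounding box around the worm
  hw <- max(pose$width)
  xr <- range(pose$points[, 1]); yr <- range(pose$points[, 2])
  ci <- which(qx >= xr[1] - hw - dsf & qx <= xr[2] + hw + dsf)
  ri <- which(qy >= yr[1] - hw - dsf & qy <= yr[2] + hw + dsf)
  mask <- matrix(FALSE, nr, nc)
  if (length(ri) == 0 || length(ci) == 0) return(mask)
  q <- cbind(rep(qx[ci], each = length(ri)), rep(qy[ri], times = length(ci)))
  pr <- project_polyline(q, pose$points, pose$arclen)
  wat <- stats::approx(pose$arclen, pose$width, xout = clamp(pr$arc, 0, max(pose$arclen)))$y
  inside <- !pr$beyond & abs(pr$offset) <= wat
  mask[ri, ci] <- matrix(inside, length(ri), length(ci))
  mask
}
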