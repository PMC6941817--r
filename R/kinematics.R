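#' Kinematic parameters of a synthetic crawling worm
#'
#' Bundles every ground-truth parameter of the synthetic video generator.
#' Defaults describe a wild-type adult C. elegans crawling on agar: body
#' length 1.2 mm, forward speed ~0.13 mm/s, recorded at 12 Hz for 10 s.
#' The locomotion model is a laterally undulating body sliding along its own
#' track (each segment follows its predecessor), with an optional wave-slip
#' frequency, slow random heading drift of the track, and independent
#' high-frequency jitter of the head region.
#'
#' @param body_length body length in micrometres
#' @param speed forward (arc-length) speed in micrometres per second
#' @param undulation_amplitude lateral wave amplitude in micrometres
#' @param undulation_wavelength wavelength of the undulation along the body
#'   axis in micrometres
#' @param undulation_frequency wave slip frequency in Hz relative to perfect
#'   ground tracking. At 0 the undulation wave is stationary in the lab frame
#'   and the body slides along it exactly (ideal crawling on agar); the
#'   default 0.01 Hz adds the slow lateral wave creep seen in real recordings,
#'   so the worm does not perfectly retrace its own track
#' @param head_jitter_std standard deviation, in radians per frame, of the
#'   random rigid rotation applied to the anterior 10% of the body about the
#'   s = 0.1 point (models head foraging movements)
#' @param frame_rate video sampling rate in Hz
#' @param duration video duration in seconds
#' @param heading_drift_std standard deviation of the track heading change,
#'   in radians per frame of forward travel
#' @param half_width maximal body half-width in micrometres (width profile
#'   tapers towards head and tail)
#' @param n_points number of centerline points per pose (uniform in arc length)
#' @param seed integer seed; the full dataset is reproducible from it
#' @return object of class `worm_kinematics`
#' @export
#' @examples
#' kin <- worm_kinematics(seed = 1)
#' kin$n_frames  # 120 frames = 12 Hz x 10 s
worm_kinematics <- function(body_length = 1200, speed = 130,
                            undulation_amplitude = 120,
                            undulation_wavelength = 800,
                            undulation_frequency = 0.01,
                            head_jitter_std = 0.25,
                            frame_rate = 12, duration = 10,
                            heading_drift_std = 0.02,
                            half_width = 45, n_points = 101,
                            seed = 1L) {
  stopifnot(body_length > 0, speed >= 0, frame_rate > 0, duration > 0,
            undulation_amplitude >= 0, undulation_wavelength > 0,
            head_jitter_std >= 0, heading_drift_std >= 0,
            half_width > 0, n_points >= 3)
  kin <- list(body_length = body_length, speed = speed,
              undulation_amplitude = undulation_amplitude,
              undulation_wavelength = undulation_wavelength,
              undulation_frequency = undulation_frequency,
              head_jitter_std = head_jitter_std,
              frame_rate = frame_rate, duration = duration,
              heading_drift_std = heading_drift_std,
              half_width = half_width, n_points = as.integer(n_points),
              seed = as.integer(seed),
              n_frames = as.integer(round(frame_rate * duration)))
  class(kin) <- "worm_kinematics"
  kin
}

#' @export
print.worm_kinematics <- function(x, ...) {
  cat("<worm_kinematics>",
      sprintf("  length %g um, speed %g um/s, %g Hz x %g s (%d frames)",
              x$body_length, x$speed, x$frame_rate, x$duration, x$n_frames),
      sprintf("  wave A = %g um, lambda = %g um, slip %g Hz",
              x$undulation_amplitude, x$undulation_wavelength,
              x$undulation_frequency),
      sprintf("  head jitter sd %g rad/frame, heading drift sd %g rad/frame, seed %d",
              x$head_jitter_std, x$heading_drift_std, x$seed),
      sep = "\n")
  invisible(x)
}

#' Body half-width profile
#'
#' Adult-like caliber: a blunt head ramp, near-constant mid-body diameter,
#' and a conical tail over the posterior quarter, evaluated at normalized
#' arc-length coordinates s (head = 0).
#' @keywords internal
width_profile <- function(s, half_width) {
  head_ramp <- tanh(s / 0.06)
  tail <- sqrt(pmax(0, 1 - (pmax(s - 0.75, 0) / 0.25)^2))
  half_width * pmax(head_ramp * tail, 0.08)
}

# Static decorated track the worm slides along, plus per-frame random draws.
# Everything is a deterministic function of the seed; poses for any frame can
# be re-generated independently.
worm_path <- function(kin) {
  L <- kin$body_length
  travel <- kin$speed * kin$duration
  umax <- L + travel + 200
  du <- 2
  # heading of the track: random walk in curvature, drawn per step of
  # per-frame forward travel, interpolated onto the fine grid
  step_pf <- max(kin$speed / kin$frame_rate, 1)
  node_u <- seq(0, umax + 20, by = 10)
  set.seed(substream(kin$seed, 1L))
  dtheta <- rnorm(length(node_u), 0, kin$heading_drift_std * sqrt(10 / step_pf))
  theta_node <- cumsum(dtheta)
  phi0 <- runif(1, 0, 2 * pi)
  u <- seq(0, umax, by = du)
  theta <- stats::approx(node_u, theta_node, xout = u, rule = 2)$y
  hx <- cos(theta); hy <- sin(theta)
  bx <- cumsum(c(0, hx[-length(hx)])) * du
  by <- cumsum(c(0, hy[-length(hy)])) * du
  # per-frame head jitter angles, independent across frames
  set.seed(substream(kin$seed, 2L))
  jitter <- rnorm(kin$n_frames, 0, kin$head_jitter_std)
  list(u = u, bx = bx, by = by, theta = theta, phi0 = phi0,
       jitter = jitter, umax = umax)
}

# Decorate the axial track with the undulation wave at time t and return the
# fine curve with its cumulative arc length.
decorated_curve <- function(kin, path, t_s) {
  A <- kin$undulation_amplitude
  lam <- kin$undulation_wavelength
  ph <- 2 * pi * path$u / lam + path$phi0 +
    2 * pi * kin$undulation_frequency * t_s
  off <- A * sin(ph)
  nx <- -sin(path$theta); ny <- cos(path$theta)
  px <- path$bx + off * nx
  py <- path$by + off * ny
  pts <- cbind(px, py)
  list(pts = pts, cum = cum_arclength(pts))
}

#' Generate the ground-truth centerline pose for one frame
#'
#' The body occupies a fixed arc-length span of the decorated track; the head
#' advances along the track at the configured speed, so each body segment
#' follows its predecessor. Head jitter is applied as a rigid rotation of the
#' anterior 10% of the body about the s = 0.1 point, which preserves arc
#' length exactly.
#'
#' @param kin a [worm_kinematics] object
#' @param frame 0-based frame index
#' @param path optional cached path from repeated calls (internal)
#' @return object of class `centerline_pose`: `points` (n x 2, um,
#'   head first), `s` (normalized arc length), `width` (half-width per point,
#'   um), `arclen` (cumulative, um), `frame`
#' @export
generate_centerline <- function(kin, frame, path = NULL) {
  stopifnot(inherits(kin, "worm_kinematics"), frame >= 0)
  if (is.null(path)) path <- worm_path(kin)
  t_s <- frame / kin$frame_rate
  cur <- decorated_curve(kin, path, t_s)
  L <- kin$body_length
  a_head <- L + 50 + kin$speed * t_s
  svec <- seq(0, 1, length.out = kin$n_points)
  pts <- interp_polyline(cur$pts, cur$cum, a_head - svec * L)
  # rigid head rotation about the s = 0.1 pivot
  jmax <- 0.1
  jidx <- which(svec < jmax)
  ang <- if (frame + 1 <= length(path$jitter)) path$jitter[frame + 1] else 0
  if (length(jidx) > 0 && ang != 0) {
    piv <- interp_polyline(cur$pts, cur$cum, a_head - jmax * L)
    ca <- cos(ang); sa <- sin(ang)
    rel <- sweep(pts[jidx, , drop = FALSE], 2, as.numeric(piv))
    rot <- cbind(rel[, 1] * ca - rel[, 2] * sa,
                 rel[, 1] * sa + rel[, 2] * ca)
    pts[jidx, ] <- sweep(rot, 2, as.numeric(piv), `+`)
  }
  structure(list(frame = frame, points = pts, s = svec,
                 width = width_profile(svec, kin$half_width),
                 arclen = cum_arclength(pts)),
            class = "centerline_pose")
}

#' @export
print.centerline_pose <- function(x, ...) {
  cat(sprintf("<centerline_pose> frame %d, %d points, arc length %.1f um\n",
              x$frame, nrow(x$points), max(x$arclen)))
  invisible(x)
}

#' Interpolated position on a pose at normalized coordinate s
#' @param pose a `centerline_pose`
#' @param s normalized arc-length coordinate(s) in `[0, 1]`
#' @return length(s) x 2 matrix of positions in micrometres
#' @export
pose_point <- function(pose, s) {
  stopifnot(all(s >= 0 & s <= 1))
  L <- max(pose$arclen)
  interp_polyline(pose$points, pose$arclen, s * L)
}

#' Local frame (point, tangent, in-plane normal) of a pose at coordinate s
#' @inheritParams pose_point
#' @return list with `point` (1 x 2), `tangent` (unit, head to tail),
#'   `normal` (tangent rotated +90 degrees)
#' @export
pose_frame <- function(pose, s) {
  L <- max(pose$arclen)
  p <- interp_polyline(pose$points, pose$arclen, s * L)
  tg <- polyline_tangent(pose$points, pose$arclen, s * L)
  list(point = p, tangent = tg, normal = rot90cw(tg))
}

#' Cut a pose into cross-sectional slabs
#'
#' Slice centers sit at s = (k - 0.5) / n (cell-centered); each slice plane is
#' perpendicular to the local centerline tangent; the slab thickness is
#' body length / n (24 um for the default 1.2 mm worm cut into 50 slices).
#'
#' @param pose a `centerline_pose`
#' @param n_slices number of slabs
#' @param body_length nominal body length in um used for the slab thickness;
#'   defaults to the pose's measured arc length (within 1% of nominal)
#' @return data.frame with slice index, `s_center`, slice-center position
#'   (um), unit tangent and in-plane normal, and `thickness` (um)
#' @export
slice_worm <- function(pose, n_slices = 50, body_length = NULL) {
  stopifnot(n_slices >= 1)
  s_c <- (seq_len(n_slices) - 0.5) / n_slices
  L <- max(pose$arclen)
  Lnom <- if (is.null(body_length)) L else body_length
  p <- interp_polyline(pose$points, pose$arclen, s_c * L)
  tg <- polyline_tangent(pose$points, pose$arclen, s_c * L)
  nn <- rot90cw(tg)
  data.frame(slice = seq_len(n_slices), s_center = s_c,
             x = p[, 1], y = p[, 2],
             tx = tg[, 1], ty = tg[, 2], nx = nn[, 1], ny = nn[, 2],
             thickness = Lnom / n_slices)
}

#' Slab index containing a coordinate s (boundary belongs to the lower slab)
#' @keywords internal
slab_of <- function(s, n_slices = 50) {
  pmin(pmax(ceiling(s * n_slices), 1L), n_slices)
}

#' Snap a slice coordinate to the nearest slab center
#'
#' The imaged slice is always one of the n cross-sectional slabs, so a
#' requested coordinate selects the slab whose center (k - 0.5) / n is
#' nearest (ties towards the head). Returns the slab index.
#' @keywords internal
snap_slice <- function(s, n_slices = 50) {
  pmin(pmax(floor(s * n_slices + 0.5), 1L), n_slices)
}
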