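# Gradient-echo Cartesian acquisition simulator. One k-space line is encoded
# per repetition time TR from the instantaneous field-of-view image; the
# gradient center either follows the coordinate predictor, stays fixed, or
# follows the ground-truth pose. Encoding physics is reduced to the Fourier
# sampling contract: no relaxation, uniform coil sensitivity, and worm motion
# within a single line is ignored (very-short-echo assumption).

#' Acquisition parameters of the gradient-echo sequence
#'
#' @param TR repetition time in ms (83 ms matches the 12 Hz video frame
#'   interval; one k-space line is acquired per frame)
#' @param TE echo time in ms
#' @param n_lines number of phase-encode lines N
#' @param n_readout readout samples per line M
#' @param horizon prediction horizon in frames (1..10 in prediction mode)
#' @param slice_step slice increment for multi-slice sweeps (normalized s)
#' @param mode gradient-center policy: `"prediction"` (follow the coordinate
#'   predictor), `"no_prediction"` (fixed at the slice position of a
#'   reference frame), `"oracle"` (follow the ground-truth pose), `"static"`
#'   (worm frozen at the start frame)
#' @param resolution_ratio MR:optical pixel ratio r (one optical pixel
#'   corresponding to r MR voxels, so the MR voxel size is the raw optical
#'   pixel size divided by r), used by the resolution paradigm. The default
#'   NULL keeps the MR voxel at the phantom's in-plane resolution (1.6 um)
#'   independently of the optics
#' @param start_frame 1-based index of the frame at which line 1 is acquired
#'   (late enough that the tracker history is warmed up)
#' @param voxel_um explicit MR voxel size in micrometres (overrides
#'   `resolution_ratio` when given)
#' @return object of class `sequence_params`
#' @export
sequence_params <- function(TR = 83, TE = 4, n_lines = 64L, n_readout = 64L,
                            horizon = 1L, slice_step = 0.02,
                            mode = c("prediction", "no_prediction",
                                     "oracle", "static"),
                            resolution_ratio = NULL, start_frame = 21L,
                            voxel_um = NULL) {
  mode <- match.arg(mode)
  stopifnot(TE > 0, TR > TE, n_lines >= 1, n_readout >= 1,
            is.null(resolution_ratio) || resolution_ratio >= 1,
            slice_step > 0)
  if (mode == "prediction" && horizon < 1)
    stop("prediction mode requires a horizon of at least 1 frame")
  structure(list(TR = TR, TE = TE, n_lines = as.integer(n_lines),
                 n_readout = as.integer(n_readout),
                 horizon = as.integer(horizon), slice_step = slice_step,
                 mode = mode, resolution_ratio = resolution_ratio,
                 start_frame = as.integer(start_frame),
                 voxel_um = voxel_um),
            class = "sequence_params")
}

#' @export
print.sequence_params <- function(x, ...) {
  rat <- if (is.null(x$resolution_ratio)) "phantom-native"
         else sprintf("%g:1", x$resolution_ratio)
  cat(sprintf(
    "<sequence_params> %s, TR %g ms, TE %g ms, %d x %d, horizon %d, resolution %s\n",
    x$mode, x$TR, x$TE, x$n_lines, x$n_readout, x$horizon, rat))
  invisible(x)
}

# MR voxel size in um for a dataset/params pair
voxel_size_um <- function(dataset, params) {
  if (!is.null(params$voxel_um)) return(params$voxel_um)
  if (!is.null(params$resolution_ratio))
    return(dataset$optics$pixel_size / params$resolution_ratio)
  dataset$phantoms[[1]]$in_plane_resolution
}

#' Slice plan: gradient center and in-plane axes of the field of view
#'
#' The FoV is a square grid of `n` voxels per axis centered at the gradient
#' center `gc`; `xi` (phase-encode axis) lies in the dish plane, nominally
#' along the in-plane normal of the center line; `eta` (frequency-encode
#' axis) is the out-of-plane vertical, so xi . eta = 0 holds exactly.
#' @param gc gradient center (x, y) in micrometres
#' @param xi unit 2-vector of the in-plane phase-encode axis
#' @param voxel_um voxel size in micrometres
#' @param n grid size along xi (phase-encode lines)
#' @param m grid size along eta (readout samples); defaults to `n`
#' @return object of class `slice_plan`
#' @export
slice_plan <- function(gc, xi, voxel_um, n = 64L, m = n) {
  xi <- as.numeric(xi)
  nx <- sqrt(sum(xi^2))
  if (nx == 0) stop("xi must be a nonzero vector")
  xi <- xi / nx
  structure(list(gc = as.numeric(gc), xi = xi,
                 xi3 = c(xi, 0), eta3 = c(0, 0, 1),
                 voxel_um = voxel_um, n = as.integer(n), m = as.integer(m)),
            class = "slice_plan")
}

# perfect plan from the ground-truth pose at a frame
plan_from_pose <- function(pose, s, voxel_um, n = 64L, m = n) {
  fr <- pose_frame(pose, s)
  slice_plan(fr$point, fr$normal, voxel_um, n, m)
}

# centered voxel offsets for a grid of k voxels
grid_offsets <- function(k, voxel_um) (seq_len(k) - (k / 2 + 0.5)) * voxel_um

#' True appearance of a slice on the FoV grid
#'
#' The reference image of slice s: the phantom of the slab containing s
#' (boundaries belong to the lower slab), sampled on the FoV voxel grid by
#' bilinear interpolation. When the voxel size equals the phantom in-plane
#' resolution the grids coincide and the phantom is returned exactly. The
#' appearance is frame-independent (the pose only positions and orients the
#' slice in the dish).
#'
#' @param dataset a `video_dataset`
#' @param s slice coordinate in `[0, 1]`
#' @param frame 1-based frame index (validated; content does not depend on it)
#' @param voxel_um FoV voxel size in micrometres
#' @param n FoV grid size along xi
#' @param m FoV grid size along eta (defaults to `n`)
#' @return n x m matrix
#' @export
true_slice_image <- function(dataset, s, frame = 1L, voxel_um = NULL,
                             n = 64L, m = n) {
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  if (frame < 1 || frame > length(dataset$poses)) stop("invalid frame")
  ph <- dataset$phantoms[[snap_slice(s, dataset$n_slices)]]
  if (is.null(voxel_um)) voxel_um <- ph$in_plane_resolution
  res <- ph$in_plane_resolution
  ctr <- (nrow(ph$intensities) + 1) / 2
  bilinear_sample(ph$intensities,
                  grid_offsets(n, voxel_um) / res + ctr,
                  grid_offsets(m, voxel_um) / res + ctr, fill = 0)
}

#' Image observed in the field of view for a given gradient center
#'
#' Samples the worm volume -- slice phantoms positioned by the frame's
#' ground-truth pose -- on the FoV grid. Each FoV column (position along xi)
#' is projected onto the posed center line, yielding its arc coordinate and
#' signed in-plane offset: along-body placement error beyond a slab boundary
#' therefore substitutes neighbouring-slice content, while in-plane error
#' shifts the cross-section and fills the vacated voxels with zeros --
#' the two artifact mechanisms of an off-center gradient. Grid points beyond
#' the body return 0; a FoV entirely outside the worm yields an all-zero
#' image.
#'
#' @param dataset a `video_dataset`
#' @param plan a [slice_plan]
#' @param frame 1-based frame index
#' @return n x n matrix (rows: xi/phase axis, cols: eta/vertical axis)
#' @export
observed_fov_image <- function(dataset, plan, frame) {
  if (frame < 1 || frame > length(dataset$poses)) stop("invalid frame")
  pose <- dataset$poses[[frame]]
  n <- plan$n
  m <- if (is.null(plan$m)) n else plan$m
  offs <- grid_offsets(n, plan$voxel_um)
  q <- cbind(plan$gc[1] + offs * plan$xi[1],
             plan$gc[2] + offs * plan$xi[2])
  pr <- project_polyline(q, pose$points, pose$arclen)
  L <- max(pose$arclen)
  s_i <- pr$arc / L
  slab <- slab_of(s_i, dataset$n_slices)
  valid <- !pr$beyond
  out <- matrix(0, n, m)
  res <- dataset$phantoms[[1]]$in_plane_resolution
  ctr <- (nrow(dataset$phantoms[[1]]$intensities) + 1) / 2
  bcoord <- grid_offsets(m, plan$voxel_um) / res + ctr
  for (k in unique(slab[valid])) {
    rows <- which(valid & slab == k)
    P <- dataset$phantoms[[k]]$intensities
    out[rows, ] <- bilinear_sample(P, pr$offset[rows] / res + ctr, bcoord,
                                   fill = 0)
  }
  out
}

#' Encode one phase-encode line of k-space
#'
#' Each voxel of the FoV image contributes its intensity with a phase
#' proportional to its xi index (phase step of line J: -pi + (J-1) * 2*pi/N)
#' and a frequency proportional to its eta index; the detected sum signal
#' over the readout equals row J of the centered 2-D discrete Fourier
#' transform of the image (DC line at J = N/2 + 1).
#'
#' @param fov FoV image matrix (N x M)
#' @param J line index in 1..N
#' @return complex vector of length M
#' @export
encode_line <- function(fov, J) {
  N <- nrow(fov)
  if (J < 1 || J > N) stop("line index out of range")
  dft_centered(fov)[J, ]
}

#' Run a gradient-echo acquisition of one slice of the moving worm
#'
#' Acquires `params$n_lines` k-space lines, one per TR (locked to the video
#' frame interval). Before each line the gradient center is updated
#' according to the mode: `prediction` places it at the position of the
#' slice coordinate s_c = s - v * horizon predicted `horizon` frames earlier
#' from the detected track; `no_prediction` keeps it fixed at the slice's
#' ground-truth position at a reference frame; `oracle` follows the
#' ground-truth pose exactly; `static` freezes the worm at the start frame.
#' Motion within one line is ignored.
#'
#' @param dataset a `video_dataset`
#' @param params a [sequence_params]
#' @param s slice coordinate in `[0, 1]`
#' @param track a `worm_track` (required in prediction mode)
#' @param np_frame reference frame of the no-prediction gradient center;
#'   default `start_frame + horizon`
#' @return `kspace` object: complex `k` (N x M), `params`, `s`, `per_line`
#'   bookkeeping data.frame
#' @export
run_gre <- function(dataset, params, s, track = NULL, np_frame = NULL) {
  stopifnot(inherits(params, "sequence_params"))
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  # the imaged slice is one of the slabs: snap to the nearest slab center
  s <- (snap_slice(s, dataset$n_slices) - 0.5) / dataset$n_slices
  N <- params$n_lines
  M <- params$n_readout
  f0 <- params$start_frame
  n_frames <- length(dataset$poses)
  need <- if (params$mode == "static") f0 else f0 + N - 1
  if (need > n_frames)
    stop("video too short for the acquisition: need ", need,
         " frames, have ", n_frames)
  vox <- voxel_size_um(dataset, params)
  mode <- params$mode
  if (mode == "prediction") {
    if (is.null(track)) stop("prediction mode requires a worm track")
    if (f0 - params$horizon < 1)
      stop("start_frame too early for the requested horizon")
  }
  if (mode == "no_prediction") {
    if (is.null(np_frame)) np_frame <- f0 + params$horizon
    np_plan <- plan_from_pose(dataset$poses[[min(np_frame, n_frames)]], s,
                              vox, N, M)
  }
  K <- matrix(complex(real = 0, imaginary = 0), N, M)
  per_line <- vector("list", N)
  static_fov <- NULL
  for (J in seq_len(N)) {
    f <- f0 + J - 1L
    clamped <- FALSE
    if (mode == "static") {
      if (is.null(static_fov))
        static_fov <- true_slice_image(dataset, s, f0, voxel_um = vox,
                                       n = N, m = M)
      fov <- static_fov
      gc <- plan_from_pose(dataset$poses[[f0]], s, vox, N, M)$gc
    } else if (mode == "oracle") {
      plan <- plan_from_pose(dataset$poses[[f]], s, vox, N, M)
      fov <- observed_fov_image(dataset, plan, f)
      gc <- plan$gc
    } else if (mode == "no_prediction") {
      fov <- observed_fov_image(dataset, np_plan, f)
      gc <- np_plan$gc
    } else {
      fp <- f - params$horizon
      st <- track$frames[[fp]]
      if (!isTRUE(st$present))
        stop("worm detection failed on frame ", fp,
             " required by the predictor")
      s_c <- s - st$v * params$horizon
      clamped <- s_c < 0 || s_c > 1
      s_c <- clamp(s_c, 0, 1)
      fr <- skeleton_frame(st$skel, s_c)
      plan <- slice_plan(fr$point, fr$normal, vox, N, M)
      fov <- observed_fov_image(dataset, plan, f)
      gc <- plan$gc
    }
    K[J, ] <- encode_line(fov, J)
    per_line[[J]] <- data.frame(line = J, frame = f, gc_x = gc[1],
                                gc_y = gc[2], clamped = clamped)
  }
  structure(list(k = K, params = params, s = s,
                 voxel_um = vox,
                 per_line = do.call(rbind, per_line)),
            class = "kspace")
}

#' @export
print.kspace <- function(x, ...) {
  cat(sprintf("<kspace> %d x %d lines, slice s = %g, mode %s\n",
              nrow(x$k), ncol(x$k), x$s, x$params$mode))
  invisible(x)
}

#' Reconstruct the magnitude image from k-space
#' @param kspace a `kspace` object or complex matrix
#' @return nonnegative magnitude matrix (`recon_image`)
#' @export
reconstruct <- function(kspace) {
  K <- if (inherits(kspace, "kspace")) kspace$k else kspace
  out <- Mod(idft_centered(K))
  class(out) <- c("recon_image", class(out))
  out
}
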