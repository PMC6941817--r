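#' Generate a complete synthetic video dataset
#'
#' Produces the synthetic stand-in for one recorded video: rendered frames,
#' exact ground-truth centerline poses, and the 50-slice cross-section
#' phantom library. Poses are translated so the whole trajectory fits in the
#' frame with a margin; everything is reproducible from `kin$seed`.
#'
#' @param kin a [worm_kinematics]
#' @param optics a [worm_optics]; image dimensions are enlarged automatically
#'   if the trajectory would not fit
#' @param n_slices number of phantom slabs
#' @param phantom_res in-plane resolution of the slice phantoms (um/voxel)
#' @param render whether to render pixel frames (poses and phantoms only if
#'   FALSE, e.g. for prediction-only studies)
#' @return object of class `video_dataset` with `frames` (list of matrices),
#'   `poses` (list of `centerline_pose`), `phantoms` (list of
#'   `slice_phantom`), `kin`, `optics`, `background`
#' @export
generate_dataset <- function(kin, optics = worm_optics(), n_slices = 50,
                             phantom_res = 1.6, render = TRUE) {
  stopifnot(inherits(kin, "worm_kinematics"))
  path <- worm_path(kin)
  poses <- lapply(seq_len(kin$n_frames) - 1L,
                  function(f) generate_centerline(kin, f, path))
  # translate trajectory into the frame with a margin
  allpts <- do.call(rbind, lapply(poses, `[[`, "points"))
  margin <- max(poses[[1]]$width) + 12 * optics$pixel_size
  xr <- range(allpts[, 1]); yr <- range(allpts[, 2])
  need_c <- ceiling((diff(xr) + 2 * margin) / optics$pixel_size)
  need_r <- ceiling((diff(yr) + 2 * margin) / optics$pixel_size)
  if (need_r > optics$nrow) optics$nrow <- as.integer(need_r)
  if (need_c > optics$ncol) optics$ncol <- as.integer(need_c)
  shift <- c(margin - xr[1] +
               (optics$ncol * optics$pixel_size - diff(xr) - 2 * margin) / 2,
             margin - yr[1] +
               (optics$nrow * optics$pixel_size - diff(yr) - 2 * margin) / 2)
  poses <- lapply(poses, function(p) {
    p$points <- sweep(p$points, 2, shift, `+`)
    p
  })
  bg <- render_background(optics, kin$seed)
  frames <- NULL
  if (render) {
    frames <- lapply(seq_along(poses), function(i) {
      render_frame(poses[[i]], optics, bg,
                   noise_seed = substream(kin$seed, 100L + i))
    })
  }
  radii <- width_profile((seq_len(n_slices) - 0.5) / n_slices, kin$half_width)
  sources <- synthetic_sections(n_slices, size = 128, res_um = phantom_res / 2,
                                radii_um = radii, seed = kin$seed)
  phantoms <- build_slice_phantoms(sources, n_slices,
                                   in_plane_resolution = phantom_res)
  structure(list(frames = frames, poses = poses, phantoms = phantoms,
                 kin = kin, optics = optics, background = bg,
                 n_slices = n_slices),
            class = "video_dataset")
}

#' @export
print.video_dataset <- function(x, ...) {
  cat(sprintf(
    "<video_dataset> %d frames (%d x %d px, %.3g um/px), %d phantoms, seed %d\n",
    length(x$poses), x$optics$nrow, x$optics$ncol, x$optics$pixel_size,
    length(x$phantoms), x$kin$seed))
  invisible(x)
}

#' Write a dataset to a directory
#'
#' Layout: `frames.tif` (multi-page 16-bit grayscale TIFF), `poses.csv`
#' (frame, point_index, x_um, y_um, halfwidth_um), `phantoms/phantom_XX.png`
#' (8-bit), and `kinematics.yaml` (all kinematic and optic fields incl. seed).
#' @param dataset a `video_dataset`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(dataset$frames)) {
    tiff::writeTIFF(lapply(dataset$frames, function(f) {
      m <- unclass(f); attributes(m) <- list(dim = dim(m)); m
    }), file.path(dir, "frames.tif"), bits.per.sample = 16L)
  }
  pose_df <- do.call(rbind, lapply(dataset$poses, function(p) {
    data.frame(frame = p$frame, point_index = seq_len(nrow(p$points)) - 1L,
               x_um = p$points[, 1], y_um = p$points[, 2],
               halfwidth_um = p$width)
  }))
  write.csv(pose_df, file.path(dir, "poses.csv"), row.names = FALSE)
  pdir <- file.path(dir, "phantoms")
  dir.create(pdir, showWarnings = FALSE)
  for (ph in dataset$phantoms) {
    png::writePNG(ph$intensities,
                  file.path(pdir, sprintf("phantom_%02d.png", ph$slice_index)))
  }
  meta <- c(unclass(dataset$kin),
            list(optics = unclass(dataset$optics),
                 n_slices = dataset$n_slices,
                 phantom_res = dataset$phantoms[[1]]$in_plane_resolution))
  yaml::write_yaml(meta, file.path(dir, "kinematics.yaml"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset]
#' @param dir dataset directory
#' @return a `video_dataset` (frames present if `frames.tif` exists)
#' @export
read_dataset <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "kinematics.yaml"))
  kin <- do.call(worm_kinematics,
                 meta[intersect(names(meta), names(formals(worm_kinematics)))])
  optics <- do.call(worm_optics, meta$optics)
  pose_df <- read.csv(file.path(dir, "poses.csv"))
  poses <- lapply(split(pose_df, pose_df$frame), function(d) {
    d <- d[order(d$point_index), ]
    pts <- cbind(d$x_um, d$y_um)
    structure(list(frame = d$frame[1], points = pts,
                   s = seq(0, 1, length.out = nrow(pts)),
                   width = d$halfwidth_um, arclen = cum_arclength(pts)),
              class = "centerline_pose")
  })
  poses <- poses[order(as.integer(names(poses)))]
  names(poses) <- NULL
  pfiles <- sort(list.files(file.path(dir, "phantoms"), "phantom_.*\\.png$",
                            full.names = TRUE))
  phantoms <- lapply(seq_along(pfiles), function(k) {
    structure(list(intensities = png::readPNG(pfiles[k]),
                   slice_index = k,
                   s_center = (k - 0.5) / length(pfiles),
                   in_plane_resolution = meta$phantom_res),
              class = "slice_phantom")
  })
  frames <- NULL
  fpath <- file.path(dir, "frames.tif")
  if (file.exists(fpath)) {
    frames <- tiff::readTIFF(fpath, all = TRUE)
    frames <- lapply(frames, function(f) {
      attr(f, "pixel_size") <- optics$pixel_size
      class(f) <- c("frame_image", class(f))
      f
    })
  }
  structure(list(frames = frames, poses = poses, phantoms = phantoms,
                 kin = kin, optics = optics,
                 background = NULL, n_slices = meta$n_slices),
            class = "video_dataset")
}
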