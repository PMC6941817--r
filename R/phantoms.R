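#' Synthetic TEM-like cross-section source images
#'
#' Stand-in for a transmission-electron-microscope slice stack (labelled
#' synthetic throughout): bright-background images of worm cross-sections
#' with anatomically inspired structure -- an outer cuticle ring, four body
#' wall muscle quadrants, and an intestine lumen whose size and orientation
#' vary smoothly along the body. Low-density regions are bright, as in TEM.
#'
#' @param n_slices number of sections (one per slab along the body)
#' @param size source image side length in pixels
#' @param res_um micrometres per source pixel
#' @param radii_um disc radius per section in micrometres (defaults to the
#'   half-width profile of the default worm evaluated at the slab centers)
#' @param seed seed for the fine intensity texture
#' @return list of size x size matrices in `[0, 1]`
#' @export
synthetic_sections <- function(n_slices = 50, size = 128, res_um = 0.8,
                               radii_um = NULL, seed = 1L) {
  stopifnot(n_slices >= 1, size >= 64)
  s_c <- (seq_len(n_slices) - 0.5) / n_slices
  if (is.null(radii_um)) radii_um <- width_profile(s_c, 45)
  set.seed(substream(seed, 4L))
  ctr <- (size + 1) / 2
  xs <- ((1:size) - ctr) * res_um
  X <- matrix(xs, size, size, byrow = TRUE)
  Y <- matrix(xs, size, size)
  R <- sqrt(X^2 + Y^2)
  TH <- atan2(Y, X)
  out <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    r0 <- radii_um[k]
    ang <- 2 * pi * (k - 1) / n_slices          # slow structural rotation
    img <- matrix(1, size, size)                # white background (low density)
    body <- R <= r0
    img[body] <- 0.62                           # cytoplasm, mid density
    cuticle <- R <= r0 & R >= r0 * 0.88
    img[cuticle] <- 0.25                        # dense outer cuticle
    musc <- R < r0 * 0.85 & R > r0 * 0.45 &
      (cos(2 * (TH - ang))^2 > 0.55)
    img[musc] <- 0.4                            # muscle quadrants
    # intestine: off-center ellipse, size varies along the body
    gx <- X - 0.25 * r0 * cos(ang); gy <- Y - 0.25 * r0 * sin(ang)
    gr <- (0.18 + 0.12 * sin(pi * s_c[k])) * r0
    gut <- (gx^2 / (1.4 * gr)^2 + gy^2 / gr^2) <= 1 & R < r0 * 0.8
    img[gut] <- 0.88                            # lumen, low density (bright)
    tex <- matrix(rnorm(size^2, 0, 0.03), size, size)
    img[body] <- clamp(img[body] + tex[body], 0, 1)
    out[[k]] <- img
  }
  out
}

#' Remove the bright background of a section image
#'
#' Background is the border-connected region within tolerance of the image
#' maximum; it is set exactly to zero (foreground kept as-is).
#' @param img matrix in `[0, 1]`
#' @param tol intensity tolerance below the maximum that still counts as
#'   background
#' @return list with `img` (background zeroed) and `fg` (logical foreground)
#' @export
remove_background_section <- function(img, tol = 0.05) {
  bright <- img >= max(img) - tol
  lab <- EBImage::bwlabel(bright)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labs <- setdiff(border_labs, 0)
  bg <- matrix(FALSE, nrow(img), ncol(img))
  if (length(border_labs) > 0) bg <- matrix(lab %in% border_labs, nrow(img))
  out <- img
  out[bg] <- 0
  list(img = out, fg = !bg)
}

#' Invert intensities within a foreground mask
#'
#' Maps x to 1 - x inside the mask and leaves the (zeroed) background at 0,
#' so bright low-density regions become dark as they would in MR. Applying
#' the inversion twice restores the background-removed input.
#' @param img matrix with zeroed background
#' @param fg logical foreground mask
#' @return matrix
#' @export
invert_section <- function(img, fg) {
  out <- img
  out[fg] <- 1 - img[fg]
  out
}

#' Block-average downsampling to a target square size
#'
#' Area-weighted averaging (no decimation): the image is first interpolated
#' onto a fine grid commensurate with the target, then averaged per block.
#' For integer ratios this is the plain block mean.
#' @param img matrix
#' @param size target side length
#' @return size x size matrix
#' @export
resample_block <- function(img, size = 64) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr %% size == 0 && nc %% size == 0) {
    fr <- nr %/% size; fc <- nc %/% size
    grp_r <- rep(seq_len(size), each = fr)
    tmp <- rowsum(img, grp_r) / fr
    out <- t(rowsum(t(tmp), rep(seq_len(size), each = fc)) / fc)
    dimnames(out) <- NULL
    return(out)
  } else {
    up <- 4L  # supersample then block-average
    rpos <- (seq_len(size * up) - 0.5) * nr / (size * up) + 0.5 - 0.5
    cpos <- (seq_len(size * up) - 0.5) * nc / (size * up) + 0.5 - 0.5
    fine <- bilinear_sample(img, rpos + 0.5, cpos + 0.5, fill = 0)
    grp <- rep(seq_len(size), each = up)
    tmp <- rowsum(fine, grp) / up
    out <- t(rowsum(t(tmp), grp) / up)
    dimnames(out) <- NULL
    out
  }
}

#' Build the 64 x 64 slice-phantom library from section images
#'
#' Pipeline per source image: remove the bright background (set to zero),
#' invert the color map so low-density regions appear dark, and resample to
#' 64 x 64 by block averaging. Sections are assigned to slabs in order along
#' the body; slab k is centered at s = (k - 0.5) / n_slices.
#'
#' @param sources list of grayscale matrices (>= 64 x 64), ordered head first
#' @param n_slices number of slabs along the body
#' @param in_plane_resolution micrometres per phantom voxel
#' @return list of `slice_phantom` objects: `intensities` (64 x 64 in
#'   `[0, 1]`, zero background), `slice_index`, `s_center`,
#'   `in_plane_resolution`
#' @export
build_slice_phantoms <- function(sources, n_slices = 50,
                                 in_plane_resolution = 1.6) {
  if (n_slices < 1) stop("n_slices must be >= 1")
  stopifnot(length(sources) >= 1)
  if (any(vapply(sources, function(x) nrow(x) < 64 || ncol(x) < 64, TRUE)))
    stop("source images must be at least 64 x 64")
  n_src <- length(sources)
  processed <- lapply(sources, function(img) {
    rb <- remove_background_section(img)
    inv <- invert_section(rb$img, rb$fg)
    clamp(resample_block(inv, 64L), 0, 1)
  })
  lapply(seq_len(n_slices), function(k) {
    src <- ceiling(k * n_src / n_slices)
    structure(list(intensities = processed[[src]],
                   slice_index = k,
                   s_center = (k - 0.5) / n_slices,
                   in_plane_resolution = in_plane_resolution),
              class = "slice_phantom")
  })
}
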