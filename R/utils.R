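#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx fft median rnorm runif quantile setNames
#' @importFrom utils head tail read.csv write.csv
NULL

# Coordinate conventions (used everywhere):
#  * raw image pixels: 0-based (row, col), origin top-left, row-major;
#    world position of pixel (r, c) center = ((c + 0.5), (r + 0.5)) * pixel_size,
#    in micrometres, y pointing down.
#  * downsampled (factor 9) pixels: continuous coordinate q such that
#    world um = q * 9 * pixel_size; pixel (R, C) center has q = (R + 0.5).

#' Swap quadrants of a matrix so the DC bin moves to/from the center
#'
#' For even dimensions the forward and inverse shifts coincide, which is the
#' only case used by the acquisition model (64 x 64 grids).
#' @param x numeric or complex matrix
#' @return matrix of the same shape
#' @keywords internal
fftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c((nr %/% 2 + 1):nr, 1:(nr %/% 2))
  ci <- c((nc %/% 2 + 1):nc, 1:(nc %/% 2))
  x[ri, ci, drop = FALSE]
}

#' Centered 2-D discrete Fourier transform
#'
#' Spatial index m and frequency index u both run over -N/2 .. N/2-1 relative
#' to the matrix center, so row N/2+1 is the DC line and row 1 carries the
#' most negative spatial frequency (initial phase -pi).
#' @param img numeric or complex matrix with even dimensions
#' @return complex matrix
#' @keywords internal
dft_centered <- function(img) {
  fftshift2(stats::fft(fftshift2(img)))
}

#' Centered inverse 2-D discrete Fourier transform
#' @param k complex matrix with even dimensions
#' @return complex matrix (divide-by-N normalisation included)
#' @keywords internal
idft_centered <- function(k) {
  fftshift2(stats::fft(fftshift2(k), inverse = TRUE)) / length(k)
}

#' Derive an independent RNG substream seed
#'
#' Deterministic fan-out of one user seed into per-stage streams; keeps the
#' result inside the 32-bit integer range R requires.
#' @keywords internal
substream <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * offset) %% 2147483647L)
}

#' Clamp values into an interval
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Linear interpolation along a polyline at given arc-length positions
#'
#' @param pts n x 2 matrix of polyline vertices
#' @param cum cumulative arc length per vertex (first = 0, nondecreasing)
#' @param at arc-length positions (clamped to the valid range)
#' @return length(at) x 2 matrix
#' @keywords internal
interp_polyline <- function(pts, cum, at) {
  at <- clamp(at, cum[1], cum[length(cum)])
  cbind(stats::approx(cum, pts[, 1], xout = at, ties = "ordered")$y,
        stats::approx(cum, pts[, 2], xout = at, ties = "ordered")$y)
}

#' Cumulative arc length of a polyline
#' @keywords internal
cum_arclength <- function(pts) {
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  c(0, cumsum(seg))
}

#' Unit tangent of a polyline at an arc-length position
#'
#' Central difference over a small arc window; direction of increasing arc
#' length (head to tail for a pose or skeleton path stored head-first).
#' @keywords internal
polyline_tangent <- function(pts, cum, at, h = NULL) {
  L <- cum[length(cum)]
  if (is.null(h)) h <- max(L / 200, 1e-6)
  p1 <- interp_polyline(pts, cum, at - h)
  p2 <- interp_polyline(pts, cum, at + h)
  d <- p2 - p1
  n <- sqrt(rowSums(d^2))
  n[n == 0] <- 1
  d / n
}

#' In-plane normal: tangent rotated by +90 degrees (y-down convention)
#' @keywords internal
rot90cw <- function(t) cbind(-t[, 2], t[, 1])

#' Project points onto a polyline
#'
#' Returns, for each query point, the arc-length coordinate of the nearest
#' point on the polyline, the signed perpendicular offset (positive on the
#' +normal side, normal = tangent rotated by 90 degrees), and whether the
#' nearest point is an interior projection or a clamped endpoint.
#'
#' @param q m x 2 query points
#' @param pts n x 2 polyline vertices
#' @param cum cumulative arc length (from [cum_arclength])
#' @return list with `arc`, `offset`, `beyond` (logical: off either end)
#' @keywords internal
project_polyline <- function(q, pts, cum) {
  n <- nrow(pts); m <- nrow(q)
  ax <- pts[-n, 1]; ay <- pts[-n, 2]
  dx <- diff(pts[, 1]); dy <- diff(pts[, 2])
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-12
  # t-parameter of each query on each segment, clamped to [0,1]
  qx <- matrix(q[, 1], m, n - 1)
  qy <- matrix(q[, 2], m, n - 1)
  axm <- matrix(ax, m, n - 1, byrow = TRUE)
  aym <- matrix(ay, m, n - 1, byrow = TRUE)
  dxm <- matrix(dx, m, n - 1, byrow = TRUE)
  dym <- matrix(dy, m, n - 1, byrow = TRUE)
  tt <- ((qx - axm) * dxm + (qy - aym) * dym) / matrix(len2, m, n - 1, byrow = TRUE)
  ttc <- clamp(tt, 0, 1)
  px <- axm + ttc * dxm
  py <- aym + ttc * dym
  d2 <- (qx - px)^2 + (qy - py)^2
  best <- max.col(-d2, ties.method = "first")
  ib <- cbind(seq_len(m), best)
  tb <- ttc[ib]
  arc <- cum[best] + tb * sqrt(len2[best])
  # signed offset: cross product sign of (query - foot) against tangent
  fx <- px[ib]; fy <- py[ib]
  tx <- dx[best] / sqrt(len2[best]); ty <- dy[best] / sqrt(len2[best])
  # normal = (-ty, tx): tangent rotated +90 (y down)
  off <- (q[, 1] - fx) * (-ty) + (q[, 2] - fy) * tx
  beyond <- (best == 1 & tt[ib] < 0) | (best == (n - 1) & tt[ib] > 1)
  list(arc = arc, offset = off, beyond = beyond)
}

#' Bilinear sampling of a matrix at arbitrary fractional points
#'
#' @param P matrix
#' @param r,c equal-length vectors of fractional row/col positions (1-based)
#' @return numeric vector of sampled values (`fill` outside the grid)
#' @keywords internal
bilinear_points <- function(P, r, c, fill = 0) {
  nr <- nrow(P); nc <- ncol(P)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  gv <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- P[cbind(ri[ok], ci[ok])]
    v
  }
  val <- gv(r0, c0) * (1 - fr) * (1 - fc) +
    gv(r0 + 1, c0) * fr * (1 - fc) +
    gv(r0, c0 + 1) * (1 - fr) * fc +
    gv(r0 + 1, c0 + 1) * fr * fc
  val[r < 0.5 | r > nr + 0.5 | c < 0.5 | c > nc + 0.5] <- fill
  val
}

#' Bilinear sampling of a matrix on fractional (row, col) grids
#'
#' Sample positions outside the grid return `fill`.
#' @param P matrix
#' @param rvec fractional row positions (1-based, 1 = first row center)
#' @param cvec fractional column positions
#' @return length(rvec) x length(cvec) matrix
#' @keywords internal
bilinear_sample <- function(P, rvec, cvec, fill = 0) {
  nr <- nrow(P); nc <- ncol(P)
  m <- length(rvec); k <- length(cvec)
  R <- matrix(rvec, m, k)
  C <- matrix(cvec, m, k, byrow = TRUE)
  r0 <- floor(R); c0 <- floor(C)
  fr <- R - r0; fc <- C - c0
  out <- matrix(fill, m, k)
  # gather with out-of-range guard: index 0 weight contributions dropped
  gv <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- matrix(0, m, k)
    v[ok] <- P[cbind(ri[ok], ci[ok])]
    v
  }
  inside <- R >= 0.5 & R <= nr + 0.5 & C >= 0.5 & C <= nc + 0.5
  val <- gv(r0, c0) * (1 - fr) * (1 - fc) +
    gv(r0 + 1, c0) * fr * (1 - fc) +
    gv(r0, c0 + 1) * (1 - fr) * fc +
    gv(r0 + 1, c0 + 1) * fr * fc
  out[inside] <- val[inside]
  out
}
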