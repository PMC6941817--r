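#' Structural similarity between a reconstruction and its reference
#'
#' Mean local structural similarity with the measure's canonical settings:
#' 11 x 11 Gaussian window (sigma 1.5), stabilizers K1 = 0.01 and K2 = 0.03,
#' dynamic range taken from the reference image `x` (a constant reference
#' falls back to range 1). Local statistics are computed by Gaussian
#' filtering and averaged over the interior region whose windows lie fully
#' inside the image. Identical images return 1; structurally unrelated
#' images return about 0; negative means are clipped to 0 so the score lies
#' in `[0, 1]`.
#'
#' @param x reference image matrix
#' @param y comparison image matrix (same shape)
#' @param window window side length (odd)
#' @param sigma Gaussian window standard deviation
#' @param K1,K2 stabilizing constants
#' @return `ssim_result`: list with `s_xy` and the settings used
#' @export
#' @examples
#' img <- matrix(runif(64 * 64), 64)
#' ssim(img, img)$s_xy  # 1
ssim <- function(x, y, window = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  x <- unclass(x); y <- unclass(y)
  if (!all(dim(x) == dim(y))) stop("image shape mismatch")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  L <- diff(range(x))
  if (L < .Machine$double.eps) L <- 1
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  w <- EBImage::makeBrush(window, shape = "Gaussian", sigma = sigma)
  w <- w / sum(w)
  f <- function(img) as.matrix(EBImage::filter2(EBImage::Image(img), w))
  mx <- f(x); my <- f(y)
  sxx <- f(x * x) - mx^2
  syy <- f(y * y) - my^2
  sxy <- f(x * y) - mx * my
  smap <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  # interior region only: filter2 wraps at the boundary
  b <- (window - 1L) %/% 2L
  ri <- (b + 1):(nrow(x) - b)
  ci <- (b + 1):(ncol(x) - b)
  if (length(ri) < 1 || length(ci) < 1) { ri <- seq_len(nrow(x)); ci <- seq_len(ncol(x)) }
  val <- max(0, min(1, mean(smap[ri, ci])))
  structure(list(s_xy = val, window = window, sigma = sigma,
                 K1 = K1, K2 = K2, dynamic_range = L),
            class = "ssim_result")
}

#' @export
print.ssim_result <- function(x, ...) {
  cat(sprintf("<ssim_result> s_xy = %.4f (window %d, sigma %g)\n",
              x$s_xy, x$window, x$sigma))
  invisible(x)
}

#' @export
as.numeric.ssim_result <- function(x, ...) x$s_xy
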