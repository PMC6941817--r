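# Structural similarity, the simulation paradigms and the imageability
# taxonomy.

# direct evaluation of the SSIM definition with a Gaussian window (oracle,
# independent of the package implementation)
ssim_direct <- function(x, y, window = 11, sigma = 1.5,
                        K1 = 0.01, K2 = 0.03, L = NULL) {
  if (is.null(L)) L <- diff(range(x))
  if (L < .Machine$double.eps) L <- 1
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  h <- (window - 1) / 2
  g <- outer(-h:h, -h:h, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  g <- g / sum(g)
  nr <- nrow(x); nc <- ncol(x)
  vals <- c()
  for (i in (h + 1):(nr - h)) for (j in (h + 1):(nc - h)) {
    wx <- x[(i - h):(i + h), (j - h):(j + h)]
    wy <- y[(i - h):(i + h), (j - h):(j + h)]
    mx <- sum(g * wx); my <- sum(g * wy)
    sxx <- sum(g * wx^2) - mx^2; syy <- sum(g * wy^2) - my^2
    sxy <- sum(g * wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * sxy + C2)) /
                ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
  }
  max(0, min(1, mean(vals)))
}

test_that("identical images score exactly 1 and mismatched shapes error", {
  set.seed(11)
  for (img in list(matrix(runif(64 * 64), 64),
                   synthetic_sections(1, seed = 3)[[1]][1:64, 1:64])) {
    expect_identical(ssim(img, img)$s_xy, 1)
  }
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 9, 9)), "mismatch")
  expect_error(ssim(matrix(NA_real_, 8, 8), matrix(0, 8, 8)), "finite")
})

test_that("ssim is symmetric, bounded, and matches the direct formula", {
  set.seed(12)
  x <- matrix(runif(32 * 32), 32)
  y <- matrix(runif(32 * 32), 32)
  expect_equal(ssim(x, y)$s_xy, ssim(y, x)$s_xy, tolerance = 1e-12)
  for (i in 1:5) {
    a <- matrix(runif(32 * 32), 32); b <- matrix(runif(32 * 32), 32)
    s <- ssim(a, b)$s_xy
    expect_gte(s, 0); expect_lte(s, 1)
  }
  # direct-formula oracle on a small structured pair
  a <- matrix(0, 24, 24); a[8:16, 8:16] <- 1
  b <- matrix(0, 24, 24); b[10:18, 10:18] <- 1
  expect_equal(ssim(a, b)$s_xy, ssim_direct(a, b), tolerance = 1e-6)
})

test_that("structural opposites score near 0 and tiny noise near 1", {
  chk <- matrix(rep(c(0, 1), length.out = 32 * 32), 32)
  chk[, seq(2, 32, 2)] <- 1 - chk[, seq(2, 32, 2)]
  expect_lte(ssim(chk, 1 - chk)$s_xy, 0.05)
  const <- matrix(0.5, 32, 32)
  set.seed(13)
  eps <- matrix(rnorm(32 * 32, 0, 1e-6), 32)
  expect_gte(ssim(const, const + eps)$s_xy, 0.99)
})

test_that("paradigm reports enumerate the requested conditions exactly once", {
  ds <- tiny_dataset()
  tr <- tiny_track()
  pb <- list(n_lines = 16L, n_readout = 16L, start_frame = 12L)
  rep1 <- simulation_body_position(list(ds), list(tr), params_base = pb)
  expect_equal(nrow(rep1), 6)
  expect_equal(sort(unique(rep1$s)), c(0.02, 0.5, 1.0))
  expect_setequal(unique(rep1$mode), c("prediction", "no_prediction"))
  expect_equal(nrow(unique(rep1[, c("s", "mode")])), 6)
  rep2 <- simulation_resolution(list(ds), list(tr), params_base = pb)
  expect_equal(nrow(rep2), 6)
  expect_equal(sort(unique(rep2$ratio)), c(1, 2, 4))
  rep3 <- simulation_horizon(list(ds), list(tr), horizons = 1:10,
                             params_base = pb)
  expect_equal(nrow(rep3), 20)
  expect_equal(sort(unique(rep3$horizon)), 1:10)
  # deterministic given the same dataset and parameters
  rep3b <- simulation_horizon(list(ds), list(tr), horizons = 1:10,
                              params_base = pb)
  expect_identical(as.data.frame(rep3), as.data.frame(rep3b))
})

test_that("improvement ratio aggregates per video then across videos", {
  df <- data.frame(video = rep(1:2, each = 4),
                   s = 0.5, horizon = 1, ratio = NA,
                   mode = rep(c("prediction", "prediction",
                                "no_prediction", "no_prediction"), 2),
                   ssim = c(0.6, 0.4, 0.2, 0.2, 0.8, 0.6, 0.3, 0.1))
  ir <- improvement_ratio(structure(df, class = c("paradigm_report",
                                                  "data.frame")))
  expect_equal(ir$mean_prediction, mean(c(0.5, 0.7)))
  expect_equal(ir$mean_no_prediction, mean(c(0.2, 0.2)))
  expect_equal(ir$ratio, 0.6 / 0.2)
})

test_that("imageability regimes follow the timescale comparison", {
  expect_identical(classify_imageability(50, 76, 83), "not_imageable")
  expect_identical(classify_imageability(500, 100, 83),
                   "imageable_contrast_restricted")
  expect_identical(classify_imageability(500, 76, 83),
                   "imageable_unrestricted")
  expect_error(classify_imageability(-1, 76, 83), "positive")
  expect_error(classify_imageability(500, 0, 83), "positive")
})
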