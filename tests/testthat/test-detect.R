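# Detection chain: preprocessing, background, segmentation, head detection,
# skeleton coordinate system and the speed estimate.

test_that("block-mean preprocessing has the stated size and value contract", {
  z <- matrix(0.25, 900, 900)
  out <- preprocess(z)
  expect_equal(dim(out), c(100L, 100L))
  expect_true(all(abs(out - 0.25) < 1e-12))
  # checkerboard of uniform 9x9 blocks reproduces the block values exactly
  vals <- matrix(runif(9), 3, 3)
  big <- vals[rep(1:3, each = 9), rep(1:3, each = 9)]
  expect_equal(unclass(preprocess(big)), vals, ignore_attr = TRUE)
  # partial edge blocks are partial means; intensity range preserved
  out2 <- preprocess(matrix(runif(100 * 95), 100, 95))
  expect_equal(dim(out2), c(12L, 11L))
  expect_true(all(out2 >= 0 & out2 <= 1))
  expect_error(preprocess(matrix(0, 5, 5)), "smaller")
})

test_that("temporal median background is exact under half-coverage", {
  set.seed(1)
  truth <- matrix(runif(30 * 40, 0.6, 0.9), 30, 40)
  frames <- lapply(1:11, function(i) {
    f <- truth
    f[, (3 * i):(3 * i + 2)] <- 0.1  # transient dark band, <50% per pixel
    f
  })
  bg <- estimate_background(frames, method = "median")
  # oracle: per-pixel sort
  arr <- array(unlist(frames), dim = c(30, 40, 11))
  oracle <- apply(arr, c(1, 2), function(v) sort(v)[6])
  expect_equal(bg, oracle, tolerance = 1e-12)
  expect_equal(bg, truth, tolerance = 1e-12)
  expect_error(estimate_background(frames[1:2]), "at least 3")
  # identical frames: background equals the frame for both methods
  same <- replicate(5, truth, simplify = FALSE)
  expect_equal(estimate_background(same, method = "median"), truth)
})

test_that("quantile background recovers a noisy static background", {
  set.seed(2)
  truth <- matrix(0.8, 40, 40)
  frames <- lapply(1:40, function(i)
    truth + matrix(rnorm(1600, 0, 0.02), 40, 40))
  bg <- estimate_background(frames, refine = FALSE)
  # upper quantile of symmetric noise overshoots by a known small amount
  expect_lt(mean(abs(bg - truth)), 3 * 0.02)
  bg2 <- estimate_background(frames)
  expect_lt(mean(abs(bg2 - truth)), 0.02 / sqrt(10))
  # with a transient dark band the refinement still recovers the background
  frames2 <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    f[, ((2 * i) %% 38) + 1:3] <- 0.2
    f
  })
  bg3 <- estimate_background(frames2)
  expect_lt(mean(abs(bg3 - truth)), 0.02)
})

test_that("segmentation keeps the largest component and gates tiny ones", {
  bg <- matrix(0.8, 50, 60)
  fr <- bg
  fr[20:24, 10:40] <- 0.3          # worm-like tube
  fr[40:41, 55:56] <- 0.35         # small speck
  wm <- segment_worm(fr, bg)
  expect_true(wm$present)
  expect_true(all(wm$mask[22, 12:38]))
  expect_false(any(wm$mask[40:41, 55:56]))
  # worm-free frame: nothing above threshold survives the area gate
  set.seed(3)
  fr2 <- bg + matrix(rnorm(3000, 0, 0.01), 50, 60)
  expect_false(segment_worm(fr2, bg)$present)
  expect_error(segment_worm(matrix(0, 2, 2), bg), "mismatch")
})

test_that("segmentation overlaps the ground-truth tube (IoU >= 0.7)", {
  ds <- default_dataset()
  pre <- lapply(ds$frames, preprocess)
  bg <- estimate_background(pre)
  ious <- vapply(seq(1, 120, by = 6), function(i) {
    gt <- rasterize_tube(ds$poses[[i]], ds$optics)
    wm <- segment_worm(pre[[i]], bg)
    sum(gt & wm$mask) / sum(gt | wm$mask)
  }, numeric(1))
  expect_gte(mean(ious), 0.7)
})

test_that("COG follows the mask and the smoothing contract", {
  m <- matrix(FALSE, 10, 10); m[4, 7] <- TRUE
  expect_equal(compute_cog(m, dsf = 1), c(6.5, 3.5))
  # alpha = 1 ignores history; constant masks give a fixed point
  expect_equal(compute_cog(m, prev = c(0, 0), alpha = 1, dsf = 1),
               c(6.5, 3.5))
  sm <- compute_cog(m, prev = c(6.5, 3.5), alpha = 0.5, dsf = 1)
  expect_equal(sm, c(6.5, 3.5))
  expect_error(compute_cog(matrix(FALSE, 3, 3)), "empty")
})

test_that("head detection uses difference mass and falls back when still", {
  ends <- rbind(c(5, 5), c(25, 25))
  still <- replicate(5, matrix(0.5, 30, 30), simplify = FALSE)
  hd <- detect_head(still, ends, prev_head = c(25, 25))
  expect_false(hd$confident)
  expect_identical(hd$index, 2L)  # nearest to previous head
  # motion near endpoint 1 wins confidently
  moving <- lapply(1:5, function(i) {
    f <- matrix(0.5, 30, 30); f[4:6, 4:6] <- 0.5 + 0.1 * i; f
  })
  hd2 <- detect_head(moving, ends)
  expect_true(hd2$confident)
  expect_identical(hd2$index, 1L)
  expect_error(detect_head(still[1], ends), "at least 2")
})

test_that("skeleton of a straight tube is ordered with monotone s", {
  m <- matrix(FALSE, 40, 130)
  m[18:22, 11:111] <- TRUE
  sk <- skeletonize(m, head = c(20, 11), dsf = 1)
  expect_equal(sk$s[1], 0)
  expect_equal(sk$s[length(sk$s)], 1)
  expect_true(all(diff(sk$s) > 0))
  # arc length close to the tube axis length (within 2 px + end caps)
  expect_equal(sk$length_um, 100, tolerance = 0.05)
  # ordering follows the head: first node near column 11
  expect_lt(sk$path[1, 1], 15)
  sk2 <- skeletonize(m, head = c(20, 111), dsf = 1)
  expect_gt(sk2$path[1, 1], 95)
  expect_error(skeletonize(matrix(FALSE, 5, 5)), "empty")
})

test_that("locate_poi interpolates the path and validates s", {
  m <- matrix(FALSE, 40, 130)
  m[18:22, 11:111] <- TRUE
  sk <- skeletonize(m, head = c(20, 11), dsf = 1, smooth = 0)
  expect_equal(locate_poi(sk, 0)[1, ], sk$path[1, ], tolerance = 1e-9)
  expect_equal(locate_poi(sk, 1)[1, ], sk$path[nrow(sk$path), ],
               tolerance = 1e-9)
  mid <- locate_poi(sk, 0.5)
  expect_equal(mid[1, 2], 19.5, tolerance = 1)
  expect_equal(mid[1, 1], (sk$path[1, 1] + sk$path[nrow(sk$path), 1]) / 2,
               tolerance = 1)
  expect_error(locate_poi(sk, 1.2), "\\[0, 1\\]")
})

test_that("skeleton length and s stay faithful on real motion", {
  ds <- default_dataset()
  tr <- default_track()
  lens <- tr$summary$skel_length_um
  true_len <- vapply(ds$poses, function(p) max(p$arclen), numeric(1))
  expect_lt(abs(mean(lens) / mean(true_len) - 1), 0.05)
  for (i in seq(1, 120, by = 10))
    expect_true(all(diff(tr$frames[[i]]$skel$s) > 0))
})

test_that("head assignment is right on at least 90% of jittering frames", {
  ds <- default_dataset()
  tr <- default_track()
  ok <- vapply(seq_along(tr$frames), function(i) {
    o <- tr$frames[[i]]
    if (!isTRUE(o$present)) return(NA)
    gh <- ds$poses[[i]]$points[1, ]
    gt <- ds$poses[[i]]$points[nrow(ds$poses[[i]]$points), ]
    sum((o$head_um - gh)^2) < sum((o$head_um - gt)^2)
  }, logical(1))
  expect_gte(mean(ok, na.rm = TRUE), 0.9)
})

test_that("speed estimate recovers ground truth and scales linearly", {
  # stationary worm
  sk <- list(path = cbind(c(0, 100), c(0, 0)), arclen = c(0, 100),
             length_um = 100)
  hist <- matrix(rep(c(50, 0), each = 4), 4, 2)
  expect_equal(estimate_velocity(hist, sk), 0)
  # pure translation at the default speed
  tr <- memo("straight_track", track_video(straight_dataset()))
  v_true <- 130 / 1200 / 12
  expect_equal(mean(tr$summary$v[15:140]), v_true, tolerance = 0.1)
  # doubling the generator speed doubles the estimate
  ds2 <- memo("straight2x", generate_dataset(straight_kin(speed = 260,
                                                          duration = 6,
                                                          seed = 22L)))
  tr2 <- memo("straight2x_track", track_video(ds2))
  expect_equal(mean(tr2$summary$v[15:70]) / mean(tr$summary$v[15:140]), 2,
               tolerance = 0.1)
})
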