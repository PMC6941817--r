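# Synthetic worm videos: centerline kinematics, rendering, slicing and the
# cross-section phantom library.

test_that("degenerate wave gives a straight centerline of nominal length", {
  kin <- straight_kin(duration = 1)
  pose <- generate_centerline(kin, 0)
  expect_equal(max(pose$arclen), 1200, tolerance = 0.01)
  # all points on one line: lateral spread of the (head-anchored) direction
  d <- sweep(pose$points, 2, pose$points[1, ])
  u <- d[nrow(d), ] / sqrt(sum(d[nrow(d), ]^2))
  lateral <- d[, 1] * (-u[2]) + d[, 2] * u[1]
  expect_lt(max(abs(lateral)), 1e-6)
})

test_that("head advances at speed / frame_rate along the track", {
  kin <- worm_kinematics(head_jitter_std = 0, undulation_frequency = 0,
                         duration = 6, seed = 7L)
  path <- wormmri:::worm_path(kin)
  heads <- t(vapply(0:60, function(f)
    generate_centerline(kin, f, path)$points[1, ], numeric(2)))
  step <- sqrt(rowSums(diff(heads)^2))
  expect_equal(mean(step), kin$speed / kin$frame_rate, tolerance = 0.05)
  expect_lt(max(abs(step - kin$speed / kin$frame_rate)) /
              (kin$speed / kin$frame_rate), 0.05)
})

test_that("poses conserve arc length and uniform spacing at default motion", {
  ds <- tiny_dataset()
  for (i in seq(1, length(ds$poses), by = 5)) {
    p <- ds$poses[[i]]
    expect_equal(max(p$arclen), 1200, tolerance = 0.01)
    spacing <- diff(p$arclen)
    expect_lt(diff(range(spacing)) / mean(spacing), 0.02)
    expect_true(all(diff(p$s) > 0))
  }
})

test_that("same seed reproduces identical poses and frames", {
  kin <- worm_kinematics(duration = 1, seed = 99L)
  d1 <- generate_dataset(kin)
  d2 <- generate_dataset(kin)
  expect_identical(d1$poses[[5]]$points, d2$poses[[5]]$points)
  expect_identical(d1$frames[[5]], d2$frames[[5]])
  expect_identical(d1$phantoms[[10]]$intensities,
                   d2$phantoms[[10]]$intensities)
})

test_that("zero speed leaves all poses identical apart from head jitter", {
  kin <- worm_kinematics(speed = 0, head_jitter_std = 0,
                         undulation_frequency = 0, duration = 1, seed = 5L)
  d <- generate_dataset(kin, render = FALSE)
  expect_equal(d$poses[[1]]$points, d$poses[[10]]$points, tolerance = 1e-12)
})

test_that("slice_worm produces the stated geometry", {
  pose <- generate_centerline(straight_kin(duration = 1), 0)
  sl <- slice_worm(pose, 50, body_length = 1200)
  expect_identical(sl$thickness[1], 24)
  expect_equal(sl$s_center, (1:50 - 0.5) / 50)
  # normals perpendicular to tangents everywhere
  expect_lt(max(abs(sl$tx * sl$nx + sl$ty * sl$ny)), 1e-9)
  # straight worm: all slice planes parallel (constant normal)
  expect_lt(max(abs(diff(sl$nx))) + max(abs(diff(sl$ny))), 1e-6)
  s1 <- slice_worm(pose, 1)
  expect_equal(s1$s_center, 0.5)
  expect_equal(s1$thickness, max(pose$arclen))
})

test_that("phantom build: background removal, inversion, downsampling", {
  # constant white source becomes an all-zero phantom
  white <- matrix(1, 128, 128)
  ph <- build_slice_phantoms(list(white), n_slices = 1)
  expect_true(all(ph[[1]]$intensities == 0))
  # bright disc on removed background: oracle = manual invert + block mean
  src <- matrix(1, 128, 128)
  xx <- matrix(1:128, 128, 128, byrow = TRUE); yy <- t(xx)
  disc <- (xx - 64.5)^2 + (yy - 64.5)^2 <= 30^2
  src[disc] <- 0.9
  ph <- build_slice_phantoms(list(src), n_slices = 1)[[1]]$intensities
  manual <- matrix(0, 128, 128)
  manual[disc] <- 1 - 0.9
  grp <- rep(1:64, each = 2)
  oracle <- t(rowsum(t(rowsum(manual, grp) / 2), grp) / 2)
  dimnames(oracle) <- NULL
  expect_equal(ph, oracle, tolerance = 1e-12)
  # slab centers for a full 50-slice library
  ph50 <- build_slice_phantoms(synthetic_sections(50, seed = 2), 50)
  expect_length(ph50, 50)
  expect_equal(ph50[[7]]$s_center, 6.5 / 50)
  expect_true(all(vapply(ph50, function(p) all(dim(p$intensities) == 64),
                         TRUE)))
})

test_that("inversion is an involution on the background-removed source", {
  src <- synthetic_sections(3, seed = 4)[[2]]
  rb <- remove_background_section(src)
  twice <- invert_section(invert_section(rb$img, rb$fg), rb$fg)
  expect_equal(twice, rb$img, tolerance = 1e-12)
})

test_that("renderer draws a dark tube on a static background", {
  optics <- worm_optics(noise_sd = 0)
  bg <- render_background(optics, seed = 8L)
  empty <- structure(list(frame = 0L, points = NULL, s = numeric(0),
                          width = numeric(0), arclen = numeric(0)),
                     class = "centerline_pose")
  fr <- render_frame(empty, optics, bg)
  expect_equal(unclass(fr), bg, ignore_attr = TRUE)
  kin <- straight_kin(duration = 1)
  pose <- generate_centerline(kin, 0)
  pose$points <- sweep(pose$points, 2, c(200, 400 - pose$points[1, 2]), `+`)
  fr <- render_frame(pose, optics, bg)
  mid <- pose$points[50, ] / optics$pixel_size
  expect_lt(fr[round(mid[2]), round(mid[1])],
            bg[round(mid[2]), round(mid[1])] - 0.3)
  # background pixels far from the worm are untouched
  expect_equal(fr[1:20, 1:20], bg[1:20, 1:20], ignore_attr = TRUE)
  # out-of-bounds centerline raises
  pose$points[1, ] <- c(-50, -50)
  expect_error(render_frame(pose, optics, bg), "outside")
})

test_that("default dataset has 120 frames and 50 phantoms", {
  ds <- default_dataset()
  expect_length(ds$poses, 120)
  expect_length(ds$frames, 120)
  expect_length(ds$phantoms, 50)
  expect_true(all(vapply(ds$frames, function(f) all(f >= 0 & f <= 1), TRUE)))
})
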