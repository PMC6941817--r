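# Gradient-echo acquisition: encoding contract, FoV geometry, acquisition
# modes and reconstruction.

test_that("encode_line matches the direct double-sum DFT", {
  set.seed(7)
  for (i in 1:3) {
    img <- matrix(runif(64 * 64), 64)
    oracle <- brute_dft(img)
    for (J in c(1, 9, 33, 64)) {
      line <- encode_line(img, J)
      expect_lt(max(Mod(line - oracle[J, ])) / max(Mod(oracle[J, ])), 1e-10)
    }
  }
  expect_error(encode_line(matrix(0, 64, 64), 65), "out of range")
  expect_true(all(encode_line(matrix(0, 64, 64), 5) == 0))
  # single unit voxel at the grid center: constant magnitude 1, and the
  # DC line (J = N/2 + 1) is real positive
  delta <- matrix(0, 64, 64); delta[33, 33] <- 1
  expect_equal(Mod(encode_line(delta, 17)), rep(1, 64), tolerance = 1e-12)
  expect_equal(encode_line(delta, 33)[33], 1 + 0i, tolerance = 1e-12)
})

test_that("true slice lookup returns the phantom exactly on matching grids", {
  ds <- tiny_dataset()
  res <- ds$phantoms[[1]]$in_plane_resolution
  tru <- true_slice_image(ds, ds$phantoms[[25]]$s_center, voxel_um = res)
  expect_equal(tru, ds$phantoms[[25]]$intensities, tolerance = 1e-12)
  # frame does not change the appearance
  tru2 <- true_slice_image(ds, ds$phantoms[[25]]$s_center, frame = 10,
                           voxel_um = res)
  expect_identical(tru, tru2)
  # boundary coordinate snaps to the nearest center, ties to the lower slab
  expect_equal(true_slice_image(ds, 0.5),
               true_slice_image(ds, ds$phantoms[[25]]$s_center))
  expect_error(true_slice_image(ds, 1.5), "\\[0, 1\\]")
})

test_that("observed FoV equals the true slice for a perfect gradient center", {
  ds <- straight_dataset()
  s <- ds$phantoms[[25]]$s_center
  pl <- wormmri:::plan_from_pose(ds$poses[[1]], s, 1.6)
  obs <- observed_fov_image(ds, pl, 1)
  expect_equal(obs, true_slice_image(ds, s), tolerance = 1e-9)
  # curved worm: agreement within discretisation error
  dsc <- tiny_dataset()
  plc <- wormmri:::plan_from_pose(dsc$poses[[5]], s, 1.6)
  obsc <- observed_fov_image(dsc, plc, 5)
  expect_lt(mean(abs(obsc - true_slice_image(dsc, s))), 0.01)
})

test_that("in-plane gradient offset shifts the image with zero fill", {
  ds <- straight_dataset()
  s <- ds$phantoms[[25]]$s_center
  fr <- pose_frame(ds$poses[[1]], s)
  vox <- 1.6
  pl <- slice_plan(fr$point + 10 * vox * fr$normal, fr$normal, vox)
  obs <- observed_fov_image(ds, pl, 1)
  tru <- true_slice_image(ds, s)
  # shifting G_C by +10 voxels along xi moves content 10 rows down the
  # xi axis and zero-fills the vacated rows
  expect_equal(obs[1:54, ], tru[11:64, ], tolerance = 1e-9)
  # G_C far outside the worm sees nothing
  pl2 <- slice_plan(fr$point + c(0, 5000), fr$normal, vox)
  expect_true(all(observed_fov_image(ds, pl2, 1) == 0))
})

test_that("static acquisition is the DFT of the true slice and inverts", {
  ds <- tiny_dataset()
  p <- sequence_params(mode = "static", start_frame = 5L, n_lines = 64L)
  ks <- run_gre(ds, p, 0.5)
  tru <- true_slice_image(ds, 0.5, voxel_um = ks$voxel_um)
  expect_lt(max(Mod(ks$k - brute_dft(tru))) / max(Mod(ks$k)), 1e-10)
  rec <- reconstruct(ks)
  expect_lt(max(abs(rec - tru)), 1e-6)
  expect_true(all(reconstruct(matrix(complex(real = 0), 64, 64)) == 0))
})

test_that("oracle acquisition of a rigidly translating worm matches static", {
  ds <- straight_dataset()
  p_o <- sequence_params(mode = "oracle", start_frame = 5L)
  p_s <- sequence_params(mode = "static", start_frame = 5L)
  ks_o <- run_gre(ds, p_o, 0.6)
  ks_s <- run_gre(ds, p_s, 0.6)
  expect_lt(max(Mod(ks_o$k - ks_s$k)) / max(Mod(ks_s$k)), 1e-6)
})

test_that("k-space magnitude obeys the shift theorem", {
  ds <- tiny_dataset()
  tru <- true_slice_image(ds, 0.5)
  # circular shift leaves the magnitude spectrum unchanged and the
  # reconstruction is the shifted image
  shifted <- tru[c(11:64, 1:10), ]
  K2 <- wormmri:::dft_centered(shifted)
  expect_equal(Mod(K2), Mod(wormmri:::dft_centered(tru)), tolerance = 1e-9)
  expect_equal(unclass(reconstruct(K2)), shifted, tolerance = 1e-9)
})

test_that("run_gre validates inputs and modes differ as expected", {
  ds <- tiny_dataset()
  tr <- tiny_track()
  expect_error(run_gre(ds, sequence_params(mode = "oracle"), 0.5),
               "too short")
  expect_error(sequence_params(TE = 100, TR = 83), "TR > TE")
  p_pred <- sequence_params(mode = "prediction", horizon = 1L,
                            start_frame = 12L, n_lines = 16L)
  p_np <- sequence_params(mode = "no_prediction", horizon = 1L,
                          start_frame = 12L, n_lines = 16L)
  expect_error(run_gre(ds, p_pred, 0.5), "track")
  ks_p <- run_gre(ds, p_pred, 0.5, track = tr)
  ks_n <- run_gre(ds, p_np, 0.5)
  expect_equal(dim(ks_p$k), c(16L, 64L))
  expect_gt(max(Mod(ks_p$k - ks_n$k)), 0)
  # bookkeeping covers every line at the right frame
  expect_equal(ks_p$per_line$frame, 12:27)
})
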