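# Tracking stage: multiplane splitting, bead localization, sharpness
# metric, axial calibration and whole-video tracking on rendered fixtures.

test_that("multiplane split is lossless and labels round-trip", {
  fr <- matrix(stats::rnorm(300 * 300), 300, 300)
  mp <- split_multiplane(fr, 0.79e-6)
  expect_length(mp$sub_images, 9L)
  expect_true(all(vapply(mp$sub_images, function(s)
    identical(dim(s), c(100L, 100L)), TRUE)))
  expect_identical(sort(mp$plane_labels), -4:4)
  expect_identical(reassemble_multiplane(mp), fr)

  # paint each tile with its plane label and read it back
  painted <- matrix(0, 30, 30)
  for (row in 1:3) for (col in 1:3)
    painted[(row - 1) * 10 + 1:10, (col - 1) * 10 + 1:10] <-
      3 * (row - 1) + (col - 1) - 4
  mp2 <- split_multiplane(painted, 0.79e-6)
  expect_identical(vapply(mp2$sub_images, function(s) s[1, 1], 0),
                   as.numeric(mp2$plane_labels))

  expect_error(split_multiplane(matrix(0, 100, 99), 1e-6), "100x99")
})

test_that("bead localization is exact on symmetric frames and flags degenerate input", {
  vid <- render_bead_video(static_traj(), 0.25e-6, c(49, 49))
  loc <- locate_xy(vid[, , 1])
  expect_true(loc$ok)
  expect_equal(loc$x_px, 24, tolerance = 1e-6)
  expect_equal(loc$y_px, 24, tolerance = 1e-6)

  expect_false(locate_xy(matrix(5, 40, 40))$ok)
})

test_that("sub-pixel positions are recovered within 0.05 px at contrast-to-noise 20", {
  # single frame at an asymmetric sub-pixel position
  tr <- static_traj(x = -0.2 * 0.25e-6, y = 1.7 * 0.25e-6)
  vid <- render_bead_video(tr, 0.25e-6, c(48, 48), noise_sigma = 30,
                           seed = 3)
  loc <- locate_xy(vid[, , 1])
  expect_lt(abs(loc$x_px - attr(vid, "true_x_px")[1]), 0.05)
  expect_lt(abs(loc$y_px - attr(vid, "true_y_px")[1]), 0.05)

  # render-and-recover RMS over a diffusing sequence
  ctx <- thick_ctx()
  trd <- simulate_free_diffusion(ctx, 0.02, 80L, n_axes = 2L, seed = 4)
  vid2 <- render_bead_video(trd, 0.25e-6, c(48, 48), noise_sigma = 30,
                            seed = 5)
  errs <- vapply(1:80, function(i) {
    l <- locate_xy(vid2[, , i])
    c(l$x_px - attr(vid2, "true_x_px")[i],
      l$y_px - attr(vid2, "true_y_px")[i])
  }, numeric(2L))
  expect_lt(sqrt(mean(errs^2)), 0.05)
})

test_that("localization is equivariant under whole-pixel shifts", {
  # noiseless frames whose content differs by an exact whole-pixel shift
  ps <- 0.25e-6
  base_tr <- static_traj(x = 0.3 * ps, y = -0.45 * ps)
  shift_tr <- static_traj(x = (0.3 - 3) * ps, y = (-0.45 - 5) * ps)
  base <- locate_xy(render_bead_video(base_tr, ps, c(64, 64))[, , 1])
  loc <- locate_xy(render_bead_video(shift_tr, ps, c(64, 64))[, , 1])
  expect_equal(loc$x_px, base$x_px - 3, tolerance = 1e-9)
  expect_equal(loc$y_px, base$y_px - 5, tolerance = 1e-9)
})

test_that("sharpness ranks focus, is zero on flat images and unimodal in z", {
  sharp <- render_bead_video(static_traj(z = 0), 0.25e-6)[, , 1]
  blurred <- render_bead_video(static_traj(z = 2e-6), 0.25e-6)[, , 1]
  expect_gt(sharpness(sharp), sharpness(blurred))
  expect_identical(sharpness(matrix(7, 20, 20)), 0)

  zs <- seq(-3e-6, 3e-6, length.out = 25L)
  prof <- vapply(zs, function(z)
    sharpness(render_bead_video(static_traj(z = z), 0.25e-6)[, , 1]),
    numeric(1L))
  peak <- which.max(prof)
  expect_equal(zs[peak], 0, tolerance = 1e-9)
  expect_true(all(diff(prof[1:peak]) > 0))
  expect_true(all(diff(prof[peak:length(prof)]) < 0))
})

test_that("z calibration covers the sweep, validates input and serializes exactly", {
  zg <- seq(-3e-6, 3e-6, length.out = 25L)
  cal <- calibrate_z(multiplane_sweep(zg), zg)
  expect_gte(diff(cal$valid_range), 0.8 * diff(range(zg)))

  expect_error(calibrate_z(multiplane_sweep(c(-1e-6, 0, 0, 1e-6, 2e-6)),
                           c(-1e-6, 0, 0, 1e-6, 2e-6)), "non-monotone")
  expect_error(calibrate_z(multiplane_sweep(c(-1e-6, 0, 1e-6)),
                           c(-1e-6, 0, 1e-6)), "at least 5")

  tmp <- tempfile(fileext = ".json")
  write_calibration(cal, tmp)
  cal2 <- read_calibration(tmp)
  expect_identical(cal2$z_grid, cal$z_grid)
  expect_identical(cal2$profiles, cal$profiles)
  expect_identical(cal2$valid_range, cal$valid_range)
})

test_that("axial localization reaches sub-plane precision and flags out-of-range", {
  zg <- seq(-2.5e-6, 2.5e-6, length.out = 21L)
  cal <- calibrate_z(multiplane_sweep(zg), zg)
  dz <- 0.79e-6

  fr0 <- multiplane_sweep(0)[, , 1]
  lz0 <- locate_z(split_multiplane(fr0, dz), cal)
  expect_true(lz0$ok)
  expect_lt(abs(lz0$z), dz / 10)

  fr1 <- multiplane_sweep(dz)[, , 1]
  lz1 <- locate_z(split_multiplane(fr1, dz), cal)
  expect_lt(abs(lz1$z - dz), 60e-9)

  # bead two plane spacings up: sharpest sub-image is plane +2
  fr2 <- multiplane_sweep(2 * dz)[, , 1]
  mp2 <- split_multiplane(fr2, dz)
  sig <- vapply(mp2$sub_images, sharpness, numeric(1L))
  expect_identical(mp2$plane_labels[which.max(sig)], 2L)

  frout <- multiplane_sweep(3.2e-6)[, , 1]
  expect_false(locate_z(split_multiplane(frout, dz), cal)$ok)
})

test_that("a static noiseless video tracks to a zero-variance trajectory", {
  vid <- render_bead_video(static_traj(n = 12L), 0.25e-6)
  tk <- track_video(vid, "2d", ctx = thick_ctx())
  expect_length(tk$t, 12L)
  expect_equal(suppressWarnings(as.numeric(plateau_variance(tk))), 0)
})

test_that("failed frames are dropped, recorded, and never interpolated", {
  vid <- render_bead_video(static_traj(n = 20L), 0.25e-6)
  vid[, , 8] <- 500   # uniform frames: localization must fail
  vid[, , 9] <- 500
  vid[, , 10] <- 500
  expect_warning(tk <- track_video(vid, "2d", ctx = thick_ctx()),
                 "dropped")
  expect_identical(tk$dropped_frames, c(8L, 9L, 10L))
  expect_length(tk$t, 10L)  # longest contiguous run: frames 11..20

  uniform <- array(500, dim = c(24, 24, 3))
  expect_error(track_video(uniform, "2d", pixel_size = 1e-6,
                           frame_rate = 100, ctx = thick_ctx()),
               "no frame")
})

test_that("multiplane tracking recovers the axial trap variance end to end", {
  ctx <- water_ctx()
  kappa_z <- 2e-7
  trap <- trap_params(3.2e-7, 3.2e-7, kappa_z)
  tr <- simulate_trapped_bead(ctx, trap, 0.025, 2000L, seed = 31)
  vid <- render_multiplane_video(tr, 0.25e-6, c(48, 48),
                                 plane_spacing = 0.79e-6,
                                 noise_sigma = 10, seed = 32)
  zg <- seq(-2.5e-6, 2.5e-6, length.out = 21L)
  cal <- calibrate_z(multiplane_sweep(zg, ctx = ctx), zg)
  tk <- track_video(vid, "multiplane", ctx = ctx, cal = cal)
  expect_gt(length(tk$t), 1800L)
  vz <- as.numeric(plateau_variance(tk, "z"))
  expect_equal(vz, kBT(ctx) / kappa_z, tolerance = 0.2)
})
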