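test_that("sheet generator is deterministic and static when nothing moves", {
  spec <- sheet_phantom_spec(image_shape_px = c(60, 80), n_frames = 3,
                             n_cells = 40, wave_speed_um_min = 0,
                             noise_model = NULL, seed = 5)
  a <- make_sheet_timelapse(spec)
  b <- make_sheet_timelapse(spec)
  expect_identical(a$stack$data, b$stack$data)
  # no wave, no drift, no noise: all frames identical
  expect_equal(a$stack$data[2, 1, 1, , ], a$stack$data[1, 1, 1, , ])
  expect_equal(a$stack$data[3, 1, 2, , ], a$stack$data[1, 1, 2, , ])
  expect_true(min(a$stack$data) >= 0)
  expect_error(sheet_phantom_spec(wave_decay_len_um = 0), "decay")
})

test_that("pure rigid drift shows up at the programmed phase-correlation peak", {
  spec <- sheet_phantom_spec(image_shape_px = c(90, 120), n_frames = 3,
                             n_cells = 70, wave_amplitude_um = 0,
                             rigid_drift = c(3, 0, 0),
                             noise_model = NULL, seed = 6)
  sh <- make_sheet_timelapse(spec)
  f1 <- sh$stack$data[1, 1, 1, , ]
  f2 <- sh$stack$data[2, 1, 1, , ]
  inner <- 10:80                              # avoid the warp border
  shift <- phase_corr_shift(f1[inner, 11:110], f2[inner, 11:110])
  expect_equal(unname(shift[1]), 3, tolerance = 0.1)
  expect_equal(unname(shift[2]), 0, tolerance = 0.1)
})

test_that("sheet ground truth matches the analytic displacement model", {
  sh <- small_sheet()
  gt <- sh$ground_truth
  spec_v <- gt$params$wave_speed_um_min
  expect_equal(gt$wavefront_um,
               spec_v / 60 * gt$times_s)
  # crest displacement (evaluated when the wave passes each point) decays
  # with distance and is capped by A
  v <- gt$params$wave_speed_um_min / 60
  d_near <- 15 * gt$params$pixel_size_um
  d_far <- 195 * gt$params$pixel_size_um
  u_near <- sheet_displacement(gt, 20, 80, t_s = d_near / v)$u_um
  u_far <- sheet_displacement(gt, 200, 80, t_s = d_far / v)$u_um
  expect_true(all(c(u_near, u_far) <= gt$params$wave_amplitude_um + 1e-12))
  expect_gt(u_near, u_far)
})

test_that("calcium generator obeys its stated edge cases", {
  base <- list(image_shape_px = c(48, 200), n_frames = 6,
               n_prewound_frames = 2, noise_model = NULL,
               wound_centroid_px = c(3, 24), seed = 8)
  # stationary front stays at the wound margin
  s0 <- do.call(calcium_phantom_spec, c(base, front_speed_um_min = 0))
  ca0 <- make_calcium_timelapse(s0)
  expect_true(all(ca0$ground_truth$front_position_um == 0))
  last <- ca0$stack$data[6, 1, 1, , ]
  first <- ca0$stack$data[1, 1, 1, , ]
  # far from the wound nothing activates (margin sigmoid has decayed away)
  expect_lt(max(abs(last[, 170:200] - first[, 170:200]) / first[, 170:200]),
            0.005)
  # at the wound margin activation is present
  expect_gt(mean(last[, 1:10]) / mean(first[, 1:10]), 1.5)
  # front positions lie on a line of the programmed slope
  s1 <- do.call(calcium_phantom_spec, c(base, front_speed_um_min = 100))
  ca1 <- make_calcium_timelapse(s1)
  active <- ca1$ground_truth$front_position_um > 0
  t_act <- ca1$ground_truth$times_s[active] -
    ca1$ground_truth$times_s[base$n_prewound_frames + 1]
  expect_equal(ca1$ground_truth$front_position_um[active],
               100 / 60 * t_act)
  # zero peak_dff gives a flat downstream kymograph
  s2 <- do.call(calcium_phantom_spec, c(base, peak_dff = 0))
  ca2 <- make_calcium_timelapse(s2)
  ky <- gcamp_kymograph(ca2$stack, small_wound(), n_prewound_frames = 2)
  expect_lt(max(abs(ky$dff), na.rm = TRUE), 1e-9)
  expect_error(do.call(calcium_phantom_spec, c(base, peak_dff = -1)),
               "peak_dff")
})

test_that("cluster phantom sidecar volumes equal the closed-form mensuration", {
  expect_equal(woundwave:::.analytic_volume("hemisphere", c(10, 10, 10)),
               2 / 3 * pi * 1000)
  expect_equal(woundwave:::.analytic_volume("slab", c(5, 10, 2.5)),
               8 * 5 * 10 * 2.5)
  expect_equal(woundwave:::.analytic_volume("ellipsoid", c(3, 4, 5)),
               4 / 3 * pi * 60)
  cl <- make_cluster_stack(cluster_phantom_spec(
    radii_um = 10, volume_scale_after = 1.0, pixel_size_um = 0.5,
    noise_model = NULL, seed = 2))
  expect_equal(cl$ground_truth$analytic_volume_um3[1],
               2 / 3 * pi * 1000, tolerance = 1e-12)
  expect_equal(cl$ground_truth$analytic_volume_um3[1],
               cl$ground_truth$analytic_volume_um3[2])
})

test_that("calibration images follow the programmed binding curve and vignette", {
  cal0 <- make_calibration_images(imax = 2, kd_mM = 100,
                                  concentrations_mM = c(0, 100),
                                  vignette_strength = 0, background_level = 0,
                                  noise_sd = 0)
  expect_lt(mean(cal0$images[[1]]), 1e-12)            # zero concentration
  expect_equal(mean(cal0$images[[2]]), 1, tolerance = 1e-12)  # Imax/2 at Kd
  calv <- make_calibration_images(vignette_strength = 0.4,
                                  background_level = 0, noise_sd = 0)
  img <- calv$images[[4]]
  H <- nrow(img); W <- ncol(img)
  corner <- img[1, 1]; center <- img[(H + 1) / 2, (W + 1) / 2]
  expect_equal(corner / center, calv$flatfield[1, 1] /
                 calv$flatfield[(H + 1) / 2, (W + 1) / 2], tolerance = 1e-9)
  expect_error(make_calibration_images(kd_mM = 0), "kd")
})

test_that("ground-truth sidecars round-trip losslessly through JSON", {
  sh <- small_sheet()
  p <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sh$ground_truth, p)
  gt2 <- read_ground_truth(p)
  expect_equal(gt2$wavefront_um, sh$ground_truth$wavefront_um)
  expect_equal(gt2$params$wave_speed_um_min,
               sh$ground_truth$params$wave_speed_um_min)
  expect_equal(gt2$drift_cumulative, sh$ground_truth$drift_cumulative,
               ignore_attr = TRUE)
})
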