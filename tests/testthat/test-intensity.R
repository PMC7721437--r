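calcium_small <- function() fixture("calcium_small", function() {
  make_calcium_timelapse(calcium_phantom_spec(
    image_shape_px = c(64, 360), n_frames = 10, front_speed_um_min = 120,
    n_prewound_frames = 2, peak_dff = 1.5,
    wound_centroid_px = c(4, 32), noise_model = list(gaussian_sd = 1),
    seed = 17))
})

calcium_wound <- function() {
  wound_annotation(rbind(c(2, 20), c(7, 20), c(7, 44), c(2, 44)),
                   centroid = c(4, 32))
}

test_that("delta-F/F0 formula and ratio invariance hold", {
  ca <- calcium_small()
  ky <- gcamp_kymograph(ca$stack, calcium_wound(), n_prewound_frames = 2)
  # pre-wound bins are zero by construction
  expect_lt(max(abs(ky$dff[, 1:2]), na.rm = TRUE), 0.05)
  # doubling both channels leaves dff unchanged
  st2 <- ca$stack
  st2$data <- st2$data * 2
  ky2 <- gcamp_kymograph(st2, calcium_wound(), n_prewound_frames = 2)
  expect_equal(ky2$dff, ky$dff, tolerance = 1e-12)
  # F_t = 2 F_0 in the signal channel gives dff = 1
  arr <- array(50, c(2, 1, 2, 16, 40))
  arr[2, 1, 1, , ] <- 100
  st <- timelapse_stack(arr, 1)
  w <- wound_annotation(rbind(c(1, 4), c(3, 4), c(3, 12), c(1, 12)))
  kyc <- gcamp_kymograph(st, w, n_prewound_frames = 1)
  expect_equal(ky_vals <- kyc$dff[is.finite(kyc$dff[, 2]), 2],
               rep(1, length(ky_vals)))
})

test_that("calcium phantom kymograph reproduces plateau and front trajectory", {
  ca <- calcium_small()
  ky <- gcamp_kymograph(ca$stack, calcium_wound(), n_prewound_frames = 2)
  # plateau behind the front reaches the programmed peak dff
  expect_equal(max(ky$dff, na.rm = TRUE), 1.5, tolerance = 0.1)
  # front position per frame within one bin of the sidecar truth
  gmax <- max(ky$dff, na.rm = TRUE)
  truth <- ca$ground_truth$front_position_um
  cover <- max(ky$bin_centers_um) - 10
  for (t in which(truth > 20 & truth < cover)) {
    above <- which(ky$dff[, t] > gmax / 2)
    front <- ky$bin_centers_um[max(above)]
    expect_lt(abs(front - truth[t]), 10)
  }
  # estimator recovers the programmed speed
  fs <- estimate_front_speed(ky)
  expect_equal(fs$speed_um_min, 120, tolerance = 12)
})

test_that("demons registration meets its identity/recovery/scaling contracts", {
  sh <- small_sheet()
  tex <- sh$stack$data[1, 1, 1, 1:128, 1:128]
  id <- demons_field(tex, tex)
  expect_lt(median(sqrt(id$ux^2 + id$uy^2)), 0.1)
  # known 2 px sinusoidal warp recovered in well-textured regions
  H <- 128; W <- 128
  gx <- matrix(rep(1:W, each = H), H, W); gy <- matrix(rep(1:H, W), H, W)
  ux <- 2 * sin(2 * pi * gy / 64); uy <- 1.5 * cos(2 * pi * gx / 64)
  moving <- woundwave:::warp_image(tex, gx + ux, gy + uy, fill = 0)
  fld <- demons_field(moving, tex)
  expect_lt(fld$mse_after, fld$mse_before)
  g <- woundwave:::image_gradients(tex)
  g2 <- g$gx^2 + g$gy^2
  well <- matrix(FALSE, H, W)
  well[15:114, 15:114] <- TRUE
  well <- well & g2 > stats::quantile(g2, 0.5)
  err2 <- (fld$ux + ux)^2 + (fld$uy + uy)^2
  expect_lt(sqrt(mean(err2[well])), 0.5)
  # pure intensity scaling produces almost no displacement
  sc <- demons_field(tex * 1.3, tex)
  expect_lt(median(sqrt(sc$ux^2 + sc$uy^2)), 0.5)
})

test_that("field composition is consistent with sequential warping", {
  mkfield <- function(ux, uy) structure(list(ux = ux, uy = uy),
                                        class = "DisplacementField")
  z <- matrix(0, 40, 40)
  idc <- compose_fields(list(mkfield(z, z), mkfield(z, z)))
  expect_equal(idc[[2]]$ux, z)
  expect_equal(idc[[2]]$uy, z)
  # translations add
  tr <- compose_fields(list(mkfield(z + 3, z), mkfield(z + 2, z)))
  inner <- 5:30
  expect_equal(tr[[2]]$ux[inner, inner], (z + 5)[inner, inner])
  # random smooth fields: composed warp equals sequential warping
  set.seed(41)
  smooth_field <- function() {
    f <- woundwave:::gauss_blur2d(matrix(rnorm(40 * 40), 40, 40), 4)
    2 * f / max(abs(f))
  }
  f1 <- mkfield(smooth_field(), smooth_field())
  f2 <- mkfield(smooth_field(), smooth_field())
  comp <- compose_fields(list(f1, f2))
  probe <- woundwave:::gauss_blur2d(matrix(runif(40 * 40, 0, 100), 40, 40), 2)
  seq_warp <- woundwave:::warp_by_field(
    woundwave:::warp_by_field(probe, f2), f1)
  one_warp <- woundwave:::warp_by_field(probe, comp[[2]])
  ok <- !is.na(seq_warp) & !is.na(one_warp)
  ok[c(1:6, 35:40), ] <- FALSE; ok[, c(1:6, 35:40)] <- FALSE
  expect_lt(sqrt(mean((seq_warp[ok] - one_warp[ok])^2)), 1)
  expect_error(compose_fields(list(f1, NULL)), "chain")
})

test_that("warped dF/F0 decouples shape from intensity", {
  sh <- dff_sheet()
  frames <- max_project_z(sh$stack, 1)
  flds <- dff_sheet_fields()
  comp <- compose_fields(flds)
  w <- wound_annotation(rbind(c(2, 40), c(9, 40), c(9, 80), c(2, 80)))
  res <- warped_dff_trace(frames, comp, w, exclusion_um = 20,
                          pixel_size_um = sh$stack$pixel_size_um)
  # pure motion, constant intensity: trace stays within +/- 0.05
  expect_true(all(abs(res$trace) <= 0.05))
  # global 10% brightening with no motion: trace = 0.10
  br <- list(frames[[1]], frames[[1]] * 1.1, frames[[1]] * 1.1)
  fb <- lapply(2:3, function(t) demons_field(br[[t]], br[[t - 1]]))
  resb <- warped_dff_trace(br, compose_fields(fb), w, exclusion_um = 20,
                           pixel_size_um = sh$stack$pixel_size_um)
  expect_equal(resb$trace[2:3], c(0.1, 0.1), tolerance = 0.01)
  # motion plus a programmed 30% brightening in a band is recovered
  band <- matrix(0, 120, 150); band[, 60:100] <- 1
  f2b <- frames[[2]] * (1 + 0.3 * band)
  res2 <- warped_dff_trace(list(frames[[1]], f2b), comp[1], w,
                           exclusion_um = 20,
                           pixel_size_um = sh$stack$pixel_size_um)
  # expected: 0.3 times the band's share of the analysed region, computed
  # from the geometry alone (rect wound x in [2,9], y in [40,80]; 20 um
  # exclusion at 0.65 um/px is ~31 px)
  px <- matrix(rep(1:150, each = 120), 120)
  py <- matrix(rep(1:120, 150), 120)
  dx <- pmax(2 - px, px - 9, 0); dy <- pmax(40 - py, py - 80, 0)
  used <- sqrt(dx^2 + dy^2) > 20 / 0.65
  expect_equal(res2$trace[2], 0.3 * mean(band[used]), tolerance = 0.05)
})

test_that("gain applied to a whole movie leaves warped dF/F0 unchanged", {
  sh <- dff_sheet()
  frames <- max_project_z(sh$stack, 1)
  flds <- dff_sheet_fields()
  comp <- compose_fields(flds)
  w <- wound_annotation(rbind(c(2, 40), c(9, 40), c(9, 80), c(2, 80)))
  res1 <- warped_dff_trace(frames, comp, w, exclusion_um = 20,
                           pixel_size_um = 0.65)
  res2 <- warped_dff_trace(lapply(frames, `*`, 7.3), comp, w,
                           exclusion_um = 20, pixel_size_um = 0.65)
  expect_equal(res2$trace, res1$trace, tolerance = 1e-9)
})

test_that("QC exclusion reproduces the printed slope and deviation rules", {
  # constant background: passes
  expect_false(qc_exclusion(rep(500, 10))$excluded)
  # slope 3 against m = 500: 3 > 0.005 * 500 = 2.5 -> excluded
  q <- qc_exclusion(500 + 3 * (0:19), m = 500)
  expect_equal(q$slope_per_frame, 3, tolerance = 1e-9)
  expect_true(q$excluded)
  expect_match(q$reasons, "slope", all = FALSE)
  # slope 2 is under the threshold -> retained
  expect_false(qc_exclusion(500 + 2 * (0:19), m = 500)$excluded)
  # first frame 240 against m = 500: |240 - 500| = 260 > 250 -> excluded
  q2 <- qc_exclusion(c(240, rep(500, 9)), m = 500)
  expect_equal(q2$first_frame_deviation, 260)
  expect_true(q2$excluded)
  expect_match(q2$reasons, "first-frame", all = FALSE)
  # first frame off by 240 < 250 -> the deviation rule does not trigger
  q3 <- qc_exclusion(c(740, rep(500, 19)), m = 500)
  expect_false(any(grepl("first-frame", q3$reasons)))
  expect_error(qc_exclusion(c(1, 2)), "3 frames")
})
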