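test_that("KLT tracks a static texture with sub-0.1 px median displacement", {
  sh <- small_sheet()
  f <- sh$stack$data[1, 1, 1, , ]
  tr <- track_features(list(f, f), max_corners = 400)
  ok <- tr$valid[, 1] & tr$valid[, 2]
  disp <- sqrt((tr$x[ok, 2] - tr$x[ok, 1])^2 + (tr$y[ok, 2] - tr$y[ok, 1])^2)
  expect_gt(sum(ok), 100)
  expect_lt(median(disp), 0.1)
})

test_that("KLT recovers a rigid (3, 2) px/frame shift within 0.2 px", {
  sh <- small_sheet()
  f1 <- sh$stack$data[1, 1, 1, , ]
  f2 <- roll2(f1, 2, 3)
  f3 <- roll2(f2, 2, 3)
  tr <- track_features(list(f1, f2, f3), max_corners = 500)
  ok <- tr$valid[, 1] & tr$valid[, 2]
  expect_equal(median(tr$x[ok, 2] - tr$x[ok, 1]), 3, tolerance = 0.2)
  expect_equal(median(tr$y[ok, 2] - tr$y[ok, 1]), 2, tolerance = 0.2)
})

test_that("KLT matches the generator's decaying displacement wave (< 0.3 px RMSE)", {
  sh <- small_sheet()
  tr <- fixture("small_sheet_tracks", function()
    track_features(sh$stack, max_corners = 1200))
  gt <- sh$ground_truth
  dt <- sh$stack$frame_interval_s
  errs <- c()
  for (t in 3:6) {
    ok <- tr$valid[, t] & tr$valid[, t + 1]
    g_now <- sheet_displacement(gt, tr$x[ok, t], tr$y[ok, t], (t - 1) * dt)
    g_next <- sheet_displacement(gt, tr$x[ok, t], tr$y[ok, t], t * dt)
    pdx <- g_next$ux_px - g_now$ux_px
    pdy <- g_next$uy_px - g_now$uy_px
    odx <- tr$x[ok, t + 1] - tr$x[ok, t]
    ody <- tr$y[ok, t + 1] - tr$y[ok, t]
    errs <- c(errs, (odx - pdx)^2 + (ody - pdy)^2)
  }
  expect_lt(sqrt(mean(errs)), 0.3)
})

test_that("wound-axis projection equals brute-force dot products", {
  w <- small_wound()
  pts <- cbind(c(55, 5, 120), c(80, 80, 30))
  ax <- build_wound_axis(pts, w, pixel_size_um = 2)
  # collinear point 50 px from the centroid projects to 100 um
  expect_equal(project_on_axis(ax, 5 + 50 * ax$direction[1],
                               80 + 50 * ax$direction[2]), 100)
  # perpendicular displacement leaves the coordinate unchanged
  perp <- c(-ax$direction[2], ax$direction[1])
  expect_equal(project_on_axis(ax, 55 + 10 * perp[1], 80 + 10 * perp[2]),
               project_on_axis(ax, 55, 80))
  # random cloud: loop oracle
  set.seed(9)
  rx <- runif(20, 0, 200); ry <- runif(20, 0, 160)
  brute <- vapply(1:20, function(i)
    sum((c(rx[i], ry[i]) - w$centroid) * ax$direction) * 2, 1)
  expect_equal(project_on_axis(ax, rx, ry), brute)
  expect_error(build_wound_axis(rbind(c(5, 80)), w), "coincides")
})

test_that("kymograph arithmetic: unit conversion, bin means, occupancy", {
  # two points moving 1 um/frame at 30 s/frame -> 2 um/min everywhere
  nT <- 5
  x <- rbind(seq(40, 44), seq(80, 84))       # +1 px/frame
  y <- rbind(rep(10, nT), rep(12, nT))
  tr <- make_tracks(x, y, pixel_size_um = 1, frame_interval_s = 30)
  w <- wound_annotation(rbind(c(0, 0), c(2, 0), c(2, 20), c(0, 20)),
                        centroid = c(1, 11))
  ax <- build_wound_axis(tr, w)
  ky <- speed_kymograph(tr, ax, bin_um = 10)
  expect_true(all(abs(ky$mean_speed_um_min[is.finite(ky$mean_speed_um_min)] -
                        2) < 1e-9))
  # occupancy conserves the valid point count per frame
  expect_true(all(colSums(ky$n_points) == 2))
  # two points in one bin with speeds 1 and 3 um/min -> bin mean 2
  x2 <- rbind(c(42, 42.5, 43), c(44, 45.5, 47))  # 0.5 and 1.5 px/frame
  y2 <- matrix(10, 2, 3)
  tr2 <- make_tracks(x2, y2, pixel_size_um = 1, frame_interval_s = 30)
  ky2 <- speed_kymograph(tr2, ax, bin_um = 10)
  expect_equal(ky2$mean_speed_um_min[5, 2], 2)   # bin 40-50 um
  # doubling the frame interval halves reported speeds
  tr3 <- make_tracks(x2, y2, pixel_size_um = 1, frame_interval_s = 60)
  ky3 <- speed_kymograph(tr3, ax, bin_um = 10)
  expect_equal(ky3$mean_speed_um_min[5, 2], 1)
  expect_error(speed_kymograph(tr2, ax, bin_um = 0), "bin_um")
})

test_that("empty bins are missing, never zero", {
  x <- rbind(c(40, 41, 42))
  y <- rbind(c(10, 10, 10))
  tr <- make_tracks(x, y, 1, 30)
  w <- wound_annotation(rbind(c(0, 0), c(2, 0), c(2, 20), c(0, 20)),
                        centroid = c(1, 10))
  ax <- build_wound_axis(tr, w)
  ky <- speed_kymograph(tr, ax, bin_um = 10)
  expect_true(all(is.na(ky$mean_speed_um_min[1, ])))
  expect_true(all(ky$n_points[1, ] == 0))
})

test_that("rotating frames and annotation together leaves the kymograph unchanged", {
  sh <- small_sheet()
  tr <- fixture("small_sheet_tracks", function()
    track_features(sh$stack, max_corners = 1200))
  w <- small_wound()
  ax <- build_wound_axis(tr, w)
  ky <- speed_kymograph(tr, ax)
  # rotate everything by 90 degrees: (x, y) -> (H + 1 - y, x)
  H <- dim(sh$stack$data)[4]
  tr90 <- tr
  tr90$x <- H + 1 - tr$y
  tr90$y <- tr$x
  poly90 <- cbind(H + 1 - w$polygon[, 2], w$polygon[, 1])
  w90 <- wound_annotation(poly90, centroid = c(H + 1 - w$centroid[2],
                                               w$centroid[1]))
  ky90 <- speed_kymograph(tr90, build_wound_axis(tr90, w90))
  same <- is.finite(ky$mean_speed_um_min) & is.finite(ky90$mean_speed_um_min)
  expect_gt(mean(same), 0.5)
  expect_equal(is.finite(ky90$mean_speed_um_min),
               is.finite(ky$mean_speed_um_min))
  expect_equal(ky90$mean_speed_um_min[same], ky$mean_speed_um_min[same],
               tolerance = 1e-6)
})

test_that("relative-velocity correction removes a global drift", {
  # constructed field: wave-like near motion + constant drift everywhere
  set.seed(31)
  n <- 60; nT <- 6
  d0 <- runif(n, 5, 420)                     # 1D start positions (um = px)
  near_v <- ifelse(d0 < 300, 1.5, 0)         # um/frame toward the wound
  drift <- c(0.8, -0.6)
  x <- matrix(NA_real_, n, nT); y <- matrix(NA_real_, n, nT)
  x0 <- 5 + d0; y0 <- runif(n, 10, 90)
  for (t in seq_len(nT)) {
    x[, t] <- x0 - near_v * (t - 1) + drift[1] * (t - 1)
    y[, t] <- y0 + drift[2] * (t - 1)
  }
  tr_drift <- make_tracks(x, y, 1, 60)
  w <- wound_annotation(rbind(c(2, 30), c(8, 30), c(8, 70), c(2, 70)),
                        centroid = c(5, 50))
  ax <- build_wound_axis(tr_drift, w)
  ky_corr <- relative_velocity_correction(tr_drift, ax, cutoff_um = 300)
  # without drift at all
  for (t in seq_len(nT)) {
    x[, t] <- x0 - near_v * (t - 1)
    y[, t] <- y0
  }
  tr_clean <- make_tracks(x, y, 1, 60)
  ky_clean <- speed_kymograph(tr_clean, build_wound_axis(tr_clean, w),
                              max_distance_um = 300)
  nb <- min(nrow(ky_corr$mean_speed_um_min), nrow(ky_clean$mean_speed_um_min))
  a <- ky_corr$mean_speed_um_min[1:nb, ]
  b <- ky_clean$mean_speed_um_min[1:nb, ]
  ok <- is.finite(a) & is.finite(b)
  expect_lt(max(abs(a[ok] - b[ok])), 0.05)
  # far-field-only motion: near-field speeds reflect the cancelled vector
  expect_error(relative_velocity_correction(
    make_tracks(x[d0 < 250, , drop = FALSE], y[d0 < 250, , drop = FALSE], 1, 60),
    ax, cutoff_um = 300), "far-field")
})

test_that("mean speed trace weights bins by occupancy", {
  # build a kymograph by hand: counts (10, 30), speeds (1, 3) -> mean 2.5
  ky <- woundwave:::.kym_new(
    values = matrix(c(1, 3), 2, 4), counts = matrix(c(10L, 30L), 2, 4),
    bin_edges = c(0, 10, 20), times_s = seq(0, 90, 30), variant = "speed")
  trc <- mean_speed_trace(ky, window_um = 300, n_frames = 4)
  expect_equal(trc, rep(2.5, 4))
  # spatially uniform kymograph: trace equals the bin value
  ky_u <- woundwave:::.kym_new(matrix(1.7, 2, 4), matrix(5L, 2, 4),
                               c(0, 10, 20), seq(0, 90, 30), "speed")
  expect_equal(mean_speed_trace(ky_u, 300, 4), rep(1.7, 4))
})

test_that("phase medians agree with a brute-force loop and flip sign", {
  set.seed(32)
  vals <- matrix(rnorm(5 * 12), 5, 12)
  ky <- woundwave:::.kym_new(vals, matrix(1L, 5, 12),
                             seq(0, 50, 10), seq(0, 330, 30), "horizontal")
  phases <- list(p1 = 1:4, p2 = 5:8, p3 = 9:12)
  got <- phase_median_velocity(ky, phases)
  brute <- vapply(phases, function(fr)
    median(vapply(fr, function(t) mean(vals[, t]), 1)), 1)
  expect_equal(got, brute)
  # sign-flipped field gives opposite-sign medians
  ky_neg <- woundwave:::.kym_new(-vals, matrix(1L, 5, 12),
                                 seq(0, 50, 10), seq(0, 330, 30), "horizontal")
  expect_equal(phase_median_velocity(ky_neg, phases), -got)
  expect_error(phase_median_velocity(ky, list(integer(0))), "empty")
  # constant field: median is the constant
  ky_c <- woundwave:::.kym_new(matrix(2, 5, 12), matrix(1L, 5, 12),
                               seq(0, 50, 10), seq(0, 330, 30), "horizontal")
  expect_equal(unname(phase_median_velocity(ky_c, phases)), rep(2, 3))
})

test_that("front-speed estimation: ideal front, stationary front, wave phantom", {
  # ideal front advancing one 10-um bin per 30-s frame -> 20 um/min
  nb <- 20; nT <- 15
  vals <- matrix(0, nb, nT)
  for (t in 1:nT) vals[seq_len(min(t + 1, nb)), t] <- 1
  ky <- woundwave:::.kym_new(vals, matrix(1L, nb, nT),
                             seq(0, nb * 10, 10), (0:(nT - 1)) * 30, "speed")
  fs <- estimate_front_speed(ky)
  expect_equal(fs$speed_um_min, 20, tolerance = 1e-9)
  expect_false(fs$flagged)
  # stationary activation -> speed 0, flagged as non-advancing
  vals0 <- matrix(0, nb, nT); vals0[1:3, ] <- 1
  ky0 <- woundwave:::.kym_new(vals0, matrix(1L, nb, nT),
                              seq(0, nb * 10, 10), (0:(nT - 1)) * 30, "speed")
  fs0 <- estimate_front_speed(ky0)
  expect_equal(fs0$speed_um_min, 0, tolerance = 1e-9)
  # sheet phantom: kymograph ridge slope matches the programmed wave speed
  sh <- small_sheet()
  tr <- fixture("small_sheet_tracks", function()
    track_features(sh$stack, max_corners = 1200))
  ky_w <- speed_kymograph(tr, build_wound_axis(tr, small_wound()))
  fs_w <- estimate_front_speed(ky_w)
  expect_equal(fs_w$speed_um_min,
               sh$ground_truth$params$wave_speed_um_min, tolerance = 4)
})
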