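#' Reference-normalized delta-F/F0 calcium kymograph
#'
#' Bins pixels by horizontal distance from the wound centroid in `bin_um`
#' increments. In each bin and frame the calcium-indicator intensity is
#' normalized to the nuclear-reference intensity in that bin (cancelling
#' expression variation), and the normalized signal is expressed relative to
#' its pre-wound baseline: `dff = (F_t - F_0) / F_0` with `F_0` the mean of
#' the normalized signal over the pre-wound frames.
#'
#' @param stack two-channel [timelapse_stack()].
#' @param wound a [wound_annotation()].
#' @param bin_um bin pitch (um).
#' @param n_prewound_frames frames before wounding defining `F_0` (>= 1).
#' @param signal_channel,reference_channel channel indices or names.
#' @param background scalar or matrix subtracted from both projections.
#' @return object of class `DffKymograph` with `dff[bin, t]`, the
#'   normalized signal `f`, `bin_centers_um`, `bin_edges_um`, `times_s`.
#' @export
gcamp_kymograph <- function(stack, wound, bin_um = 10,
                            n_prewound_frames = 1,
                            signal_channel = 1, reference_channel = 2,
                            background = 0) {
  stopifnot(inherits(stack, "TimelapseStack"))
  if (n_prewound_frames < 1) stop("need at least one pre-wound frame")
  G <- max_project_z(stack, signal_channel)
  R <- max_project_z(stack, reference_channel)
  H <- nrow(G[[1]]); W <- ncol(G[[1]])
  px <- stack$pixel_size_um
  d_um <- abs(matrix(rep(seq_len(W), each = H), H, W) -
                wound$centroid[1]) * px
  edges <- seq(0, ceiling(max(d_um) / bin_um) * bin_um + bin_um, by = bin_um)
  nb <- length(edges) - 1
  bin_idx <- pmin(findInterval(as.vector(d_um), edges), nb)
  nT <- length(G)
  f <- matrix(NA_real_, nb, nT)
  for (t in seq_len(nT)) {
    g <- pmax(G[[t]] - background, 0)
    r <- pmax(R[[t]] - background, 0)
    sg <- rowsum(as.vector(g), bin_idx)
    sr <- rowsum(as.vector(r), bin_idx)
    ids <- as.integer(rownames(sg))
    ratio <- ifelse(sr > 0, sg / sr, NA_real_)
    f[ids, t] <- ratio
  }
  f0 <- rowMeans(f[, seq_len(n_prewound_frames), drop = FALSE])
  dff <- sweep(f, 1, f0, "/") - 1
  dff[!is.finite(dff)] <- NA_real_
  structure(list(dff = dff, f = f, f0 = f0,
                 bin_edges_um = edges,
                 bin_centers_um = (head(edges, -1) + tail(edges, -1)) / 2,
                 times_s = (seq_len(nT) - 1) * stack$frame_interval_s,
                 n_prewound_frames = n_prewound_frames),
            class = "DffKymograph")
}

#' @export
print.DffKymograph <- function(x, ...) {
  cat(sprintf("DffKymograph: %d bins x %d frames (baseline: %d pre-wound frame(s))\n",
              nrow(x$dff), ncol(x$dff), x$n_prewound_frames))
  invisible(x)
}

# ---- demons non-rigid registration -----------------------------------------

.resize_half <- function(img) {
  sm <- gauss_blur2d(img, 1)
  sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2)]
}

.upsample_field <- function(u, H, W) {
  Hs <- nrow(u$ux); Ws <- ncol(u$ux)
  gy <- (seq_len(H) - 1) * (Hs - 1) / max(H - 1, 1) + 1
  gx <- (seq_len(W) - 1) * (Ws - 1) / max(W - 1, 1) + 1
  mx <- matrix(rep(gx, each = H), H, W)
  my <- matrix(rep(gy, W), H, W)
  sc <- (W - 1) / max(Ws - 1, 1)
  list(ux = warp_image(u$ux, mx, my, fill = 0) * sc,
       uy = warp_image(u$uy, mx, my, fill = 0) * sc)
}

# Warp image by displacement field: out(x) = img(x + u(x)).
warp_by_field <- function(img, field, fill = NA_real_) {
  H <- nrow(img); W <- ncol(img)
  gx <- matrix(rep(seq_len(W), each = H), H, W)
  gy <- matrix(rep(seq_len(H), W), H, W)
  warp_image(img, gx + field$ux, gy + field$uy, fill = fill)
}

#' Demons non-rigid registration of one frame onto a reference
#'
#' Estimates a dense displacement field `u` such that
#' `moving(x + u(x)) ~ fixed(x)` pixel by pixel, by multiresolution demons
#' iterations: the classic intensity-difference force along the fixed-image
#' gradient, Gaussian smoothing of each update (fluid regularization) and of
#' the accumulated field (diffusion regularization), with updates combined
#' by composition so the field stays a smooth invertible warp.
#'
#' @param moving,fixed same-size matrices, rigidly pre-registered.
#' @param levels multiresolution levels.
#' @param iterations demons iterations per level.
#' @param update_sigma Gaussian sigma (px) smoothing each update.
#' @param field_sigma Gaussian sigma (px) smoothing the accumulated field.
#' @param presmooth_sigma Gaussian presmoothing of both images (px).
#' @param step_length_px demons force normalization length; each iteration's
#'   update is capped near `step_length_px / 2` px.
#' @return object of class `DisplacementField` with matrices `ux`, `uy`
#'   (px), plus `mse_before`/`mse_after`.
#' @export
demons_field <- function(moving, fixed, levels = 3, iterations = 50,
                         update_sigma = 1, field_sigma = 1,
                         presmooth_sigma = 1, step_length_px = 2) {
  stopifnot(all(dim(moving) == dim(fixed)))
  if (mean(moving) <= 0 || mean(fixed) <= 0)
    stop("demons needs images with positive mean intensity")
  # normalize out global illumination so the field explains shape, not gain
  mov <- gauss_blur2d(moving / mean(moving), presmooth_sigma)
  fix <- gauss_blur2d(fixed / mean(fixed), presmooth_sigma)
  pyr_m <- .build_pyramid(mov, levels)
  pyr_f <- .build_pyramid(fix, levels)
  u <- NULL
  for (l in levels:1) {
    Fm <- pyr_m[[l]]; Ff <- pyr_f[[l]]
    H <- nrow(Ff); W <- ncol(Ff)
    if (is.null(u)) {
      u <- list(ux = matrix(0, H, W), uy = matrix(0, H, W))
    } else {
      u <- .upsample_field(u, H, W)
    }
    G <- image_gradients(Ff)
    g2 <- G$gx^2 + G$gy^2
    for (it in seq_len(iterations)) {
      warped <- warp_by_field(Fm, u, fill = NA_real_)
      diff <- warped - Ff
      diff[is.na(diff)] <- 0
      # Gauss-Newton-like force with self-scaling damping: the damping term
      # matches g2 at the rms residual, capping each update near half the
      # typical remaining displacement (and at step_length_px / 2)
      beta <- max(mean(g2) / max(mean(diff^2), 1e-12),
                  1 / step_length_px^2)
      denom <- g2 + diff^2 * beta
      fac <- ifelse(denom > 1e-12, diff / denom, 0)
      dux <- -fac * G$gx
      duy <- -fac * G$gy
      dux <- gauss_blur2d(dux, update_sigma)
      duy <- gauss_blur2d(duy, update_sigma)
      # compose: u <- u(x + du(x)) + du(x)
      gx <- matrix(rep(seq_len(W), each = H), H, W)
      gy <- matrix(rep(seq_len(H), W), H, W)
      ux_new <- warp_image(u$ux, gx + dux, gy + duy, fill = 0) + dux
      uy_new <- warp_image(u$uy, gx + dux, gy + duy, fill = 0) + duy
      u$ux <- gauss_blur2d(ux_new, field_sigma)
      u$uy <- gauss_blur2d(uy_new, field_sigma)
    }
  }
  movn <- moving / mean(moving); fixn <- fixed / mean(fixed)
  mse0 <- mean((movn - fixn)^2)
  mse1 <- mean((warp_by_field(movn, u, fill = NA_real_) - fixn)^2,
               na.rm = TRUE)
  if (mse1 > mse0 * 1.001 + 1e-4 * mean(fixn^2))
    stop(sprintf(
      "demons registration diverged: dissimilarity rose from %.4g to %.4g",
      mse0, mse1))
  structure(list(ux = u$ux, uy = u$uy, mse_before = mse0, mse_after = mse1),
            class = "DisplacementField")
}

#' @export
print.DisplacementField <- function(x, ...) {
  mag <- sqrt(x$ux^2 + x$uy^2)
  cat(sprintf("DisplacementField %d x %d px: median |u| = %.3f px\n",
              nrow(x$ux), ncol(x$ux), median(mag)))
  invisible(x)
}

#' Compose a chain of per-step displacement fields
#'
#' Given fields `fields[[t]]` warping frame `t + 1` onto frame `t`
#' (`frame_{t+1}(x + u_t(x)) ~ frame_t(x)`), returns for each frame the
#' composed field warping it directly onto frame 1:
#' `u_{1<-t+1}(x) = u_{1<-t}(x) + u_t(x + u_{1<-t}(x))`.
#'
#' @param fields list of `DisplacementField`s (consecutive chain).
#' @return list of `DisplacementField`s; element `t` maps frame `t + 1` to
#'   frame 1 (element names `to_frame1_from`).
#' @export
compose_fields <- function(fields) {
  if (!length(fields)) return(list())
  if (any(!vapply(fields, inherits, TRUE, "DisplacementField")))
    stop("gap in the field chain: all elements must be DisplacementFields")
  H <- nrow(fields[[1]]$ux); W <- ncol(fields[[1]]$ux)
  gx <- matrix(rep(seq_len(W), each = H), H, W)
  gy <- matrix(rep(seq_len(H), W), H, W)
  out <- vector("list", length(fields))
  acc <- list(ux = matrix(0, H, W), uy = matrix(0, H, W))
  for (t in seq_along(fields)) {
    step <- fields[[t]]
    sx <- warp_image(step$ux, gx + acc$ux, gy + acc$uy, fill = 0)
    sy <- warp_image(step$uy, gx + acc$ux, gy + acc$uy, fill = 0)
    acc <- list(ux = acc$ux + sx, uy = acc$uy + sy)
    out[[t]] <- structure(list(ux = acc$ux, uy = acc$uy),
                          class = "DisplacementField")
  }
  out
}

#' Shape-decoupled per-frame mean delta-F/F0 trace
#'
#' Warps every frame onto the first frame through composed displacement
#' fields, Gaussian-smooths each aligned frame, and computes the pixel-wise
#' relative intensity change `(F_t(x_hat, y_hat) - F_0(x, y)) / F_0(x, y)`.
#' The spatial mean per frame excludes pixels within `exclusion_um` of the
#' wound polygon (about one cell diameter), pixels with undefined warps, and
#' pixels with non-positive baseline.
#'
#' @param frames list of registered single-channel matrices, or a
#'   [timelapse_stack()].
#' @param fields composed fields from [compose_fields()] (length
#'   `length(frames) - 1`).
#' @param wound a [wound_annotation()] (polygon in pixel coordinates).
#' @param exclusion_um wound-margin exclusion distance (um).
#' @param smooth_sigma Gaussian sigma (px) applied before the ratio.
#' @param pixel_size_um calibration (taken from the stack if supplied).
#' @return list with `trace` (per-frame mean dff; frame 1 is 0 by
#'   construction), `n_pixels` used per frame, and `excluded_f0` count.
#' @export
warped_dff_trace <- function(frames, fields, wound, exclusion_um = 20,
                             smooth_sigma = 2, pixel_size_um = 1) {
  if (inherits(frames, "TimelapseStack")) {
    pixel_size_um <- frames$pixel_size_um
    frames <- max_project_z(frames, 1)
  }
  nT <- length(frames)
  stopifnot(length(fields) == nT - 1)
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  wmask <- polygon_mask(wound$polygon, H, W)
  outside <- matrix(1, H, W); outside[wmask] <- 0
  dist_px <- EBImage::distmap(t(outside))    # distance to the wound region
  dist_um <- t(as.matrix(dist_px)) * pixel_size_um
  keep_space <- dist_um > exclusion_um
  F0 <- gauss_blur2d(frames[[1]], smooth_sigma)
  bad_f0 <- F0 <= 0
  trace <- numeric(nT)
  npix <- integer(nT)
  trace[1] <- 0
  npix[1] <- sum(keep_space & !bad_f0)
  for (t in 2:nT) {
    aligned <- warp_by_field(frames[[t]], fields[[t - 1]], fill = NA_real_)
    sm <- gauss_blur2d(ifelse(is.na(aligned), 0, aligned), smooth_sigma)
    wvalid <- gauss_blur2d(matrix(as.numeric(!is.na(aligned)), H, W),
                           smooth_sigma)
    ok <- keep_space & !bad_f0 & wvalid > 0.99
    dff <- (sm / pmax(wvalid, 1e-9) - F0) / F0
    trace[t] <- mean(dff[ok])
    npix[t] <- sum(ok)
  }
  list(trace = trace, n_pixels = npix, excluded_f0 = sum(bad_f0))
}

#' Illumination quality-control exclusion rules
#'
#' A movie is excluded when either (a) the slope of a least-squares fit of
#' mean background intensity over time exceeds `0.005 m` intensity units per
#' frame, or (b) the first frame's background differs from `m` by more than
#' `0.5 m`, where `m` is the median background intensity over the movie
#' (everything downstream is normalized to the first frame, so a deviant
#' first frame biases the whole delta-F/F0 trajectory).
#'
#' @param background_trace per-frame mean background intensity (>= 3
#'   frames).
#' @param m median background intensity; defaults to
#'   `median(background_trace)`.
#' @return object of class `QcReport` with `m`, `slope_per_frame`,
#'   `first_frame_deviation`, `excluded`, `reasons`.
#' @export
qc_exclusion <- function(background_trace, m = NULL) {
  y <- as.numeric(background_trace)
  if (length(y) < 3) stop("need at least 3 frames of background")
  m <- m %||% median(y)
  fr <- seq_along(y)
  slope <- unname(coef(lm(y ~ fr))[2])
  dev1 <- abs(y[1] - m)
  reasons <- character(0)
  if (slope > 0.005 * m)
    reasons <- c(reasons, sprintf(
      "background slope %.3g > 0.005 m = %.3g per frame", slope, 0.005 * m))
  if (dev1 > 0.5 * m)
    reasons <- c(reasons, sprintf(
      "first-frame deviation %.3g > 0.5 m = %.3g", dev1, 0.5 * m))
  structure(list(m = m, background_trace = y, slope_per_frame = slope,
                 first_frame_deviation = dev1,
                 excluded = length(reasons) > 0, reasons = reasons),
            class = "QcReport")
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("QcReport: m = %.4g, slope %.4g / frame, first-frame dev %.4g\n",
              x$m, x$slope_per_frame, x$first_frame_deviation))
  cat(if (x$excluded) paste(" EXCLUDED:", paste(x$reasons, collapse = "; "))
      else "  passed", "\n")
  invisible(x)
}

#' Estimate a background trace from the darkest pixels
#'
#' Default background region: the darkest `frac` of pixels in the first
#' frame, applied to every frame.
#'
#' @param frames list of matrices or a [timelapse_stack()].
#' @param frac fraction of darkest pixels.
#' @return numeric per-frame mean background.
#' @export
background_trace <- function(frames, frac = 0.05) {
  if (inherits(frames, "TimelapseStack")) frames <- max_project_z(frames, 1)
  thr <- quantile(frames[[1]], frac)
  sel <- frames[[1]] <= thr
  vapply(frames, function(f) mean(f[sel]), 1)
}
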