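#' Shi-Tomasi corner detection
#'
#' Detects corners as local maxima of the smaller structure-tensor
#' eigenvalue, keeping points above `quality` times the strongest response
#' and suppressing neighbours within `min_distance` pixels (strongest first).
#'
#' @param img numeric matrix `[y, x]`.
#' @param max_corners maximum number of corners returned.
#' @param quality minimum response as a fraction of the maximum response.
#' @param min_distance minimum separation between returned corners (px).
#' @param block_size structure-tensor integration window (px).
#' @return data.frame with `x`, `y`, `response`, strongest first.
#' @export
shi_tomasi_corners <- function(img, max_corners = 3000, quality = 0.01,
                               min_distance = 5, block_size = 3) {
  g <- image_gradients(gauss_blur2d(img, 1))
  w <- matrix(1, block_size, block_size) / block_size^2
  sm <- function(m) {
    pad <- (dim(w) + 1L) %/% 2L
    crop_pad(fft_convolve(pad_replicate(m, pad), w), pad)
  }
  A <- sm(g$gx^2); C <- sm(g$gy^2); B <- sm(g$gx * g$gy)
  lam <- (A + C) / 2 - sqrt(((A - C) / 2)^2 + B^2)
  H <- nrow(img); W <- ncol(img)
  b <- 3L                                     # border margin
  lam[c(seq_len(b), H - seq_len(b) + 1L), ] <- -Inf
  lam[, c(seq_len(b), W - seq_len(b) + 1L)] <- -Inf
  # 3x3 local maxima only
  mx <- lam
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    sh <- matrix(-Inf, H, W)
    ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
    oky <- ys >= 1 & ys <= H; okx <- xs >= 1 & xs <= W
    sh[oky, okx] <- lam[ys[oky], xs[okx]]
    mx <- pmax(mx, sh)
  }
  thr <- quality * max(lam)
  cand <- which(lam >= mx & lam >= thr & is.finite(lam))
  if (!length(cand)) return(data.frame(x = numeric(), y = numeric(),
                                       response = numeric()))
  cy <- ((cand - 1L) %% H) + 1L
  cx <- ((cand - 1L) %/% H) + 1L
  score <- lam[cand]
  o <- order(score, decreasing = TRUE)
  cx <- cx[o]; cy <- cy[o]; score <- score[o]
  # greedy radius suppression on a cell grid
  cell <- max(1, min_distance)
  keep <- logical(length(cx))
  grid <- new.env(hash = TRUE, parent = emptyenv())
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_along(cx)) {
    gxc <- cx[i] %/% cell; gyc <- cy[i] %/% cell
    ok <- TRUE
    for (ddy in -1:1) for (ddx in -1:1) {
      key <- paste0(gxc + ddx, ",", gyc + ddy)
      ids <- grid[[key]]
      if (!is.null(ids) &&
          any((kx[ids] - cx[i])^2 + (ky[ids] - cy[i])^2 < min_distance^2)) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      keep[i] <- TRUE
      kx <- c(kx, cx[i]); ky <- c(ky, cy[i])
      key <- paste0(gxc, ",", gyc)
      grid[[key]] <- c(grid[[key]], length(kx))
      if (length(kx) >= max_corners) break
    }
  }
  kx2 <- cx[keep]; ky2 <- cy[keep]
  # sub-pixel refinement: parabola through the response at peak +/- 1
  sub <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    ifelse(is.finite(den) & abs(den) > 1e-12,
           pmax(-0.5, pmin(0.5, 0.5 * (m1 - p1) / den)), 0)
  }
  dx <- sub(lam[cbind(ky2, kx2 - 1L)], lam[cbind(ky2, kx2)],
            lam[cbind(ky2, kx2 + 1L)])
  dy <- sub(lam[cbind(ky2 - 1L, kx2)], lam[cbind(ky2, kx2)],
            lam[cbind(ky2 + 1L, kx2)])
  data.frame(x = kx2 + dx, y = ky2 + dy, response = score[keep])
}

.build_pyramid <- function(img, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- img
  for (l in seq_len(levels - 1)) {
    sm <- gauss_blur2d(pyr[[l]], 1)
    pyr[[l + 1]] <- sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2)]
  }
  pyr
}

# One pyramidal Lucas-Kanade step for all points at once.
# Returns list(x, y, ok) of tracked positions in `img2`.
.klt_step <- function(pyr1, pyr2, px, py, win = 15, max_iter = 30,
                      eps = 0.01) {
  levels <- length(pyr1)
  r <- (win - 1) / 2
  off <- expand.grid(dx = -r:r, dy = -r:r)
  n <- length(px)
  gx_pt <- px / 2^(levels - 1); gy_pt <- py / 2^(levels - 1)
  qx <- gx_pt; qy <- gy_pt
  ok <- rep(TRUE, n)
  for (l in levels:1) {
    I <- pyr1[[l]]; J <- pyr2[[l]]
    sc <- 2^(l - 1)
    lx <- px / sc; ly <- py / sc
    if (l < levels) { qx <- qx * 2; qy <- qy * 2 }
    G <- image_gradients(I)
    X1 <- outer(lx, off$dx, "+"); Y1 <- outer(ly, off$dy, "+")
    Iw <- matrix(bilinear_sample(I, X1, Y1), n)
    Gxw <- matrix(bilinear_sample(G$gx, X1, Y1), n)
    Gyw <- matrix(bilinear_sample(G$gy, X1, Y1), n)
    bad <- !complete.cases(Iw)
    ok[bad] <- FALSE
    Iw[is.na(Iw)] <- 0; Gxw[is.na(Gxw)] <- 0; Gyw[is.na(Gyw)] <- 0
    g11 <- rowSums(Gxw^2); g12 <- rowSums(Gxw * Gyw); g22 <- rowSums(Gyw^2)
    det <- g11 * g22 - g12^2
    sing <- det < 1e-9
    ok[sing] <- FALSE
    det[sing] <- 1
    act <- ok
    for (it in seq_len(max_iter)) {
      if (!any(act)) break
      X2 <- outer(qx, off$dx, "+"); Y2 <- outer(qy, off$dy, "+")
      Jw <- matrix(bilinear_sample(J, X2[act, , drop = FALSE],
                                   Y2[act, , drop = FALSE]), sum(act))
      out_b <- !complete.cases(Jw)
      Jw[is.na(Jw)] <- 0
      rs <- Iw[act, , drop = FALSE] - Jw
      b1 <- rowSums(rs * Gxw[act, , drop = FALSE])
      b2 <- rowSums(rs * Gyw[act, , drop = FALSE])
      dx <- (g22[act] * b1 - g12[act] * b2) / det[act]
      dy <- (g11[act] * b2 - g12[act] * b1) / det[act]
      qx[act] <- qx[act] + dx
      qy[act] <- qy[act] + dy
      ids <- which(act)
      ok[ids[out_b]] <- FALSE
      act[ids[out_b]] <- FALSE
      act[ids] <- act[ids] & (abs(dx) > eps | abs(dy) > eps)
    }
  }
  H <- nrow(pyr1[[1]]); W <- ncol(pyr1[[1]])
  ok <- ok & qx >= 1 & qx <= W & qy >= 1 & qy <= H
  list(x = qx, y = qy, ok = ok)
}

#' Track feature points through a registered timelapse
#'
#' Detects Shi-Tomasi corners and tracks them frame to frame with a
#' pyramidal Kanade-Lucas-Tomasi tracker. A forward-backward consistency
#' check terminates tracks whose re-tracked origin deviates more than
#' `fb_tol` px; displacements above `sanity_px` per frame also terminate the
#' track. Corners are re-detected every `redetect_every` frames and merged
#' in (new tracks inherit no history).
#'
#' @param frames list of single-channel matrices (registered), or a
#'   [timelapse_stack()] (first channel, z max-projected).
#' @param max_corners,quality,min_distance corner-detector settings.
#' @param win,max_level,max_iter KLT window size (px), pyramid levels,
#'   iterations.
#' @param fb_tol forward-backward tolerance (px).
#' @param sanity_px per-frame displacement bound (px).
#' @param redetect_every re-detection cadence (frames).
#' @param pixel_size_um,frame_interval_s calibration (taken from the stack
#'   when one is supplied).
#' @return object of class `PointTracks`: matrices `x`, `y` (track x frame)
#'   and logical `valid`, plus the calibration.
#' @export
track_features <- function(frames, max_corners = 3000, quality = 0.01,
                           min_distance = 5, win = 15, max_level = 3,
                           max_iter = 30, fb_tol = 1, sanity_px = 20,
                           redetect_every = 10,
                           pixel_size_um = 1, frame_interval_s = 1) {
  if (inherits(frames, "TimelapseStack")) {
    pixel_size_um <- frames$pixel_size_um
    frame_interval_s <- frames$frame_interval_s
    frames <- max_project_z(frames, 1)
  }
  nT <- length(frames)
  stopifnot(nT >= 2)
  pyrs <- lapply(frames, .build_pyramid, levels = max_level)
  corners <- shi_tomasi_corners(frames[[1]], max_corners, quality,
                                min_distance)
  if (nrow(corners) < 50)
    warning("fewer than 50 corners detected: texture too weak for reliable tracking")
  n0 <- nrow(corners)
  X <- matrix(NA_real_, n0, nT); Y <- matrix(NA_real_, n0, nT)
  V <- matrix(FALSE, n0, nT)
  X[, 1] <- corners$x; Y[, 1] <- corners$y; V[, 1] <- TRUE
  for (t in seq_len(nT - 1)) {
    live <- which(V[, t])
    if (length(live)) {
      fwd <- .klt_step(pyrs[[t]], pyrs[[t + 1]], X[live, t], Y[live, t],
                       win, max_iter)
      bwd <- .klt_step(pyrs[[t + 1]], pyrs[[t]], fwd$x, fwd$y, win, max_iter)
      fb <- sqrt((bwd$x - X[live, t])^2 + (bwd$y - Y[live, t])^2)
      disp <- sqrt((fwd$x - X[live, t])^2 + (fwd$y - Y[live, t])^2)
      good <- fwd$ok & bwd$ok & fb <= fb_tol & disp <= sanity_px
      idx <- live[good]
      X[idx, t + 1] <- fwd$x[good]
      Y[idx, t + 1] <- fwd$y[good]
      V[idx, t + 1] <- TRUE
    }
    if ((t %% redetect_every) == 0 && t + 1 < nT) {
      fresh <- shi_tomasi_corners(frames[[t + 1]], max_corners, quality,
                                  min_distance)
      if (nrow(fresh)) {
        lx <- X[V[, t + 1], t + 1]; ly <- Y[V[, t + 1], t + 1]
        if (length(lx)) {
          d2 <- outer(fresh$x, lx, "-")^2 + outer(fresh$y, ly, "-")^2
          fresh <- fresh[apply(d2, 1, min) >= min_distance^2, , drop = FALSE]
        }
        if (nrow(fresh)) {
          nn <- nrow(fresh)
          X <- rbind(X, matrix(NA_real_, nn, nT))
          Y <- rbind(Y, matrix(NA_real_, nn, nT))
          V <- rbind(V, matrix(FALSE, nn, nT))
          rows <- (nrow(X) - nn + 1):nrow(X)
          X[rows, t + 1] <- fresh$x; Y[rows, t + 1] <- fresh$y
          V[rows, t + 1] <- TRUE
        }
      }
    }
  }
  structure(list(x = X, y = Y, valid = V,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "PointTracks")
}

#' @export
print.PointTracks <- function(x, ...) {
  cat(sprintf("PointTracks: %d tracks over %d frames (%.0f%% positions valid)\n",
              nrow(x$x), ncol(x$x), 100 * mean(x$valid)))
  invisible(x)
}

# Per-point velocities (px/frame) by central differences; one-sided at track
# ends. Returns vx, vy matrices aligned with tracks.
track_velocities_px <- function(tracks) {
  X <- tracks$x; Y <- tracks$y; V <- tracks$valid
  nT <- ncol(X)
  vx <- matrix(NA_real_, nrow(X), nT); vy <- vx
  for (t in seq_len(nT)) {
    tm <- max(t - 1, 1); tp <- min(t + 1, nT)
    ok <- V[, tm] & V[, tp]
    dt <- tp - tm
    vx[ok, t] <- (X[ok, tp] - X[ok, tm]) / dt
    vy[ok, t] <- (Y[ok, tp] - Y[ok, tm]) / dt
  }
  list(vx = vx, vy = vy)
}

#' Define the wound axis from tracked points and the wound annotation
#'
#' The axis runs along the line between the centroid of all detected points
#' and the wound centroid; its origin is the wound centroid and its unit
#' direction points from the wound toward the tissue, so the projection
#' `dot(p - origin, direction)` is the (positive) 1D distance of a point
#' from the wound.
#'
#' @param tracks a [track_features()] result (or a 2-column matrix of point
#'   positions, px).
#' @param wound a [wound_annotation()].
#' @param pixel_size_um pixel size; taken from `tracks` when available.
#' @return object of class `WoundAxis` with `origin_px`, `direction`
#'   (unit vector), `pixel_size_um`.
#' @export
build_wound_axis <- function(tracks, wound, pixel_size_um = NULL) {
  if (inherits(tracks, "PointTracks")) {
    pts <- cbind(tracks$x[tracks$valid], tracks$y[tracks$valid])
    pixel_size_um <- pixel_size_um %||% tracks$pixel_size_um
  } else {
    pts <- as.matrix(tracks)
    pixel_size_um <- pixel_size_um %||% 1
  }
  if (nrow(pts) < 1) stop("need at least one valid point")
  pc <- colMeans(pts)
  dir <- pc - wound$centroid
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-9) stop("wound centroid coincides with the points centroid")
  structure(list(origin_px = as.numeric(wound$centroid), direction = dir / nd,
                 pixel_size_um = pixel_size_um),
            class = "WoundAxis")
}

#' Project points onto the wound axis
#' @param axis a [build_wound_axis()] result.
#' @param x,y point positions (px).
#' @return 1D distance from the wound centroid along the axis, in um.
#' @export
project_on_axis <- function(axis, x, y) {
  ((x - axis$origin_px[1]) * axis$direction[1] +
     (y - axis$origin_px[2]) * axis$direction[2]) * axis$pixel_size_um
}

.kym_new <- function(values, counts, bin_edges, times_s, variant) {
  structure(list(mean_speed_um_min = values, n_points = counts,
                 bin_edges_um = bin_edges,
                 bin_centers_um = (head(bin_edges, -1) + tail(bin_edges, -1)) / 2,
                 times_s = times_s, variant = variant),
            class = "VelocityKymograph")
}

#' @export
print.VelocityKymograph <- function(x, ...) {
  cat(sprintf("VelocityKymograph (%s): %d bins x %d frames, %g um bins\n",
              x$variant, length(x$bin_centers_um), length(x$times_s),
              diff(x$bin_edges_um[1:2])))
  invisible(x)
}

#' Distance-binned speed kymograph
#'
#' Points are binned by their current-frame 1D wound-axis coordinate in
#' `bin_um` increments, and for each frame the unweighted mean of per-point
#' 2D speed magnitudes (um/min) in each bin is recorded. The
#' `"horizontal"` variant averages the signed x velocity component instead
#' (positive = increasing x). Bins with no points are `NA`, not zero.
#'
#' @param tracks a [track_features()] result.
#' @param axis a [build_wound_axis()] result.
#' @param bin_um bin pitch (um, > 0).
#' @param variant `"speed"` or `"horizontal"`.
#' @param max_distance_um optional kymograph extent; defaults to the data.
#' @return object of class `VelocityKymograph`.
#' @export
speed_kymograph <- function(tracks, axis, bin_um = 10,
                            variant = c("speed", "horizontal"),
                            max_distance_um = NULL) {
  variant <- match.arg(variant)
  if (bin_um <= 0) stop("bin_um must be > 0")
  vel <- track_velocities_px(tracks)
  to_um_min <- tracks$pixel_size_um * 60 / tracks$frame_interval_s
  nT <- ncol(tracks$x)
  dmat <- matrix(NA_real_, nrow(tracks$x), nT)
  for (t in seq_len(nT)) {
    ok <- tracks$valid[, t]
    dmat[ok, t] <- project_on_axis(axis, tracks$x[ok, t], tracks$y[ok, t])
  }
  val_pt <- if (variant == "speed")
    sqrt(vel$vx^2 + vel$vy^2) * to_um_min else vel$vx * to_um_min
  use <- is.finite(dmat) & is.finite(val_pt) & dmat >= 0
  dmax <- max_distance_um %||% max(dmat[use], 0)
  edges <- seq(0, ceiling(dmax / bin_um) * bin_um + bin_um, by = bin_um)
  nb <- length(edges) - 1
  vals <- matrix(NA_real_, nb, nT)
  cnts <- matrix(0L, nb, nT)
  for (t in seq_len(nT)) {
    ok <- use[, t] & dmat[, t] < edges[nb + 1]
    if (!any(ok)) next
    bi <- pmin(findInterval(dmat[ok, t], edges), nb)
    s <- rowsum(val_pt[ok, t], bi)
    n <- rowsum(rep(1L, sum(ok)), bi)
    ids <- as.integer(rownames(s))
    vals[ids, t] <- s / n
    cnts[ids, t] <- n
  }
  times <- (seq_len(nT) - 1) * tracks$frame_interval_s
  .kym_new(vals, cnts, edges, times, variant)
}

#' Relative-velocity-corrected kymograph
#'
#' Subtracts the per-frame mean velocity vector of far-field points
#' (1D coordinate beyond `cutoff_um`) from each near-field point's velocity
#' before computing speeds, removing residual whole-larva drift. The
#' kymograph covers the near field only.
#'
#' @inheritParams speed_kymograph
#' @param cutoff_um near/far cutoff distance (um).
#' @param variant `"speed"` for corrected speed magnitude or
#'   `"horizontal"` for the corrected signed x component.
#' @return a `VelocityKymograph` with variant `"relative"` (or
#'   `"relative_horizontal"`).
#' @export
relative_velocity_correction <- function(tracks, axis, bin_um = 10,
                                         cutoff_um = 300,
                                         variant = c("speed", "horizontal")) {
  variant <- match.arg(variant)
  vel <- track_velocities_px(tracks)
  to_um_min <- tracks$pixel_size_um * 60 / tracks$frame_interval_s
  nT <- ncol(tracks$x)
  dmat <- matrix(NA_real_, nrow(tracks$x), nT)
  for (t in seq_len(nT)) {
    ok <- tracks$valid[, t]
    dmat[ok, t] <- project_on_axis(axis, tracks$x[ok, t], tracks$y[ok, t])
  }
  edges <- seq(0, ceiling(cutoff_um / bin_um) * bin_um, by = bin_um)
  nb <- length(edges) - 1
  vals <- matrix(NA_real_, nb, nT)
  cnts <- matrix(0L, nb, nT)
  for (t in seq_len(nT)) {
    far <- which(dmat[, t] > cutoff_um & is.finite(vel$vx[, t]))
    if (!length(far))
      stop("no far-field points beyond ", cutoff_um,
           " um in frame ", t, ": relative correction undefined")
    mvx <- mean(vel$vx[far, t]); mvy <- mean(vel$vy[far, t])
    near <- which(dmat[, t] >= 0 & dmat[, t] < cutoff_um &
                    is.finite(vel$vx[, t]))
    if (!length(near)) next
    cvx <- vel$vx[near, t] - mvx
    cvy <- vel$vy[near, t] - mvy
    v <- if (variant == "speed") sqrt(cvx^2 + cvy^2) * to_um_min
      else cvx * to_um_min
    bi <- pmin(findInterval(dmat[near, t], edges), nb)
    s <- rowsum(v, bi); n <- rowsum(rep(1L, length(near)), bi)
    ids <- as.integer(rownames(s))
    vals[ids, t] <- s / n
    cnts[ids, t] <- n
  }
  times <- (seq_len(nT) - 1) * tracks$frame_interval_s
  k <- .kym_new(vals, cnts, edges, times,
                if (variant == "speed") "relative" else "relative_horizontal")
  k
}

#' Mean near-wound speed trace
#'
#' Point-count-weighted mean of kymograph bins within `window_um` of the
#' wound, for the first `n_frames` frames; one summary speed per frame.
#'
#' @param kymograph a [speed_kymograph()] result.
#' @param window_um spatial window from the wound (um).
#' @param n_frames number of frames retained.
#' @return numeric vector of length `n_frames` (um/min; `NA` with a warning
#'   where the window holds no points).
#' @export
mean_speed_trace <- function(kymograph, window_um = 300, n_frames = 30) {
  nT <- length(kymograph$times_s)
  n_frames <- min(n_frames, nT)
  sel <- kymograph$bin_centers_um <= window_um
  if (!any(sel)) stop("kymograph does not cover the requested window")
  out <- rep(NA_real_, n_frames)
  for (t in seq_len(n_frames)) {
    v <- kymograph$mean_speed_um_min[sel, t]
    n <- kymograph$n_points[sel, t]
    ok <- is.finite(v) & n > 0
    if (any(ok)) out[t] <- sum(v[ok] * n[ok]) / sum(n[ok])
  }
  if (anyNA(out)) warning("empty window in ", sum(is.na(out)), " frame(s)")
  out
}

#' Per-phase median of the spatially averaged horizontal velocity
#'
#' @param kymograph a horizontal-variant [speed_kymograph()].
#' @param phase_frames list of integer frame-index vectors partitioning the
#'   time axis into phases.
#' @param window_um spatial averaging window (um).
#' @return named numeric vector of per-phase medians (um/min).
#' @export
phase_median_velocity <- function(kymograph, phase_frames,
                                  window_um = Inf) {
  sel <- kymograph$bin_centers_um <= window_um
  per_frame <- vapply(seq_along(kymograph$times_s), function(t) {
    v <- kymograph$mean_speed_um_min[sel, t]
    n <- kymograph$n_points[sel, t]
    ok <- is.finite(v) & n > 0
    if (any(ok)) sum(v[ok] * n[ok]) / sum(n[ok]) else NA_real_
  }, 1)
  out <- vapply(seq_along(phase_frames), function(i) {
    fr <- phase_frames[[i]]
    if (!length(fr)) stop("phase ", i, " is empty")
    median(per_frame[fr], na.rm = TRUE)
  }, 1)
  names(out) <- names(phase_frames) %||% paste0("phase", seq_along(out))
  out
}

#' Estimate front propagation speed from a kymograph
#'
#' For each frame, the front position is the farthest bin whose value
#' exceeds `threshold_frac` times the global kymograph maximum; the front
#' speed is the Theil-Sen slope of front position versus time. Fits with
#' R^2 below 0.5 are flagged (front not advancing monotonically).
#'
#' @param kymograph a `VelocityKymograph` or `DffKymograph`.
#' @param threshold_frac threshold as a fraction of the global maximum.
#' @param min_frames minimum frames with a defined front.
#' @return list with `speed_um_min`, `r2`, `flagged`, `front_position_um`,
#'   `times_s`.
#' @export
estimate_front_speed <- function(kymograph, threshold_frac = 0.5,
                                 min_frames = 3) {
  vals <- if (inherits(kymograph, "DffKymograph")) kymograph$dff
    else kymograph$mean_speed_um_min
  centers <- kymograph$bin_centers_um
  gmax <- max(vals, na.rm = TRUE)
  thr <- threshold_frac * gmax
  front <- vapply(seq_along(kymograph$times_s), function(t) {
    above <- which(is.finite(vals[, t]) & vals[, t] > thr)
    if (length(above)) centers[max(above)] else NA_real_
  }, 1)
  # censor frames where the front has reached the far edge of the field:
  # beyond that point the measured position saturates and no longer tracks
  # the true front
  covered <- centers[apply(is.finite(vals), 1, any)]
  if (length(covered)) {
    edge <- max(covered) - diff(centers[1:2])
    front[is.finite(front) & front >= edge] <- NA_real_
  }
  ok <- is.finite(front)
  if (sum(ok) < min_frames)
    return(list(speed_um_min = NA_real_, r2 = NA_real_, flagged = TRUE,
                front_position_um = front, times_s = kymograph$times_s))
  ts <- theil_sen(kymograph$times_s[ok], front[ok])
  list(speed_um_min = ts$slope * 60, r2 = ts$r2,
       flagged = !is.finite(ts$r2) || ts$r2 < 0.5,
       front_position_um = front, times_s = kymograph$times_s)
}

#' Write a kymograph to long-format CSV
#' @param kymograph a `VelocityKymograph` or `DffKymograph`.
#' @param path CSV path.
#' @export
write_kymograph_csv <- function(kymograph, path) {
  vals <- if (inherits(kymograph, "DffKymograph")) kymograph$dff
    else kymograph$mean_speed_um_min
  df <- data.frame(
    bin_center_um = rep(kymograph$bin_centers_um, length(kymograph$times_s)),
    time_s = rep(kymograph$times_s, each = length(kymograph$bin_centers_um)),
    value = as.vector(vals))
  if (!is.null(kymograph$n_points))
    df$n_points <- as.vector(kymograph$n_points)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Render a kymograph as an image
#' @param x a `VelocityKymograph`.
#' @param ... passed to [graphics::image()].
#' @importFrom graphics image
#' @importFrom grDevices hcl.colors
#' @export
plot.VelocityKymograph <- function(x, ...) {
  image(x = x$times_s / 60, y = x$bin_centers_um,
        z = t(x$mean_speed_um_min), col = hcl.colors(64, "viridis"),
        xlab = "time (min)", ylab = "distance from wound (um)",
        main = paste0("kymograph (", x$variant, ")"), ...)
  invisible(x)
}
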