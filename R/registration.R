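#' Rigid (Euclidean) drift registration
#'
#' Whole-body drift is estimated on the masked reference channel by
#' detecting corner features in each frame, matching normalized image-patch
#' descriptors between adjacent timepoints (nearest neighbour with a Lowe
#' ratio test), and robustly fitting a Euclidean transform (rotation +
#' translation) to the matched displacement vectors with RANSAC, followed by
#' a least-squares refit on the inliers.
#'
#' @name registration
NULL

# Normalized patch descriptors around feature points.
.patch_descriptors <- function(img, pts, patch = 11) {
  r <- (patch - 1) / 2
  off <- expand.grid(dx = -r:r, dy = -r:r)
  X <- outer(pts$x, off$dx, "+"); Y <- outer(pts$y, off$dy, "+")
  D <- matrix(bilinear_sample(img, X, Y), nrow(pts))
  keep <- complete.cases(D)
  D <- D[keep, , drop = FALSE]
  D <- D - rowMeans(D)
  nrm <- sqrt(rowSums(D^2))
  nrm[nrm < 1e-9] <- 1
  list(desc = D / nrm, pts = pts[keep, , drop = FALSE])
}

# Nearest-neighbour descriptor matching with Lowe ratio test.
.match_features <- function(d1, d2, ratio = 0.75) {
  if (nrow(d1$desc) == 0 || nrow(d2$desc) < 2)
    return(cbind(integer(0), integer(0)))
  # squared euclidean distance between unit descriptors via cross product
  S <- tcrossprod(d1$desc, d2$desc)          # similarity in [-1, 1]
  D <- 2 - 2 * S
  best <- max.col(-D)
  ii <- seq_len(nrow(D))
  d_best <- D[cbind(ii, best)]
  D[cbind(ii, best)] <- Inf
  d_second <- D[cbind(ii, max.col(-D))]
  ok <- d_best < ratio^2 * d_second
  cbind(which(ok), best[ok])
}

# Least-squares Euclidean fit p2 ~ R p1 + t (2D Procrustes without scaling).
.fit_euclidean <- function(p1, p2) {
  c1 <- colMeans(p1); c2 <- colMeans(p2)
  q1 <- sweep(p1, 2, c1); q2 <- sweep(p2, 2, c2)
  H <- crossprod(q1, q2)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  t_vec <- c2 - as.vector(R %*% c1)
  list(R = R, t = t_vec, theta = atan2(R[2, 1], R[1, 1]))
}

.euclid_residuals <- function(fit, p1, p2) {
  pred <- sweep(p1 %*% t(fit$R), 2, fit$t, "+")
  sqrt(rowSums((p2 - pred)^2))
}

# Seeded RANSAC for a Euclidean transform on matched point pairs.
ransac_euclidean <- function(p1, p2, threshold_px = 2, iterations = 1000,
                             min_inliers = 8, seed = 1L) {
  n <- nrow(p1)
  if (n < 2) return(NULL)
  best <- NULL; best_n <- 0
  with_seed(seed, {
    for (i in seq_len(iterations)) {
      s <- sample.int(n, 2)
      if (sum((p1[s[1], ] - p1[s[2], ])^2) < 1e-6) next
      f <- .fit_euclidean(p1[s, , drop = FALSE], p2[s, , drop = FALSE])
      res <- .euclid_residuals(f, p1, p2)
      nin <- sum(res < threshold_px)
      if (nin > best_n) {
        best_n <- nin
        best <- which(res < threshold_px)
      }
    }
  })
  if (is.null(best) || best_n < min_inliers) return(NULL)
  fit <- .fit_euclidean(p1[best, , drop = FALSE], p2[best, , drop = FALSE])
  res <- .euclid_residuals(fit, p1, p2)
  inl <- res < threshold_px
  fit <- .fit_euclidean(p1[inl, , drop = FALSE], p2[inl, , drop = FALSE])
  fit$inliers <- sum(inl)
  fit$inlier_fraction <- mean(inl)
  fit
}

#' Estimate a rigid drift track from reference frames
#'
#' @param reference_frames list of 2D matrices (typically the masked
#'   reference-channel projections from [mask_reference_channel()]).
#' @param crop_region optional `c(x0, y0, w, h)` region used for feature
#'   detection (e.g. a 512 x 512 region far from the wound); default uses
#'   the full frame.
#' @param max_corners,quality,min_distance corner-detector settings.
#' @param patch descriptor patch size (px).
#' @param ratio Lowe ratio for descriptor matching.
#' @param threshold_px,iterations,min_inliers RANSAC settings.
#' @param seed RANSAC seed.
#' @return object of class `RigidTransformTrack`: data.frame `per_frame`
#'   (frame, rotation_rad, tx_px, ty_px, inliers, inlier_fraction, flagged;
#'   each row maps frame `t` coordinates into frame `t - 1`), plus the list
#'   `cumulative` of 3 x 3 homogeneous transforms mapping each frame into
#'   frame-1 coordinates.
#' @export
estimate_rigid_track <- function(reference_frames, crop_region = NULL,
                                 max_corners = 1500, quality = 0.01,
                                 min_distance = 5, patch = 11, ratio = 0.75,
                                 threshold_px = 2, iterations = 1000,
                                 min_inliers = 8, seed = 1L) {
  nT <- length(reference_frames)
  stopifnot(nT >= 2)
  H <- nrow(reference_frames[[1]]); W <- ncol(reference_frames[[1]])
  if (is.null(crop_region)) crop_region <- c(1, 1, W, H)
  x0 <- crop_region[1]; y0 <- crop_region[2]
  x1 <- min(x0 + crop_region[3] - 1, W); y1 <- min(y0 + crop_region[4] - 1, H)
  feats <- lapply(reference_frames, function(f) {
    sub <- f[y0:y1, x0:x1]
    pts <- shi_tomasi_corners(sub, max_corners, quality, min_distance)
    pts$x <- pts$x + x0 - 1; pts$y <- pts$y + y0 - 1
    .patch_descriptors(f, pts, patch)
  })
  per <- data.frame(frame = seq_len(nT), rotation_rad = 0, tx_px = 0,
                    ty_px = 0, inliers = NA_integer_,
                    inlier_fraction = NA_real_, flagged = FALSE)
  cumulative <- vector("list", nT)
  cumulative[[1]] <- diag(3)
  for (t in 2:nT) {
    mt <- .match_features(feats[[t]], feats[[t - 1]], ratio)
    fit <- NULL
    if (nrow(mt) >= 2) {
      p_t <- as.matrix(feats[[t]]$pts[mt[, 1], c("x", "y")])
      p_prev <- as.matrix(feats[[t - 1]]$pts[mt[, 2], c("x", "y")])
      fit <- ransac_euclidean(p_t, p_prev, threshold_px, iterations,
                              min_inliers, seed = fan_seed(seed, paste0("ransac", t)))
    }
    if (is.null(fit)) {
      warning("frame ", t, ": too few matched features; identity transform used")
      per$flagged[t] <- TRUE
      M <- diag(3)
    } else {
      per$rotation_rad[t] <- fit$theta
      per$tx_px[t] <- fit$t[1]
      per$ty_px[t] <- fit$t[2]
      per$inliers[t] <- fit$inliers
      per$inlier_fraction[t] <- fit$inlier_fraction
      M <- rbind(cbind(fit$R, fit$t), c(0, 0, 1))
    }
    cumulative[[t]] <- cumulative[[t - 1]] %*% M
  }
  structure(list(per_frame = per, cumulative = cumulative,
                 crop_region = crop_region),
            class = "RigidTransformTrack")
}

#' @export
print.RigidTransformTrack <- function(x, ...) {
  cat(sprintf("RigidTransformTrack: %d frames, %d flagged\n",
              nrow(x$per_frame), sum(x$per_frame$flagged)))
  invisible(x)
}

#' Serialize a rigid track to CSV
#' @param track a `RigidTransformTrack`.
#' @param path CSV path.
#' @export
write_rigid_track_csv <- function(track, path) {
  utils::write.csv(track$per_frame, path, row.names = FALSE)
  invisible(path)
}

#' Resample frames into frame-1 coordinates using a rigid track
#'
#' Each frame is bilinearly resampled through the cumulative transform into
#' the coordinate system of the first frame. Pixels that fall outside the
#' source frame are `NA` (never silently zero-filled).
#'
#' @param frames list of 2D matrices, or a [timelapse_stack()] (in which
#'   case every channel and z-slice is resampled and a stack is returned
#'   with `NA` pixels replaced by 0 after attaching a validity attribute).
#' @param track a [estimate_rigid_track()] result covering all frames.
#' @return list of registered matrices (with `NA` outside the common
#'   footprint), or a registered stack.
#' @export
apply_rigid_track <- function(frames, track) {
  if (inherits(frames, "TimelapseStack")) {
    d <- dim(frames$data)
    if (d[1] != length(track$cumulative))
      stop("track does not cover all frames")
    out <- frames
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
      reg <- .apply_rigid_one(frames$data[t, z, ch, , ], track$cumulative[[t]])
      reg[is.na(reg)] <- 0
      out$data[t, z, ch, , ] <- reg
    }
    return(out)
  }
  if (length(frames) != length(track$cumulative))
    stop("track does not cover all frames")
  lapply(seq_along(frames), function(t)
    .apply_rigid_one(frames[[t]], track$cumulative[[t]]))
}

# Warp one frame into frame-1 coordinates: out(x0) = frame(A^{-1} x0) where
# A maps frame-t coords -> frame-1 coords.
.apply_rigid_one <- function(img, A) {
  H <- nrow(img); W <- ncol(img)
  Ai <- solve(A)
  gx <- matrix(rep(seq_len(W), each = H), H, W)
  gy <- matrix(rep(seq_len(H), W), H, W)
  sx <- Ai[1, 1] * gx + Ai[1, 2] * gy + Ai[1, 3]
  sy <- Ai[2, 1] * gx + Ai[2, 2] * gy + Ai[2, 3]
  warp_image(img, sx, sy, fill = NA_real_)
}
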