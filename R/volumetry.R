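#' Richardson-Lucy 3D deconvolution
#'
#' Standard multiplicative Richardson-Lucy updates
#' `e <- e * ( (obs / (e (*) psf)) (*) psf~ )` with replicate padding against
#' boundary artifacts; non-negativity is preserved by construction and total
#' flux of interior objects is conserved.
#'
#' @param vol numeric 3D array `Z x Y x X` (non-negative).
#' @param psf 3D PSF array (non-negative, normalized to sum 1), or a list
#'   `list(sigma_lateral_um, sigma_axial_um)` expanded to a separable
#'   Gaussian using the voxel calibration in `voxel_um`.
#' @param iterations number of iterations.
#' @param voxel_um `c(z_step, pixel, pixel)` in um; needed only for the
#'   Gaussian PSF shorthand.
#' @return deconvolved array of the same shape.
#' @export
richardson_lucy_3d <- function(vol, psf, iterations = 20,
                               voxel_um = c(0.5, 0.25, 0.25)) {
  stopifnot(length(dim(vol)) == 3)
  if (is.list(psf)) {
    psf <- gaussian_kernel_3d(c(psf$sigma_axial_um / voxel_um[1],
                                psf$sigma_lateral_um / voxel_um[2],
                                psf$sigma_lateral_um / voxel_um[3]))
  }
  if (any(psf < 0)) stop("psf must be non-negative")
  s <- sum(psf)
  if (s <= 0) stop("psf must have positive total mass")
  psf <- psf / s
  psf_flip <- psf[rev(seq_len(dim(psf)[1])), rev(seq_len(dim(psf)[2])),
                  rev(seq_len(dim(psf)[3])), drop = FALSE]
  dim(psf_flip) <- dim(psf)
  pad <- (dim(psf) + 1L) %/% 2L
  obs <- pad_replicate(pmax(vol, 0), pad)
  est <- obs
  eps <- 1e-12
  for (i in seq_len(iterations)) {
    blurred <- pmax(fft_convolve(est, psf), 0)
    ratio <- obs / (blurred + eps)
    est <- est * pmax(fft_convolve(ratio, psf_flip), 0)
  }
  crop_pad(est, pad)
}

#' Threshold-based footprint mask of a cell cluster
#'
#' Thresholds the maximum-intensity z-projection and keeps the largest
#' connected component (ties broken by first label), with holes filled. The
#' default `"half_max"` threshold is the midpoint between the robust
#' background and foreground levels (1st and 99.9th percentiles), which
#' localizes the 50% contour of a blurred step at the true object edge;
#' `"otsu"` and numeric thresholds are also accepted.
#'
#' @param vol 3D array `Z x Y x X` (typically deconvolved).
#' @param threshold `"half_max"`, `"otsu"`, or a numeric threshold.
#' @return logical `Y x X` matrix.
#' @export
cluster_mask <- function(vol, threshold = "half_max") {
  mp <- apply(vol, c(2, 3), max)
  thr <- if (is.numeric(threshold)) threshold
    else if (identical(threshold, "otsu")) otsu_threshold(mp)
    else 0.5 * (quantile(mp, 0.001) + quantile(mp, 0.999))
  bw <- mp > thr
  if (!any(bw)) stop("empty cluster mask: threshold removes everything")
  lab <- EBImage::bwlabel(t(bw))
  tab <- tabulate(as.integer(lab))
  big <- which.max(tab)
  mask <- t(as.matrix(lab)) == big
  mask <- t(as.matrix(EBImage::fillHull(t(mask * 1)))) > 0
  mask
}

# Two-surface edge volume: 3D Gaussian smoothing, then a z-axis Sobel
# (derivative along z, [1 2 1] smoothing in x and y); the absolute gradient
# peaks at the lower and upper cluster surfaces.
.edge_volume <- function(vol, sigma_vox = c(1, 1, 1)) {
  sm <- gauss_blur3d(vol, sigma_vox)
  kz <- c(-1, 0, 1)
  ks <- c(1, 2, 1) / 4
  k <- outer(outer(kz, ks), ks)
  pad <- (dim(k) + 1L) %/% 2L
  abs(crop_pad(fft_convolve(pad_replicate(sm, pad), k), pad))
}

# Sub-voxel peak position: least-squares parabola through log intensity in
# a +/- `halfwin` window around the integer peak (a Gaussian fit).
.gaussian_subpixel <- function(y, peak, halfwin = 2) {
  i0 <- max(1, peak - halfwin); i1 <- min(length(y), peak + halfwin)
  z <- i0:i1
  v <- log(pmax(y[z], 1e-12))
  if (length(z) < 3) return(peak)
  cf <- coef(lm(v ~ z + I(z^2)))
  a <- cf[[3]]; b <- cf[[2]]
  if (!is.finite(a) || a >= 0) return(peak)
  zc <- -b / (2 * a)
  if (zc < i0 - 1 || zc > i1 + 1) return(peak)
  zc
}

# Two dominant z-peaks (by height, minimum separation) of one linescan.
.two_peaks <- function(y, min_sep = 2, min_rel_height = 0.2) {
  n <- length(y)
  if (n < 5) return(NULL)
  loc <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) loc <- c(1L, loc)
  if (y[n] > y[n - 1]) loc <- c(loc, n)
  loc <- loc[y[loc] > min_rel_height * max(y)]
  if (length(loc) < 2) return(NULL)
  loc <- loc[order(y[loc], decreasing = TRUE)]
  p1 <- loc[1]
  p2 <- loc[abs(loc - p1) >= min_sep]
  if (!length(p2)) return(NULL)
  sort(c(p1, p2[1]))
}

#' Height of a cluster at one pixel from the z-linescan
#'
#' Finds the two dominant peaks of the edge-enhanced z-linescan at `(x, y)`
#' (the lower and upper surfaces), refines both to sub-voxel precision with
#' a local Gaussian fit, and returns the peak separation in um.
#'
#' @param edge_vol edge-enhanced volume from the smoothing + z-Sobel step
#'   (`Z x Y x X`).
#' @param x,y pixel position.
#' @param z_step_um axial spacing (um).
#' @param min_sep minimum peak separation (z-steps).
#' @return height in um, or `NA` when fewer than two surfaces are found.
#' @export
height_at_pixel <- function(edge_vol, x, y, z_step_um, min_sep = 2) {
  ls <- edge_vol[, y, x]
  pk <- .two_peaks(ls, min_sep = min_sep)
  if (is.null(pk)) return(NA_real_)
  z1 <- .gaussian_subpixel(ls, pk[1])
  z2 <- .gaussian_subpixel(ls, pk[2])
  abs(z2 - z1) * z_step_um
}

#' Build a height map of a cell cluster
#'
#' Computes the two-surface height on a stride grid over the mask
#' (every `stride`-th pixel, to save computation), removes outliers with a
#' 3 x 3 median filter on the stride grid, and interpolates to every mask
#' pixel (bilinear inside the grid hull, nearest-value fill at the rim).
#'
#' @param vol 3D array `Z x Y x X` (deconvolved stack).
#' @param mask logical `Y x X` footprint from [cluster_mask()].
#' @param z_step_um axial spacing (um).
#' @param stride computation grid step (px).
#' @param sigma_vox 3D Gaussian presmoothing sigmas (voxels).
#' @param max_undefined error when more than this fraction of grid pixels
#'   has no defined height.
#' @return object of class `HeightMap`: `height_um` (`NA` off-mask), `mask`,
#'   `stride`, `undefined_fraction`.
#' @export
build_height_map <- function(vol, mask, z_step_um, stride = 2,
                             sigma_vox = c(1, 1, 1), max_undefined = 0.5) {
  stopifnot(all(dim(vol)[2:3] == dim(mask)))
  edge <- .edge_volume(vol, sigma_vox)
  H <- nrow(mask); W <- ncol(mask)
  ys <- seq(1, H, by = stride); xs <- seq(1, W, by = stride)
  hg <- matrix(NA_real_, length(ys), length(xs))
  for (iy in seq_along(ys)) for (ix in seq_along(xs)) {
    if (mask[ys[iy], xs[ix]])
      hg[iy, ix] <- height_at_pixel(edge, xs[ix], ys[iy], z_step_um)
  }
  in_mask <- mask[ys, xs, drop = FALSE]
  undef <- mean(is.na(hg[in_mask]))
  if (undef > max_undefined)
    stop(sprintf("height undefined at %.0f%% of grid pixels: unreliable map",
                 100 * undef))
  hg <- median_filter_na(hg, 3L)
  hg[!in_mask] <- NA_real_
  hg_full <- fill_nearest(hg)
  # bilinear interpolation from the stride grid to every pixel
  gx <- matrix(rep(seq_len(W), each = H), H, W)
  gy <- matrix(rep(seq_len(H), W), H, W)
  mx <- (gx - 1) / stride + 1
  my <- (gy - 1) / stride + 1
  mx <- pmin(mx, length(xs)); my <- pmin(my, length(ys))
  hmap <- warp_image(hg_full, mx, my, fill = NA_real_)
  hmap <- matrix(pmax(hmap, 0), H, W)
  hmap[!mask] <- NA_real_
  if (anyNA(hmap[mask])) hmap[mask] <- fill_nearest(
    ifelse(mask, hmap, NA_real_))[mask]
  structure(list(height_um = hmap, mask = mask, stride = stride,
                 undefined_fraction = undef, z_step_um = z_step_um),
            class = "HeightMap")
}

#' @export
print.HeightMap <- function(x, ...) {
  cat(sprintf("HeightMap: %d mask px, median height %.2f um (%.0f%% grid undefined)\n",
              sum(x$mask), median(x$height_um[x$mask]),
              100 * x$undefined_fraction))
  invisible(x)
}

#' Integrate a height map to a volume
#'
#' Numerical integration `V = sum(height) * pixel_area`; 1 pl = 1000 um^3.
#'
#' @param height_map a [build_height_map()] result.
#' @param pixel_size_um lateral pixel size (um).
#' @return volume in picoliters, with attribute `um3`.
#' @export
integrate_volume <- function(height_map, pixel_size_um) {
  h <- height_map$height_um[height_map$mask]
  if (anyNA(h)) stop("height map not fully defined on the mask")
  v_um3 <- sum(h) * pixel_size_um^2
  structure(v_um3 / 1000, um3 = v_um3)
}

#' Full height-map volume estimate for one z-stack timepoint
#'
#' Convenience pipeline: Richardson-Lucy deconvolution, footprint masking,
#' height-map extraction, and numerical integration.
#'
#' @param stack a single-channel [timelapse_stack()].
#' @param t frame index.
#' @param psf PSF passed to [richardson_lucy_3d()] (array or sigma list).
#' @param iterations deconvolution iterations.
#' @param stride height-grid step (px).
#' @return volume in pl (attribute `um3`), with the `HeightMap` attached as
#'   attribute `height_map`.
#' @export
estimate_cluster_volume <- function(stack, t = 1, psf = list(
    sigma_lateral_um = 0.3, sigma_axial_um = 0.8),
    iterations = 20, stride = 2) {
  stopifnot(inherits(stack, "TimelapseStack"))
  vol <- stack$data[t, , 1, , ]
  dec <- richardson_lucy_3d(vol, psf, iterations,
                            voxel_um = c(stack$z_step_um,
                                         stack$pixel_size_um,
                                         stack$pixel_size_um))
  mask <- cluster_mask(dec)
  hm <- build_height_map(dec, mask, stack$z_step_um, stride = stride)
  v <- integrate_volume(hm, stack$pixel_size_um)
  attr(v, "height_map") <- hm
  v
}

#' Relative volume trace with discontinuity flags
#'
#' Normalizes per-frame volumes to the pre-wound reference frame and flags
#' frames whose volume jumps more than `discontinuity_tol` relative to the
#' previous frame (automated stand-in for manual inspection of miscalculated
#' height maps).
#'
#' @param volumes_pl per-frame volumes (pl, > 0).
#' @param times_s optional per-frame times.
#' @param prewound_frame index of the pre-wound reference frame.
#' @param discontinuity_tol relative per-frame jump that triggers a flag.
#' @return object of class `VolumeTrace` with `volume_pl`,
#'   `relative_volume`, `flagged`.
#' @export
volume_trace <- function(volumes_pl, times_s = NULL, prewound_frame = 1,
                         discontinuity_tol = 0.25) {
  v <- as.numeric(volumes_pl)
  if (length(v) < 2) stop("need at least 2 frames")
  if (any(v <= 0)) stop("volumes must be positive")
  rel <- v / v[prewound_frame]
  jump <- c(0, abs(diff(v)) / head(v, -1))
  structure(list(times_s = times_s %||% seq_along(v) - 1,
                 volume_pl = v, relative_volume = rel,
                 prewound_frame = prewound_frame,
                 flagged = jump > discontinuity_tol),
            class = "VolumeTrace")
}

#' @export
print.VolumeTrace <- function(x, ...) {
  cat(sprintf("VolumeTrace: %d frames, V0 = %.3g pl, final relative volume %.3f%s\n",
              length(x$volume_pl), x$volume_pl[x$prewound_frame],
              tail(x$relative_volume, 1),
              if (any(x$flagged)) sprintf(" (%d flagged)", sum(x$flagged))
              else ""))
  invisible(x)
}
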