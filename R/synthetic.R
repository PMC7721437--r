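#' Seeded synthetic-microscopy generators
#'
#' Every generator returns a list with a [timelapse_stack()] and a
#' `GroundTruth` record holding the analytic truth (displacement model,
#' wavefront positions, analytic volumes, generator parameters), so the whole
#' analysis pipeline can be exercised against known answers. One global seed
#' fans out to per-generator sub-seeds via a counter scheme, so identical
#' spec + seed gives bit-identical output and adding a generator never
#' perturbs the others.
#'
#' @name synthetic
NULL

ground_truth <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth record:", x$kind, "\n")
  cat("  fields:", paste(setdiff(names(x), "kind"), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a ground-truth sidecar (lossless JSON round-trip)
#' @param gt a `GroundTruth` record.
#' @param path JSON path.
#' @rdname ground_truth_io
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ground_truth_io
#' @export
read_ground_truth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "GroundTruth")
}

# ---- cell-sheet phantom -----------------------------------------------------

#' Specification for a textured migrating cell-sheet phantom
#'
#' The sheet is a Voronoi tessellation with bright junction ridges (trackable
#' corners at cell vertices, emulating junctional F-actin signal) over dim
#' cytoplasmic speckle. A wound-directed displacement wave
#' `u(d, t) = A exp(-d / lambda) g(t - d / v)` (with `g` a Gaussian pulse in
#' time) advects the texture radially toward the wound; the wavefront is at
#' distance `v t` from the wound centroid at elapsed time `t`. A second
#' reference channel of static deep-tissue blobs carries only the rigid
#' whole-body drift.
#'
#' @param image_shape_px `(H, W)` image size in pixels.
#' @param pixel_size_um,frame_interval_s calibration.
#' @param n_frames number of frames (>= 2).
#' @param n_cells number of Voronoi cells.
#' @param junction_intensity,cytoplasm_intensity texture intensities (a.u.).
#' @param wave_speed_um_min wave propagation speed (um/min, >= 0).
#' @param wave_amplitude_um maximal material displacement (um, >= 0).
#' @param wave_decay_len_um exponential amplitude decay length (um, > 0).
#' @param pulse_width_s temporal width of the displacement pulse (s).
#' @param wound_centroid_px `(x, y)` wound centroid in pixels.
#' @param noise_model `list(gaussian_sd = ...)` or `list(poisson_scale = ...)`;
#'   `NULL` disables noise.
#' @param rigid_drift per-frame `(dx_px, dy_px, dtheta_rad)` increment, a
#'   length-3 vector or an `n_frames x 3` matrix.
#' @param seed integer seed.
#' @return object of class `SheetPhantomSpec`.
#' @export
sheet_phantom_spec <- function(image_shape_px = c(300, 600),
                               pixel_size_um = 0.65,
                               frame_interval_s = 30,
                               n_frames = 20,
                               n_cells = 500,
                               junction_intensity = 200,
                               cytoplasm_intensity = 60,
                               wave_speed_um_min = 40,
                               wave_amplitude_um = 3,
                               wave_decay_len_um = 600,
                               pulse_width_s = 60,
                               wound_centroid_px = NULL,
                               noise_model = list(gaussian_sd = 3),
                               rigid_drift = c(0, 0, 0),
                               seed = 1L) {
  if (wave_decay_len_um <= 0) stop("wave_decay_len_um must be > 0")
  if (wave_speed_um_min < 0 || wave_amplitude_um < 0)
    stop("wave speed and amplitude must be >= 0")
  if (n_frames < 2) stop("need at least 2 frames")
  if (is.null(wound_centroid_px))
    wound_centroid_px <- c(5, image_shape_px[1] / 2)
  if (is.null(dim(rigid_drift)))
    rigid_drift <- matrix(rigid_drift, n_frames, 3, byrow = TRUE)
  structure(list(
    image_shape_px = image_shape_px, pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s, n_frames = n_frames,
    n_cells = n_cells, junction_intensity = junction_intensity,
    cytoplasm_intensity = cytoplasm_intensity,
    wave_speed_um_min = wave_speed_um_min,
    wave_amplitude_um = wave_amplitude_um,
    wave_decay_len_um = wave_decay_len_um,
    pulse_width_s = pulse_width_s,
    wound_centroid_px = wound_centroid_px,
    noise_model = noise_model, rigid_drift = rigid_drift, seed = seed),
    class = "SheetPhantomSpec")
}

# Distances to nearest and second-nearest Voronoi seed, chunked so the
# pixel x seed distance matrix stays small.
.voronoi_d12 <- function(px, py, seeds) {
  n <- length(px)
  d1 <- numeric(n); d2 <- numeric(n)
  ss <- rowSums(seeds^2)
  chunk <- 20000L
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    P <- cbind(px[i0:i1], py[i0:i1])
    D <- outer(rowSums(P^2), ss, "+") - 2 * tcrossprod(P, seeds)
    j1 <- max.col(-D)
    ii <- seq_len(nrow(D))
    d1[i0:i1] <- D[cbind(ii, j1)]
    D[cbind(ii, j1)] <- Inf
    j2 <- max.col(-D)
    d2[i0:i1] <- D[cbind(ii, j2)]
  }
  list(d1 = sqrt(pmax(d1, 0)), d2 = sqrt(pmax(d2, 0)))
}

.sheet_texture <- function(H, W, n_cells, junction, cytoplasm,
                           ridge_width_px = 1.2) {
  seeds <- cbind(runif(n_cells, 1, W), runif(n_cells, 1, H))
  px <- rep(seq_len(W), each = H)
  py <- rep(seq_len(H), W)
  d <- .voronoi_d12(px, py, seeds)
  ridge <- exp(-((d$d2 - d$d1) / (2 * ridge_width_px))^2)
  speck <- gauss_blur2d(matrix(rnorm(H * W), H, W), 1.2)
  speck <- speck / max(1e-9, sd(speck))
  tex <- matrix(cytoplasm, H, W) * (1 + 0.15 * speck) +
    junction * matrix(ridge, H, W)
  pmax(tex, 0)
}

.blob_texture <- function(H, W, n_blobs = round(H * W / 120), intensity = 120) {
  img <- matrix(0, H, W)
  bx <- runif(n_blobs, 1, W); by <- runif(n_blobs, 1, H)
  amp <- runif(n_blobs, 0.3, 1)
  img[cbind(pmax(1, pmin(H, round(by))), pmax(1, pmin(W, round(bx))))] <-
    amp * intensity / 0.04  # mass concentrated then spread by blur
  gauss_blur2d(img, 2.5) + 5
}

.apply_noise <- function(img, noise_model) {
  if (is.null(noise_model) || length(noise_model) == 0) return(img)
  if (!is.null(noise_model$gaussian_sd) && noise_model$gaussian_sd > 0) {
    img <- img + matrix(rnorm(length(img), sd = noise_model$gaussian_sd),
                        nrow(img))
  }
  if (!is.null(noise_model$poisson_scale) && noise_model$poisson_scale > 0) {
    s <- noise_model$poisson_scale
    img <- matrix(rpois(length(img), lambda = pmax(img, 0) * s) / s, nrow(img))
  }
  pmax(img, 0)
}

# Cumulative rigid transform (about the image center) up to frame t.
.drift_cumulative <- function(rigid_drift, n_frames) {
  cum <- apply(rigid_drift, 2, cumsum)
  cum <- rbind(rep(0, 3), cum)[seq_len(n_frames), , drop = FALSE]
  cum
}

#' Analytic sheet displacement (ground truth)
#'
#' Displacement (in um, directed toward the wound) of the material point at
#' rest position `(x, y)` px at elapsed time `t_s` seconds.
#'
#' @param gt `GroundTruth` from [make_sheet_timelapse()].
#' @param x,y rest positions, px.
#' @param t_s elapsed time, s.
#' @return list with displacement components `ux_px`, `uy_px` (px) and
#'   magnitude `u_um`.
#' @export
sheet_displacement <- function(gt, x, y, t_s) {
  p <- gt$params
  dx <- (x - p$wound_centroid_px[1]) * p$pixel_size_um
  dy <- (y - p$wound_centroid_px[2]) * p$pixel_size_um
  d <- sqrt(dx^2 + dy^2)
  v <- p$wave_speed_um_min / 60
  u_um <- if (v > 0) {
    s <- t_s - d / v
    p$wave_amplitude_um * exp(-d / p$wave_decay_len_um) *
      exp(-s^2 / (2 * p$pulse_width_s^2))
  } else 0 * d
  ux <- -u_um * dx / pmax(d, 1e-9) / p$pixel_size_um
  uy <- -u_um * dy / pmax(d, 1e-9) / p$pixel_size_um
  list(ux_px = ux, uy_px = uy, u_um = u_um)
}

#' Generate a migrating cell-sheet timelapse phantom
#'
#' @param spec a [sheet_phantom_spec()].
#' @return list with elements `stack` (two channels: `actin` carrying drift +
#'   displacement wave, `myosin` reference carrying drift only) and
#'   `ground_truth`.
#' @export
make_sheet_timelapse <- function(spec) {
  stopifnot(inherits(spec, "SheetPhantomSpec"))
  H <- spec$image_shape_px[1]; W <- spec$image_shape_px[2]
  nT <- spec$n_frames
  with_seed(fan_seed(spec$seed, "sheet"), {
    tex_act <- .sheet_texture(H, W, spec$n_cells, spec$junction_intensity,
                              spec$cytoplasm_intensity)
    tex_ref <- .blob_texture(H, W)
    cum <- .drift_cumulative(spec$rigid_drift, nT)
    cx <- (W + 1) / 2; cy <- (H + 1) / 2
    gx <- matrix(rep(seq_len(W), each = H), H, W)
    gy <- matrix(rep(seq_len(H), W), H, W)
    wcx <- spec$wound_centroid_px[1]; wcy <- spec$wound_centroid_px[2]
    v_um_s <- spec$wave_speed_um_min / 60
    arr <- array(0, c(nT, 1, 2, H, W))
    front <- numeric(nT)
    gt <- ground_truth(
      "sheet",
      params = list(
        pixel_size_um = spec$pixel_size_um,
        frame_interval_s = spec$frame_interval_s,
        wound_centroid_px = spec$wound_centroid_px,
        wave_speed_um_min = spec$wave_speed_um_min,
        wave_amplitude_um = spec$wave_amplitude_um,
        wave_decay_len_um = spec$wave_decay_len_um,
        pulse_width_s = spec$pulse_width_s),
      drift_cumulative = cum,
      wavefront_um = front, times_s = (seq_len(nT) - 1) * spec$frame_interval_s,
      spec = spec[setdiff(names(spec), "noise_model")])
    for (t in seq_len(nT)) {
      t_s <- (t - 1) * spec$frame_interval_s
      th <- cum[t, 3]
      # inverse of the rigid drift: frame coords -> reference coords
      xs <- gx - cum[t, 1] - cx
      ys <- gy - cum[t, 2] - cy
      rx <- cos(-th) * xs - sin(-th) * ys + cx
      ry <- sin(-th) * xs + cos(-th) * ys + cy
      # wave: material points move toward the wound (backward warp)
      ddx <- (rx - wcx) * spec$pixel_size_um
      ddy <- (ry - wcy) * spec$pixel_size_um
      d <- sqrt(ddx^2 + ddy^2)
      if (v_um_s > 0) {
        s <- t_s - d / v_um_s
        u_um <- spec$wave_amplitude_um * exp(-d / spec$wave_decay_len_um) *
          exp(-s^2 / (2 * spec$pulse_width_s^2))
      } else {
        u_um <- 0 * d                      # no propagation: sheet is static
      }
      u_px <- u_um / spec$pixel_size_um
      ax <- rx + u_px * ddx / pmax(d, 1e-9)
      ay <- ry + u_px * ddy / pmax(d, 1e-9)
      f_act <- warp_image(tex_act, ax, ay, fill = 0)
      f_ref <- warp_image(tex_ref, rx, ry, fill = 0)
      arr[t, 1, 1, , ] <- .apply_noise(f_act, spec$noise_model)
      arr[t, 1, 2, , ] <- .apply_noise(f_ref, spec$noise_model)
      front[t] <- v_um_s * t_s
    }
    gt$wavefront_um <- front
    list(stack = timelapse_stack(arr, spec$pixel_size_um, 1,
                                 spec$frame_interval_s,
                                 c("actin", "myosin")),
         ground_truth = gt)
  })
}

# ---- calcium phantom --------------------------------------------------------

#' Specification for a calcium-wave timelapse phantom
#'
#' A GCaMP-like channel rides on a smooth random expression map shared with a
#' constant nuclear-reference channel (so the reference ratio cancels
#' expression variation). After `n_prewound_frames` baseline frames a
#' sigmoidal activation front leaves the wound margin and advances at
#' `front_speed_um_min`; activated tissue has relative intensity
#' `1 + peak_dff`.
#'
#' @inheritParams sheet_phantom_spec
#' @param front_speed_um_min activation front speed (um/min, >= 0).
#' @param baseline baseline GCaMP intensity (a.u.).
#' @param peak_dff plateau delta-F/F0 behind the front (>= 0).
#' @param front_width_um sigmoid width of the front (um).
#' @param n_prewound_frames baseline frames before wounding.
#' @return object of class `CalciumPhantomSpec`.
#' @export
calcium_phantom_spec <- function(image_shape_px = c(256, 920),
                                 pixel_size_um = 0.65,
                                 frame_interval_s = 30,
                                 n_frames = 14,
                                 front_speed_um_min = 200,
                                 baseline = 100,
                                 peak_dff = 1.5,
                                 front_width_um = 15,
                                 n_prewound_frames = 3,
                                 wound_centroid_px = NULL,
                                 noise_model = list(gaussian_sd = 2),
                                 seed = 1L) {
  if (front_speed_um_min < 0) stop("front_speed_um_min must be >= 0")
  if (peak_dff < 0) stop("peak_dff must be >= 0")
  if (is.null(wound_centroid_px))
    wound_centroid_px <- c(5, image_shape_px[1] / 2)
  structure(list(
    image_shape_px = image_shape_px, pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s, n_frames = n_frames,
    front_speed_um_min = front_speed_um_min, baseline = baseline,
    peak_dff = peak_dff, front_width_um = front_width_um,
    n_prewound_frames = n_prewound_frames,
    wound_centroid_px = wound_centroid_px,
    noise_model = noise_model, seed = seed),
    class = "CalciumPhantomSpec")
}

#' Generate a calcium-wave timelapse phantom
#'
#' @param spec a [calcium_phantom_spec()].
#' @return list with `stack` (channels `gcamp`, `nuclear`) and `ground_truth`
#'   (front position per frame, in um from the wound centroid).
#' @export
make_calcium_timelapse <- function(spec) {
  stopifnot(inherits(spec, "CalciumPhantomSpec"))
  H <- spec$image_shape_px[1]; W <- spec$image_shape_px[2]
  nT <- spec$n_frames
  with_seed(fan_seed(spec$seed, "calcium"), {
    expr <- gauss_blur2d(matrix(rnorm(H * W), H, W), 8)
    expr <- 1 + 0.4 * expr / max(1e-9, sd(expr))
    expr <- pmax(expr, 0.2)
    gx <- matrix(rep(seq_len(W), each = H), H, W)
    d_um <- abs(gx - spec$wound_centroid_px[1]) * spec$pixel_size_um
    v <- spec$front_speed_um_min / 60
    arr <- array(0, c(nT, 1, 2, H, W))
    front <- numeric(nT)
    for (t in seq_len(nT)) {
      t_s <- (t - spec$n_prewound_frames - 1) * spec$frame_interval_s
      if (t_s < 0) {
        act <- matrix(0, H, W)
        front[t] <- 0
      } else {
        fp <- v * t_s
        act <- 1 / (1 + exp((d_um - fp) / spec$front_width_um))
        front[t] <- fp
      }
      g <- spec$baseline * expr * (1 + spec$peak_dff * act)
      r <- 80 * expr
      arr[t, 1, 1, , ] <- .apply_noise(g, spec$noise_model)
      arr[t, 1, 2, , ] <- .apply_noise(r, spec$noise_model)
    }
    gt <- ground_truth("calcium",
                       params = list(
                         pixel_size_um = spec$pixel_size_um,
                         frame_interval_s = spec$frame_interval_s,
                         front_speed_um_min = spec$front_speed_um_min,
                         peak_dff = spec$peak_dff,
                         n_prewound_frames = spec$n_prewound_frames,
                         wound_centroid_px = spec$wound_centroid_px),
                       front_position_um = front,
                       times_s = (seq_len(nT) - 1) * spec$frame_interval_s)
    list(stack = timelapse_stack(arr, spec$pixel_size_um, 1,
                                 spec$frame_interval_s,
                                 c("gcamp", "nuclear")),
         ground_truth = gt)
  })
}

# ---- cell-cluster z-stack phantom ------------------------------------------

#' Specification for a 3D cell-cluster phantom of known analytic volume
#'
#' @param shape `"hemisphere"` (flat base, radius `radii_um[1]`),
#'   `"ellipsoid"` (semi-axes `radii_um = c(ax, ay, az)`), or `"slab"`
#'   (rectangular box with half-extents `radii_um = c(hx, hy, hz)`).
#' @param radii_um shape radii/half-extents in um.
#' @param pixel_size_um,z_step_um voxel calibration.
#' @param psf_sigma_um `(lateral, axial)` Gaussian PSF sigmas (um).
#' @param interior_intensity cytoplasmic intensity (a.u.).
#' @param noise_model as in [sheet_phantom_spec()]; `list(poisson_scale = s)`
#'   gives shot noise with `s` photons per intensity unit.
#' @param volume_scale_after ground-truth volume scale factor at the second
#'   timepoint (isotropic swelling; > 0).
#' @param seed integer seed.
#' @return object of class `ClusterPhantomSpec`.
#' @export
cluster_phantom_spec <- function(shape = c("hemisphere", "ellipsoid", "slab"),
                                 radii_um = 12,
                                 pixel_size_um = 0.25,
                                 z_step_um = 0.5,
                                 psf_sigma_um = c(0.3, 0.8),
                                 interior_intensity = 100,
                                 noise_model = list(poisson_scale = 2),
                                 volume_scale_after = 1.5,
                                 seed = 1L) {
  shape <- match.arg(shape)
  if (volume_scale_after <= 0) stop("volume_scale_after must be > 0")
  structure(list(shape = shape, radii_um = radii_um,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 psf_sigma_um = psf_sigma_um,
                 interior_intensity = interior_intensity,
                 noise_model = noise_model,
                 volume_scale_after = volume_scale_after, seed = seed),
            class = "ClusterPhantomSpec")
}

.analytic_volume <- function(shape, r) {
  switch(shape,
         hemisphere = 2 / 3 * pi * r[1]^3,
         ellipsoid = 4 / 3 * pi * r[1] * r[2] * r[3],
         slab = 8 * r[1] * r[2] * r[3])
}

# occupancy fraction of each voxel, 2x supersampled per axis
.render_cluster <- function(shape, r, z0_um, nz, H, W, px, zs) {
  sub <- c(-0.25, 0.25)
  occ <- array(0, c(nz, H, W))
  xs <- (seq_len(W) - (W + 1) / 2) * px
  ys <- (seq_len(H) - (H + 1) / 2) * px
  zv <- (seq_len(nz) - 1) * zs
  for (oz in sub) for (oy in sub) for (ox in sub) {
    X <- rep(xs + ox * px, each = H)
    Y <- rep(ys + oy * px, W)
    plane_in <- switch(shape,
      hemisphere = (X^2 + Y^2),
      ellipsoid = (X / r[1])^2 + (Y / r[2])^2,
      slab = NULL)
    for (iz in seq_len(nz)) {
      z <- zv[iz] + oz * zs - z0_um
      inside <- switch(shape,
        hemisphere = z >= 0 & (plane_in + z^2) <= r[1]^2,
        ellipsoid = (plane_in + ((z - r[3]) / r[3])^2) <= 1,
        slab = abs(X) <= r[1] & abs(Y) <= r[2] & z >= 0 & z <= 2 * r[3])
      occ[iz, , ] <- occ[iz, , ] + matrix(inside, H, W) / 8
    }
  }
  occ
}

#' Generate before/after z-stacks of a cell cluster of known volume
#'
#' The second timepoint's object is scaled isotropically so its ground-truth
#' volume equals `volume_scale_after` times the first. Stacks are blurred
#' with a separable Gaussian PSF and carry the configured noise.
#'
#' @param spec a [cluster_phantom_spec()].
#' @return list with `stack` (T = 2, single channel) and `ground_truth`
#'   (analytic volumes in um^3, clipping flag).
#' @export
make_cluster_stack <- function(spec) {
  stopifnot(inherits(spec, "ClusterPhantomSpec"))
  r1 <- spec$radii_um
  if (spec$shape != "hemisphere" && length(r1) < 3)
    stop("ellipsoid/slab need 3 radii")
  s_lin <- spec$volume_scale_after^(1 / 3)
  r2 <- r1 * s_lin
  px <- spec$pixel_size_um; zs <- spec$z_step_um
  sl <- spec$psf_sigma_um[1]; sa <- spec$psf_sigma_um[2]
  rmax_xy <- if (spec$shape == "hemisphere") r2[1] else max(r2[1:2])
  hmax <- if (spec$shape == "hemisphere") r2[1] else 2 * r2[3]
  margin <- 3 * sl + 1.5
  W <- H <- 2L * as.integer(ceiling((rmax_xy + margin) / px)) + 1L
  z0_um <- 3 * sa + 0.75
  nz <- as.integer(ceiling((z0_um + hmax + 3 * sa + 0.75) / zs)) + 1L
  clipped <- FALSE
  with_seed(fan_seed(spec$seed, "cluster"), {
    arr <- array(0, c(2, nz, 1, H, W))
    for (tp in 1:2) {
      r <- if (tp == 1) r1 else r2
      occ <- .render_cluster(spec$shape, r, z0_um, nz, H, W, px, zs)
      img <- spec$interior_intensity *
        pmax(gauss_blur3d(occ, c(sa / zs, sl / px, sl / px)), 0)
      for (z in seq_len(nz)) {
        arr[tp, z, 1, , ] <- .apply_noise(img[z, , ], spec$noise_model)
      }
    }
    v1 <- .analytic_volume(spec$shape, if (length(r1) == 1) rep(r1, 3) else r1)
    gt <- ground_truth("cluster",
                       analytic_volume_um3 = c(v1, v1 * spec$volume_scale_after),
                       volume_scale_after = spec$volume_scale_after,
                       clipped = clipped,
                       params = list(shape = spec$shape, radii_um = r1,
                                     pixel_size_um = px, z_step_um = zs,
                                     psf_sigma_um = spec$psf_sigma_um,
                                     base_z_um = z0_um))
    list(stack = timelapse_stack(arr, px, zs, 45, "mneongreen"),
         ground_truth = gt)
  })
}

# ---- droplet calibration images --------------------------------------------

#' Generate droplet calibration images following a saturation binding curve
#'
#' One image per sodium concentration: mean droplet intensity equals
#' `background + vignette(x, y) * Imax [Na] / (Kd + [Na])` plus noise, with a
#' radial parabolic vignetting profile. A matching flat-field image (the
#' vignette itself, as imaged from a uniform fluorescent standard) is
#' returned for the correction step.
#'
#' @param imax saturating intensity (a.u.).
#' @param kd_mM dissociation constant (mM, > 0).
#' @param concentrations_mM sodium concentrations (>= 0).
#' @param vignette_strength relative corner falloff of the vignette in
#'   `[0, 1)`.
#' @param background_level additive background (a.u.).
#' @param noise_sd Gaussian noise sd (a.u.); 0 disables noise.
#' @param image_size `(H, W)` in px.
#' @param seed integer seed.
#' @return list with `images` (list of matrices, one per concentration),
#'   `flatfield`, `background`, and `ground_truth`.
#' @export
make_calibration_images <- function(imax = 1.1529, kd_mM = 138,
                                    concentrations_mM = c(0, 25, 50, 100, 150, 200, 300),
                                    vignette_strength = 0.3,
                                    background_level = 0.05,
                                    noise_sd = 0,
                                    image_size = c(64, 64),
                                    seed = 1L) {
  if (kd_mM <= 0) stop("kd_mM must be > 0")
  if (any(concentrations_mM < 0)) stop("concentrations must be >= 0")
  H <- image_size[1]; W <- image_size[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rr <- outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+")
  vig <- 1 - vignette_strength * rr / max(rr)
  with_seed(fan_seed(seed, "calibration"), {
    true_int <- imax * concentrations_mM / (kd_mM + concentrations_mM)
    imgs <- lapply(seq_along(concentrations_mM), function(i) {
      img <- background_level + vig * true_int[i]
      if (noise_sd > 0) img <- img + matrix(rnorm(H * W, sd = noise_sd), H, W)
      pmax(img, 0)
    })
    gt <- ground_truth("calibration", imax = imax, kd_mM = kd_mM,
                       concentrations_mM = concentrations_mM,
                       true_intensity = true_int,
                       vignette_strength = vignette_strength,
                       background_level = background_level)
    list(images = imgs, flatfield = vig, background = background_level,
         ground_truth = gt)
  })
}
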