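# Independent oracles used by the tests; deliberately simple and separate
# from the package's own implementation paths.

# Sub-pixel phase-correlation shift: returns (dx, dy) such that
# b(x, y) ~ a(x - dx, y - dy).
phase_corr_shift <- function(a, b) {
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  R <- Fa * Conj(Fb)
  R <- R / pmax(Mod(R), 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(a)
  H <- nrow(r); W <- ncol(r)
  pk <- which.max(r)
  py <- ((pk - 1) %% H) + 1
  px <- ((pk - 1) %/% H) + 1
  refine <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (abs(den) < 1e-12) 0 else 0.5 * (m1 - p1) / den
  }
  ym <- r[((py - 2) %% H) + 1, px]; yp <- r[(py %% H) + 1, px]
  xm <- r[py, ((px - 2) %% W) + 1]; xp <- r[py, (px %% W) + 1]
  dy <- (py - 1) + refine(ym, r[py, px], yp)
  dx <- (px - 1) + refine(xm, r[py, px], xp)
  if (dy > H / 2) dy <- dy - H
  if (dx > W / 2) dx <- dx - W
  c(dx = -dx, dy = -dy)
}

# Integer circular shift of a matrix (exact).
roll2 <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  m[((seq_len(H) - 1 - dy) %% H) + 1, ((seq_len(W) - 1 - dx) %% W) + 1]
}

# Hand-built PointTracks object for arithmetic tests.
make_tracks <- function(x, y, pixel_size_um = 1, frame_interval_s = 60) {
  structure(list(x = x, y = y, valid = !is.na(x),
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "PointTracks")
}

# Small shared phantoms, built once per test session.
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

small_sheet <- function() fixture("small_sheet", function() {
  make_sheet_timelapse(sheet_phantom_spec(
    image_shape_px = c(160, 300), n_frames = 8, n_cells = 220,
    wave_speed_um_min = 40, wave_amplitude_um = 2.5,
    wound_centroid_px = c(5, 80), noise_model = list(gaussian_sd = 2),
    seed = 42))
})

drift_sheet <- function() fixture("drift_sheet", function() {
  make_sheet_timelapse(sheet_phantom_spec(
    image_shape_px = c(170, 230), n_frames = 5, n_cells = 150,
    wave_amplitude_um = 0, rigid_drift = c(2.5, -1.5, 0),
    noise_model = list(gaussian_sd = 1.5), seed = 13))
})

dff_sheet <- function() fixture("dff_sheet", function() {
  make_sheet_timelapse(sheet_phantom_spec(
    image_shape_px = c(120, 150), n_frames = 5, n_cells = 130,
    wave_amplitude_um = 2, wave_decay_len_um = 300, noise_model = NULL,
    wound_centroid_px = c(5, 60), seed = 23))
})

dff_sheet_fields <- function() fixture("dff_sheet_fields", function() {
  frames <- max_project_z(dff_sheet()$stack, 1)
  lapply(2:5, function(t) demons_field(frames[[t]], frames[[t - 1]]))
})

small_wound <- function() {
  wound_annotation(rbind(c(2, 60), c(9, 60), c(9, 100), c(2, 100)),
                   centroid = c(5, 80))
}
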