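#' Calibrated timelapse image container
#'
#' A `TimelapseStack` holds a 5-dimensional intensity array in the canonical
#' `T x Z x C x Y x X` axis order together with its physical calibration.
#' Pixel coordinates are 1-based pixel centers with `x` = column and `y` = row;
#' all physical distances are reported in micrometres.
#'
#' @param data numeric array with dimensions `T x Z x C x Y x X`; intensities
#'   must be finite and non-negative.
#' @param pixel_size_um lateral pixel size in um/px (> 0).
#' @param z_step_um axial spacing in um (> 0).
#' @param frame_interval_s time between frames in seconds (> 0).
#' @param channel_names character vector, one name per channel.
#' @return an object of class `TimelapseStack`.
#' @export
timelapse_stack <- function(data, pixel_size_um, z_step_um = 1,
                            frame_interval_s = 1,
                            channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 5L)
    stop("`data` must be a 5-d array (T x Z x C x Y x X)")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(data))) stop("intensities must be finite")
  if (min(data) < 0) stop("intensities must be non-negative")
  for (v in c(pixel_size_um, z_step_um, frame_interval_s)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("calibration metadata must be strictly positive scalars")
  }
  nc <- dim(data)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("need one channel name per channel")
  structure(
    list(data = data, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
         frame_interval_s = frame_interval_s,
         channel_names = as.character(channel_names)),
    class = "TimelapseStack")
}

#' @export
print.TimelapseStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "TimelapseStack: %d frame(s) x %d z x %d channel(s) x %d x %d px\n",
    d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  pixel %g um/px, z-step %g um, frame interval %g s\n",
              x$pixel_size_um, x$z_step_um, x$frame_interval_s))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.TimelapseStack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[1]

# Extract one 2D plane [y, x].
stack_plane <- function(stack, t, z = 1, c = 1) {
  stack$data[t, z, c, , ]
}

sidecar_path <- function(path) {
  sub("\\.(tiff?|ome\\.tiff?)$", ".json", path, ignore.case = TRUE)
}

#' Write a timelapse stack to multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are written in `T`-major, then `Z`, then `C` order as 32-bit float
#' TIFF, scaled by a power of two recorded in the sidecar so integer-valued
#' data (counts below 2^24) round-trips exactly.
#'
#' @param stack a [timelapse_stack()].
#' @param path output `.tif` path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "TimelapseStack"))
  d <- dim(stack$data)
  mx <- max(stack$data)
  scale <- 2^ceiling(log2(max(mx, 1)))
  is_int <- all(stack$data == round(stack$data)) && mx < 2^31
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    pages[[i]] <- stack$data[t, z, ch, , ] / scale
    i <- i + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(page_axes = "TZC", shape = d,
               pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               frame_interval_s = stack$frame_interval_s,
               channel_names = stack$channel_names,
               intensity_scale = scale, integer_data = is_int)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a timelapse stack from TIFF
#'
#' Reads a multi-page TIFF plus its JSON sidecar (written by [write_stack()]
#' or equivalent). The sidecar's `page_axes` field states which non-spatial
#' axes the page sequence unrolls (slowest first, any permutation of "TZC");
#' the in-memory array is always normalized to `T x Z x C x Y x X`. Without a
#' sidecar the pixel size is taken from the TIFF resolution tags; if neither
#' source provides it, an error is raised rather than assuming a default.
#'
#' @param path TIFF path.
#' @param pixel_size_um,z_step_um,frame_interval_s optional overrides used
#'   when the file carries no metadata.
#' @return a [timelapse_stack()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, z_step_um = NULL,
                       frame_interval_s = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    shape <- as.integer(meta$shape)
    axes <- strsplit(meta$page_axes, "")[[1]]
    stopifnot(setequal(axes, c("T", "Z", "C")))
    npag <- prod(shape[1:3])
    if (npag != length(pages)) stop("page count does not match sidecar shape")
    ax_sizes <- shape[match(axes, c("T", "Z", "C"))]
    arr <- array(NA_real_, c(shape[1], shape[2], shape[3], shape[4], shape[5]))
    i <- 1L
    idx <- integer(3)
    for (a1 in seq_len(ax_sizes[1])) for (a2 in seq_len(ax_sizes[2]))
      for (a3 in seq_len(ax_sizes[3])) {
        idx[match(axes, c("T", "Z", "C"))] <- c(a1, a2, a3)
        arr[idx[1], idx[2], idx[3], , ] <- pages[[i]]
        i <- i + 1L
      }
    arr <- arr * (meta$intensity_scale %||% 1)
    # pages are stored on a 32-bit integer grid; snap integer-valued data
    # back onto exact integers so counts round-trip losslessly
    if (isTRUE(meta$integer_data)) arr <- round(arr)
    return(timelapse_stack(
      arr,
      pixel_size_um = pixel_size_um %||% meta$pixel_size_um,
      z_step_um = z_step_um %||% meta$z_step_um %||% 1,
      frame_interval_s = frame_interval_s %||% meta$frame_interval_s %||% 1,
      channel_names = meta$channel_names))
  }
  # no sidecar: single-channel, single-z timelapse; need a pixel size
  if (is.null(pixel_size_um)) {
    info <- attributes(pages[[1]])
    xres <- info$x.resolution
    unit <- info$resolution.unit %||% "inch"
    if (!is.null(xres) && is.finite(xres) && xres > 0) {
      per_um <- switch(as.character(unit),
                       cm = xres / 1e4, inch = xres / 25400, xres)
      pixel_size_um <- 1 / per_um
    } else {
      stop("pixel size unavailable: no sidecar, no TIFF resolution tags, ",
           "and no `pixel_size_um` given")
    }
  }
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  arr <- array(NA_real_, c(length(pages), 1, 1, H, W))
  for (t in seq_along(pages)) arr[t, 1, 1, , ] <- pages[[t]]
  timelapse_stack(arr, pixel_size_um = pixel_size_um,
                  z_step_um = z_step_um %||% 1,
                  frame_interval_s = frame_interval_s %||% 1)
}

#' Maximum-intensity z-projection
#'
#' @param stack a [timelapse_stack()].
#' @param channel channel index or name.
#' @return list of `Y x X` matrices, one per frame.
#' @export
max_project_z <- function(stack, channel = 1) {
  stopifnot(inherits(stack, "TimelapseStack"))
  ch <- resolve_channel(stack, channel)
  d <- dim(stack$data)
  lapply(seq_len(d[1]), function(t) {
    if (d[2] == 1L) stack$data[t, 1, ch, , ]
    else apply(stack$data[t, , ch, , , drop = FALSE], c(4, 5), max)
  })
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    ch <- match(channel, stack$channel_names)
    if (is.na(ch)) stop("unknown channel: ", channel)
    ch
  } else {
    ch <- as.integer(channel)
    if (ch < 1 || ch > dim(stack$data)[3]) stop("channel out of range")
    ch
  }
}

#' Background subtraction and flat-field correction
#'
#' Computes `(image - background) / flatfield` with the flat-field first
#' normalized to unit mean, so corrected intensities keep the scale of the
#' input.
#'
#' @param image numeric matrix.
#' @param background scalar or matrix of the same size.
#' @param flatfield strictly positive matrix (or scalar) sensitivity profile.
#' @return corrected matrix.
#' @export
background_flatfield_correct <- function(image, background = 0,
                                         flatfield = 1) {
  if (length(flatfield) == 1L) flatfield <- matrix(flatfield, nrow(image), ncol(image))
  if (any(flatfield <= 0)) stop("flatfield must be strictly positive")
  ff <- flatfield / mean(flatfield)
  (image - background) / ff
}

#' Mask the reference channel by thresholded signal-channel intensity
#'
#' Voxels whose signal-channel intensity exceeds a threshold are zeroed in
#' the reference channel before maximum projection, so structures not
#' overlapping the signal-expressing tissue dominate the projection (used to
#' register whole-body drift against non-migrating structures).
#'
#' @param stack two-channel [timelapse_stack()].
#' @param signal_channel,reference_channel channel indices or names.
#' @param threshold_method `"otsu"` (per-frame Otsu on the signal projection)
#'   or a numeric threshold.
#' @return list of masked reference-channel z-projections (one per frame).
#' @export
mask_reference_channel <- function(stack, signal_channel = 1,
                                   reference_channel = 2,
                                   threshold_method = "otsu") {
  cs <- resolve_channel(stack, signal_channel)
  cr <- resolve_channel(stack, reference_channel)
  d <- dim(stack$data)
  out <- vector("list", d[1])
  removed <- numeric(d[1])
  for (t in seq_len(d[1])) {
    sig_proj <- if (d[2] == 1L) stack$data[t, 1, cs, , ]
      else apply(stack$data[t, , cs, , , drop = FALSE], c(4, 5), max)
    thr <- if (is.numeric(threshold_method)) threshold_method
      else otsu_threshold(sig_proj)
    ref <- stack$data[t, , cr, , , drop = FALSE]
    if (max(sig_proj) <= min(sig_proj)) {
      mask2d <- matrix(FALSE, d[4], d[5])      # flat signal: nothing to mask
    } else {
      mask2d <- sig_proj > thr
    }
    tot <- sum(ref)
    for (z in seq_len(d[2])) {
      plane <- ref[1, z, 1, , ]
      plane[mask2d] <- 0
      ref[1, z, 1, , ] <- plane
    }
    rem <- if (tot > 0) 1 - sum(ref) / tot else 0
    removed[t] <- rem
    out[[t]] <- apply(ref, c(4, 5), max)
  }
  if (any(removed > 0.95))
    warning("signal mask removed > 95% of reference intensity in ",
            sum(removed > 0.95), " frame(s)")
  out
}

#' Wound annotation
#'
#' @param polygon matrix or data.frame of `(x, y)` vertices in pixels.
#' @param centroid optional `(x, y)` centroid; defaults to the polygon
#'   vertex mean.
#' @param exclusion_radius_um radius around the wound excluded from
#'   intensity summaries.
#' @return object of class `WoundAnnotation`.
#' @export
wound_annotation <- function(polygon, centroid = NULL,
                             exclusion_radius_um = 0) {
  poly <- as.matrix(polygon)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  if (is.null(centroid)) centroid <- colMeans(poly)
  centroid <- as.numeric(centroid)
  bb <- apply(poly, 2, range)
  if (centroid[1] < bb[1, 1] || centroid[1] > bb[2, 1] ||
      centroid[2] < bb[1, 2] || centroid[2] > bb[2, 2])
    stop("centroid outside polygon bounding box")
  structure(list(polygon = poly, centroid = centroid,
                 exclusion_radius_um = exclusion_radius_um),
            class = "WoundAnnotation")
}

#' @export
print.WoundAnnotation <- function(x, ...) {
  cat(sprintf("WoundAnnotation: %d vertices, centroid (%.1f, %.1f) px\n",
              nrow(x$polygon), x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Read/write wound annotations as GeoJSON-style polygons
#' @param wound a [wound_annotation()].
#' @param path JSON file path.
#' @rdname wound_annotation_io
#' @export
write_wound_annotation <- function(wound, path) {
  jsonlite::write_json(
    list(type = "Polygon",
         coordinates = list(unname(as.matrix(wound$polygon))),
         centroid = wound$centroid,
         exclusion_radius_um = wound$exclusion_radius_um),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname wound_annotation_io
#' @export
read_wound_annotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- j$coordinates
  poly <- if (is.array(co) && length(dim(co)) == 3) co[1, , ]
    else if (is.list(co)) co[[1]] else co
  wound_annotation(poly, centroid = j$centroid,
                   exclusion_radius_um = j$exclusion_radius_um %||% 0)
}
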