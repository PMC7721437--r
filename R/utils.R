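#' @importFrom stats rnorm rpois runif median quantile sd var lm coef fft
#'   density predict pf pt ptukey qnorm setNames complete.cases na.omit
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Counter-based fan-out of one global seed into independent per-generator
# sub-seeds; adding a new stream name never perturbs existing ones.
fan_seed <- function(seed, stream) {
  v <- utf8ToInt(stream)
  h <- sum(v * seq_along(v) * 131) %% 1000003
  as.integer(((seed %% 999983) * 48271 + h * 69621 + 7) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- image primitives -------------------------------------------------------
# Images are numeric matrices indexed [y, x] (row = y, column = x); pixel
# centers sit at integer 1-based coordinates.

#' Bilinear interpolation of image values at arbitrary positions
#'
#' @param img numeric matrix indexed `[y, x]`.
#' @param x,y numeric vectors of sample positions (1-based pixel centers).
#' @param fill value returned outside the image footprint.
#' @return numeric vector of sampled intensities.
#' @keywords internal
bilinear_sample <- function(img, x, y, fill = NA_real_) {
  H <- nrow(img); W <- ncol(img)
  out <- rep(fill, length(x))
  ok <- !is.na(x) & !is.na(y) & x >= 1 & x <= W & y >= 1 & y <= H
  if (!any(ok)) return(out)
  xs <- x[ok]; ys <- y[ok]
  x0 <- pmin(floor(xs), W - 1L); y0 <- pmin(floor(ys), H - 1L)
  fx <- xs - x0; fy <- ys - y0
  i00 <- img[cbind(y0, x0)]
  i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]
  i11 <- img[cbind(y0 + 1, x0 + 1)]
  out[ok] <- (1 - fy) * ((1 - fx) * i00 + fx * i01) +
    fy * ((1 - fx) * i10 + fx * i11)
  out
}

# Backward warp: out[y, x] = img(map_x[y, x], map_y[y, x]).
warp_image <- function(img, map_x, map_y, fill = NA_real_) {
  matrix(bilinear_sample(img, as.vector(map_x), as.vector(map_y), fill = fill),
         nrow(map_x), ncol(map_x))
}

# Central-difference gradients; one-sided at the borders.
image_gradients <- function(img) {
  H <- nrow(img); W <- ncol(img)
  gx <- img; gy <- img
  gx[, 2:(W - 1)] <- (img[, 3:W] - img[, 1:(W - 2)]) / 2
  gx[, 1] <- img[, 2] - img[, 1]
  gx[, W] <- img[, W] - img[, W - 1]
  gy[2:(H - 1), ] <- (img[3:H, ] - img[1:(H - 2), ]) / 2
  gy[1, ] <- img[2, ] - img[1, ]
  gy[H, ] <- img[H, ] - img[H - 1, ]
  list(gx = gx, gy = gy)
}

gauss_blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  # gblur's `radius` is the full (odd) brush size; keep it inside the image
  sz <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  mx <- min(dim(img))
  mx_odd <- if (mx %% 2L == 1L) mx else mx - 1L
  sz <- min(sz, mx_odd)
  if (sz < 3L) return(img)
  EBImage::gblur(img, sigma = sigma, radius = sz)
}

# Replicate-pad an n-d array by `pad` voxels along every axis.
pad_replicate <- function(arr, pad) {
  d <- dim(arr)
  idx <- lapply(seq_along(d), function(k) {
    p <- pad[min(k, length(pad))]
    pmin(pmax(seq_len(d[k] + 2 * p) - p, 1L), d[k])
  })
  do.call(`[`, c(list(arr), idx))
}

crop_pad <- function(arr, pad) {
  d <- dim(arr)
  idx <- lapply(seq_along(d), function(k) {
    p <- pad[min(k, length(pad))]
    (p + 1L):(d[k] - p)
  })
  do.call(`[`, c(list(arr), idx))
}

# Circular FFT convolution of an n-d array with a (small, centered) kernel.
fft_convolve <- function(arr, kernel) {
  d <- dim(arr); kd <- dim(kernel)
  stopifnot(length(d) == length(kd), all(kd <= d))
  kfull <- array(0, d)
  src <- as.matrix(expand.grid(lapply(kd, seq_len)))
  ctr <- (kd + 1L) %/% 2L
  dest <- src
  for (k in seq_along(d)) dest[, k] <- ((src[, k] - ctr[k]) %% d[k]) + 1L
  kfull[dest] <- kernel[src]
  out <- Re(fft(fft(arr) * fft(kfull), inverse = TRUE)) / prod(d)
  array(out, d)
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 3D Gaussian kernel, voxel units, sigma = c(z, y, x).
gaussian_kernel_3d <- function(sigma) {
  kz <- gaussian_kernel_1d(max(sigma[1], 1e-6))
  ky <- gaussian_kernel_1d(max(sigma[2], 1e-6))
  kx <- gaussian_kernel_1d(max(sigma[3], 1e-6))
  k <- outer(outer(kz, ky), kx)
  k / sum(k)
}

gauss_blur3d <- function(vol, sigma) {
  k <- gaussian_kernel_3d(sigma)
  pad <- (dim(k) + 1L) %/% 2L
  crop_pad(fft_convolve(pad_replicate(vol, pad), k), pad)
}

# Fill NA entries of a matrix with the mean of defined neighbours, iterating
# until no NA remains (nearest-neighbour diffusion fill).
fill_nearest <- function(m, max_iter = 1000L) {
  for (i in seq_len(max_iter)) {
    nas <- is.na(m)
    if (!any(nas)) return(m)
    H <- nrow(m); W <- ncol(m)
    acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
    shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    for (s in shifts) {
      sh <- matrix(NA_real_, H, W)
      ys <- seq_len(H) - s[1]; xs <- seq_len(W) - s[2]
      oky <- ys >= 1 & ys <= H; okx <- xs >= 1 & xs <= W
      sh[oky, okx] <- m[ys[oky], xs[okx]]
      has <- !is.na(sh)
      acc[has] <- acc[has] + sh[has]
      cnt <- cnt + has
    }
    fillable <- nas & cnt > 0
    m[fillable] <- acc[fillable] / cnt[fillable]
  }
  if (anyNA(m)) stop("fill_nearest did not converge")
  m
}

# Median filter with a k x k window that ignores NA; returns NA where the
# whole window is undefined.
median_filter_na <- function(m, k = 3L) {
  H <- nrow(m); W <- ncol(m); r <- k %/% 2L
  out <- matrix(NA_real_, H, W)
  for (y in seq_len(H)) {
    y0 <- max(1L, y - r); y1 <- min(H, y + r)
    for (x in seq_len(W)) {
      w <- m[y0:y1, max(1L, x - r):min(W, x + r)]
      w <- w[!is.na(w)]
      if (length(w)) out[y, x] <- median(w)
    }
  }
  out
}

# Rasterize a polygon (list/matrix of x,y vertices) onto an H x W pixel grid.
polygon_mask <- function(polygon, H, W) {
  poly <- as.matrix(polygon)
  gx <- rep(seq_len(W), each = H)
  gy <- rep(seq_len(H), W)
  inside <- pracma::inpolygon(gx, gy, poly[, 1], poly[, 2], boundary = TRUE)
  matrix(inside, H, W)
}

otsu_threshold <- function(img) {
  rng <- range(img, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1])
  EBImage::otsu(EBImage::Image((t(img) - rng[1]) / diff(rng)),
                range = c(0, 1)) * diff(rng) + rng[1]
}

# Theil-Sen slope/intercept with R^2 of the robust line.
theil_sen <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_, n = n))
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- dx != 0
  slope <- median(dy[keep] / dx[keep])
  intercept <- median(y - slope * x)
  fit <- intercept + slope * x
  ss_res <- sum((y - fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(slope = slope, intercept = intercept, r2 = r2, n = n)
}
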