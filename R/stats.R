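#' PCA over per-larva speed trajectories
#'
#' Treats each length-`m` speed-over-time trace as a point in `m`-dimensional
#' space, subtracts the ensemble-mean trajectory, and performs covariance
#' PCA (no per-dimension scaling). Component signs follow a deterministic
#' convention: the loading of largest magnitude on each component is made
#' positive, so scores are comparable across runs.
#'
#' @param trajectories numeric matrix (one row per larva, one column per
#'   frame) or a list of equal-length numeric vectors.
#' @return object of class `PcaResult` with `mean_trajectory`, `components`
#'   (columns, orthonormal), `explained_variance_fraction`, `scores`, `sdev`.
#' @export
pca_trajectories <- function(trajectories) {
  X <- if (is.list(trajectories)) do.call(rbind, trajectories)
    else as.matrix(trajectories)
  if (nrow(X) < 2) stop("need at least 2 trajectories")
  if (anyNA(X) || !all(is.finite(X))) stop("trajectories must be finite")
  mu <- colMeans(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  scores <- pc$x
  for (k in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  v <- pc$sdev^2
  frac <- if (sum(v) > 0) v / sum(v) else rep(0, length(v))
  structure(list(mean_trajectory = mu, components = rot,
                 explained_variance_fraction = frac,
                 scores = scores, sdev = pc$sdev),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("Trajectory PCA:", nrow(x$scores), "trajectories,",
      ncol(x$components), "components\n")
  ev <- round(100 * x$explained_variance_fraction[1:min(3, length(x$explained_variance_fraction))], 1)
  cat("  explained variance (%):", paste(ev, collapse = ", "), "...\n")
  invisible(x)
}

.group_list <- function(groups, values = NULL, labels = NULL) {
  if (is.data.frame(groups)) {
    stopifnot(!is.null(values), !is.null(labels))
    groups <- split(groups[[values]], groups[[labels]])
  }
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) as.numeric(g[is.finite(g)]))
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs n >= 2")
  groups
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F statistic with Welch-Satterthwaite denominator degrees of
#' freedom, appropriate when group variances are unequal.
#'
#' @param groups named list of numeric vectors (each n >= 2), or a
#'   data.frame together with `values`/`labels` column names.
#' @param values,labels column names when `groups` is a data.frame.
#' @return object of class `GroupComparison` with the omnibus statistics.
#' @export
welch_anova <- function(groups, values = NULL, labels = NULL) {
  g <- .group_list(groups, values, labels)
  k <- length(g)
  n <- vapply(g, length, 1)
  m <- vapply(g, mean, 1)
  v <- vapply(g, var, 1)
  if (any(v == 0) && all(v == 0))
    stop("all groups have zero variance; Welch's ANOVA undefined")
  w <- n / v
  W <- sum(w)
  mw <- sum(w * m) / W
  A <- sum(w * (m - mw)^2) / (k - 1)
  B <- sum((1 - w / W)^2 / (n - 1))
  f <- A / (1 + 2 * (k - 2) / (k^2 - 1) * B)
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * B)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  structure(list(labels = names(g) %||% as.character(seq_len(k)),
                 n = n, means = m, variances = v,
                 F = f, df1 = df1, df2 = df2, p = p),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("Welch's ANOVA: F(%g, %.1f) = %.4g, p = %.3g (%d groups)\n",
              x$df1, x$df2, x$F, x$p, length(x$n)))
  if (!is.null(x$pairwise)) {
    cat("Games-Howell pairwise comparisons:\n")
    print(x$pairwise, digits = 3)
  }
  invisible(x)
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' Pairwise comparisons for unequal variances and sample sizes: each pair is
#' tested with a Welch-type statistic referred to the studentized range
#' distribution with Welch degrees of freedom. Cohen's d for each pair uses
#' the average-variance definition (see [cohens_d_independent()]).
#'
#' @inheritParams welch_anova
#' @return a `GroupComparison` whose `pairwise` data.frame covers all
#'   unordered pairs (columns: `group1`, `group2`, `diff`, `t`, `df`, `p`,
#'   `cohens_d`); p-values are capped at 1.
#' @export
games_howell <- function(groups, values = NULL, labels = NULL) {
  res <- welch_anova(groups, values, labels)
  g <- .group_list(groups, values, labels)
  k <- length(g)
  n <- res$n; m <- res$means; v <- res$variances
  pairs <- utils::combn(k, 2)
  tab <- data.frame(group1 = res$labels[pairs[1, ]],
                    group2 = res$labels[pairs[2, ]],
                    diff = NA_real_, t = NA_real_, df = NA_real_,
                    p = NA_real_, cohens_d = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se2 <- v[i1] / n[i1] + v[i2] / n[i2]
    tt <- (m[i1] - m[i2]) / sqrt(se2)
    df <- se2^2 / ((v[i1] / n[i1])^2 / (n[i1] - 1) +
                     (v[i2] / n[i2])^2 / (n[i2] - 1))
    p <- ptukey(abs(tt) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    tab$diff[j] <- m[i1] - m[i2]
    tab$t[j] <- tt
    tab$df[j] <- df
    tab$p[j] <- min(p, 1)
    tab$cohens_d[j] <- cohens_d_independent(g[[i1]], g[[i2]])
  }
  res$pairwise <- tab
  res
}

#' Cohen's d for independent samples (average-variance definition)
#'
#' `d = (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)` with sample
#' (n - 1) variances.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @return Cohen's d.
#' @export
cohens_d_independent <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) stop("both variances zero: d undefined")
  (mean(a) - mean(b)) / sqrt((va + vb) / 2)
}

#' Paired two-tailed t-test with paired Cohen's d
#'
#' Two-tailed t-test on per-subject paired differences, and the paired
#' effect size `d = mean(diff) / sd(diff)`.
#'
#' @param before,after paired numeric vectors (one average per larva).
#' @return list with `t`, `df`, `p`, `d_paired`, `mean_difference`.
#' @export
paired_ttest_d <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 2)
  d <- after - before
  sdd <- sd(d)
  if (sdd == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1, p = 1,
                                 d_paired = 0, mean_difference = 0))
    stop("zero-variance nonzero differences: d undefined")
  }
  n <- length(d)
  tt <- mean(d) / (sdd / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1),
       d_paired = mean(d) / sdd, mean_difference = mean(d))
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param x numeric vector (n >= 2).
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed (reproducible; `NULL` uses the current RNG
#'   state).
#' @return numeric `c(lo, hi)`; the bootstrap mean distribution is attached
#'   as attribute `"boot"`.
#' @export
bootstrap_ci_mean <- function(x, n_boot = 10000, level = 0.95, seed = NULL) {
  stopifnot(length(x) >= 2)
  run <- function() {
    idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                  nrow = n_boot)
    rowMeans(matrix(x[idx], nrow = n_boot))
  }
  boots <- if (is.null(seed)) run() else with_seed(seed, run())
  a <- (1 - level) / 2
  ci <- unname(quantile(boots, c(a, 1 - a), type = 7))
  attr(ci, "boot") <- boots
  ci
}

#' Paired estimation-plot summary
#'
#' Mean paired difference with its bootstrap resampling distribution, a
#' percentile confidence interval, and a kernel-density summary of the
#' bootstrap distribution suitable for an estimation plot.
#'
#' @inheritParams paired_ttest_d
#' @param n_boot bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return object of class `PairedEstimation` with `mean_difference`, `ci`,
#'   `bootstrap`, and `density` (a [stats::density()] object, or `NULL` when
#'   the bootstrap distribution is degenerate).
#' @export
paired_estimation_summary <- function(before, after, n_boot = 10000,
                                      level = 0.95, seed = NULL) {
  stopifnot(length(before) == length(after), length(before) >= 2)
  diffs <- after - before
  ci <- bootstrap_ci_mean(diffs, n_boot = n_boot, level = level, seed = seed)
  boots <- attr(ci, "boot")
  degenerate <- diff(range(boots)) <= 1e-12 * max(1, abs(mean(boots)))
  dens <- if (!degenerate) density(boots) else NULL
  structure(list(mean_difference = mean(diffs), ci = as.numeric(ci),
                 bootstrap = boots, density = dens, level = level),
            class = "PairedEstimation")
}

#' @export
print.PairedEstimation <- function(x, ...) {
  cat(sprintf("Paired mean difference %.4g [%g%% CI %.4g, %.4g]\n",
              x$mean_difference, 100 * x$level, x$ci[1], x$ci[2]))
  invisible(x)
}
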