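test_that("trajectory PCA: rank-1 detection, completeness, sign convention", {
  base <- sin(seq(0, pi, length.out = 30))
  X <- rbind(base, -base) + 1    # two mirror-image trajectories
  p <- pca_trajectories(X)
  expect_equal(p$explained_variance_fraction[1], 1)
  expect_lt(sum(p$explained_variance_fraction[-1]), 1e-12)
  # components orthonormal, scores centred
  set.seed(71)
  Y <- matrix(rnorm(12 * 30), 12, 30)
  py <- pca_trajectories(Y)
  G <- crossprod(py$components)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_lt(max(abs(colMeans(py$scores))), 1e-8)
  expect_true(all(py$explained_variance_fraction >= 0))
  expect_equal(sum(py$explained_variance_fraction), 1, tolerance = 1e-12)
  # full reconstruction
  rec <- py$scores %*% t(py$components) +
    matrix(py$mean_trajectory, 12, 30, byrow = TRUE)
  expect_equal(rec, Y, tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: largest-magnitude loading is positive
  expect_true(all(apply(py$components, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("PC1 scores track the generated response amplitude", {
  set.seed(72)
  base <- exp(-((1:30) - 10)^2 / 30)
  amp <- runif(40, 0.5, 3)
  X <- outer(amp, base) + matrix(rnorm(40 * 30, sd = 0.05), 40, 30)
  p <- pca_trajectories(X)
  expect_gt(abs(cor(p$scores[, 1], amp)), 0.95)
  expect_gt(p$explained_variance_fraction[1], 0.8)
})

test_that("Welch's ANOVA matches oneway.test and the two-group t identity", {
  g <- list(a = c(12.1, 14.3, 13.8, 12.9, 15.2),
            b = c(18.5, 21.2, 19.9, 23.1),
            c = c(11.2, 10.8, 12.5, 11.9, 10.1, 12.2))
  res <- welch_anova(g)
  ref <- oneway.test(vals ~ grp, data = data.frame(
    vals = unlist(g), grp = rep(names(g), lengths(g))), var.equal = FALSE)
  expect_equal(res$F, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$df2, unname(ref$parameter[2]), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  # two groups: F equals the square of Welch's t
  res2 <- welch_anova(g[1:2])
  tt <- t.test(g$a, g$b)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)
  expect_error(welch_anova(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("Games-Howell covers all pairs with sensible p-values", {
  set.seed(73)
  # 7 conditions: all 21 unordered pairs reported
  g7 <- lapply(1:7, function(i) rnorm(6, mean = i * 3, sd = i / 2))
  names(g7) <- paste0("cond", 1:7)
  gh <- games_howell(g7)
  expect_equal(nrow(gh$pairwise), 21)
  expect_true(all(gh$pairwise$p >= 0 & gh$pairwise$p <= 1))
  # two identical groups: p ~ 1
  gid <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  expect_gt(games_howell(gid)$pairwise$p[1], 0.99)
  # well-separated groups (10 sigma): all pairwise p < 1e-4
  gsep <- list(a = rnorm(8, 0, 1), b = rnorm(8, 10, 1), c = rnorm(8, 20, 1))
  expect_true(all(games_howell(gsep)$pairwise$p < 1e-4))
})

test_that("Cohen's d uses the average-variance definition", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  expect_equal(cohens_d_independent(a, b), 0)
  # means 2 vs 0, both variances 1 -> d = 2
  x <- c(1, 2, 3); y <- c(-1, 0, 1)
  expect_equal(cohens_d_independent(x, y), 2)
  expect_equal(cohens_d_independent(y, x), -2)      # antisymmetry
  expect_error(cohens_d_independent(c(1, 1), c(2, 2)), "zero")
})

test_that("paired t-test and paired d behave on constructed and simulated data", {
  b <- c(1.2, 3.1, 2.2, 4.0)
  r0 <- paired_ttest_d(b, b)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1); expect_equal(r0$d_paired, 0)
  # diffs {0, 2}: mean 1, sd sqrt(2), d = 0.707
  r1 <- paired_ttest_d(c(5, 5), c(5, 7))
  expect_equal(r1$d_paired, 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(r1$mean_difference, 1)
  # agreement with t.test on arbitrary data
  set.seed(74)
  x <- rnorm(15); y <- x + rnorm(15, 0.5)
  r2 <- paired_ttest_d(x, y)
  ref <- t.test(y, x, paired = TRUE)
  expect_equal(r2$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-10)
  # recovery simulation: delta = 1, sd = 1, n = 20 -> mean d-hat ~ 1
  set.seed(75)
  dhat <- replicate(2000, {
    before <- rnorm(20)
    paired_ttest_d(before, before + rnorm(20, mean = 1))$d_paired
  })
  expect_equal(mean(dhat), 1, tolerance = 0.05)
})

test_that("bootstrap CIs are seeded, degenerate-safe and sensible", {
  ci_const <- bootstrap_ci_mean(rep(3.5, 10), n_boot = 200, seed = 1)
  expect_equal(as.numeric(ci_const), c(3.5, 3.5))
  set.seed(76)
  x <- rnorm(40, 5)
  ci1 <- bootstrap_ci_mean(x, n_boot = 2000, seed = 9)
  ci2 <- bootstrap_ci_mean(x, n_boot = 2000, seed = 9)
  expect_identical(as.numeric(ci1), as.numeric(ci2))
  expect_lt(ci1[1], mean(x)); expect_gt(ci1[2], mean(x))
})

test_that("paired estimation summaries expose difference, CI and density", {
  b <- c(1, 2, 3, 4, 5, 6)
  s0 <- paired_estimation_summary(b, b, n_boot = 500, seed = 2)
  expect_equal(s0$mean_difference, 0)
  expect_null(s0$density)
  s1 <- paired_estimation_summary(b, b + 0.4, n_boot = 2000, seed = 3)
  expect_equal(s1$mean_difference, 0.4, tolerance = 1e-12)
  expect_gt(s1$ci[1], 0)                     # CI excludes 0 for an exact shift
  # with noisy pairs the bootstrap density integrates to ~1
  set.seed(77)
  s2 <- paired_estimation_summary(rnorm(20), rnorm(20, 0.5),
                                  n_boot = 2000, seed = 4)
  d <- s2$density
  area <- sum(d$y) * diff(d$x[1:2])
  expect_equal(area, 1, tolerance = 1e-3)
})
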