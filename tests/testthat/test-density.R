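test_that("density grids integrate to one, even for degenerate point masses", {
  pts <- matrix(rep(c(0.5, 0.5, 0.5), each = 1000), ncol = 3) # all identical
  dg <- estimate_density(pts, bandwidth = 0.02, grid_shape = 20,
                         extents = rbind(c(0, 1), c(0, 1), c(0, 1)))
  expect_equal(sum(dg$values) * dg$voxel, 1, tolerance = 1e-6)
  # mass concentrated in the cells around the point (0.5 sits on a cell edge)
  peak <- which(dg$values == max(dg$values), arr.ind = TRUE)[1, ]
  expect_lt(abs(dg$axes[[1]][peak[1]] - 0.5), 0.05)
  near <- abs(dg$axes[[1]] - 0.5) < 0.1
  expect_gt(sum(dg$values[near, near, near]) * dg$voxel, 0.95)
})

test_that("KDE approaches the analytic Gaussian density in L1", {
  set.seed(42)
  n <- 5000
  pts <- matrix(rnorm(3 * n, 0, 0.1), ncol = 3)
  dg <- estimate_density(pts, grid_shape = 30)
  # closed-form oracle: product normal pdf on the same cell centers. At
  # n = 5000 in 3D the error is dominated by Scott-bandwidth smoothing bias;
  # the oracle computation puts it at ~0.14, frozen here with headroom.
  g <- expand.grid(dg$axes[[1]], dg$axes[[2]], dg$axes[[3]])
  truth <- dnorm(g[[1]], 0, 0.1) * dnorm(g[[2]], 0, 0.1) * dnorm(g[[3]], 0, 0.1)
  l1 <- sum(abs(as.vector(dg$values) - truth)) * dg$voxel
  expect_lt(l1, 0.16)
  # the estimate is closer to the kernel-smoothed target than to any
  # comparably mis-scaled density: same-shape sanity on the oracle grid
  smoothed <- dnorm(g[[1]], 0, sqrt(0.01 + dg$bandwidth[1]^2)) *
    dnorm(g[[2]], 0, sqrt(0.01 + dg$bandwidth[2]^2)) *
    dnorm(g[[3]], 0, sqrt(0.01 + dg$bandwidth[3]^2))
  l1_smoothed <- sum(abs(as.vector(dg$values) - smoothed)) * dg$voxel
  expect_lt(l1_smoothed, l1)
})

test_that("doubling grid resolution barely moves the overlap coefficient", {
  set.seed(7)
  n <- 2000
  a <- matrix(rnorm(3 * n, 0, 0.1), ncol = 3)
  b <- matrix(rnorm(3 * n, 0, 0.1), ncol = 3); b[, 1] <- b[, 1] + 0.1
  ext <- rbind(range(c(a[, 1], b[, 1])) + c(-0.1, 0.1),
               range(c(a[, 2], b[, 2])) + c(-0.1, 0.1),
               range(c(a[, 3], b[, 3])) + c(-0.1, 0.1))
  bc_at <- function(gs) {
    bhattacharyya_coefficient(estimate_density(a, grid_shape = gs, extents = ext),
                              estimate_density(b, grid_shape = gs, extents = ext))
  }
  expect_lt(abs(bc_at(25) - bc_at(50)), 0.01)
})

test_that("overlap identities: identical densities 1, disjoint supports 0", {
  set.seed(1)
  pts <- matrix(runif(300), ncol = 3)
  p <- estimate_density(pts, bandwidth = 0.05, grid_shape = 16)
  expect_equal(bhattacharyya_coefficient(p, p), 1, tolerance = 1e-6)

  ext <- rbind(c(-1, 11), c(-1, 2), c(-1, 2))
  a <- matrix(runif(300), ncol = 3)
  b <- a; b[, 1] <- b[, 1] + 10
  pa <- estimate_density(a, bandwidth = 0.05, grid_shape = 24, extents = ext)
  pb <- estimate_density(b, bandwidth = 0.05, grid_shape = 24, extents = ext)
  expect_lt(bhattacharyya_coefficient(pa, pb), 1e-6)

  q <- estimate_density(pts, bandwidth = 0.05, grid_shape = 18)
  expect_error(bhattacharyya_coefficient(p, q), "mismatch")
})

test_that("density estimation rejects unusable inputs", {
  expect_error(estimate_density(matrix(1:3, 1, 3)), "at least 2")
  expect_error(estimate_density(matrix(1:6, 2, 3), bandwidth = 0), "bandwidth")
  pts <- matrix(rep(1, 30), ncol = 3)
  expect_error(estimate_density(pts, bandwidth = "scott"), "zero-variance")
})

test_that("bootstrap overlap honours its identity and separation limits", {
  set.seed(5)
  pts <- matrix(rnorm(500 * 3), ncol = 3)
  # identity limit: adequately smooth bandwidth so independent resamples of
  # the same point set estimate the same density
  ov <- bootstrap_overlap(pts, pts, n_boot = 40, seed = 2, grid_shape = 24,
                          bandwidth = 0.8)
  expect_equal(ov$bc_point, 1, tolerance = 1e-9)  # same sample both roles
  expect_gte(ov$bootstrap_median, 0.99)
  expect_gte(ov$ci_low, 0.95)

  far <- pts; far[, 1] <- far[, 1] + 50
  ov2 <- bootstrap_overlap(pts, far, n_boot = 20, seed = 2, grid_shape = 24)
  expect_lte(ov2$bootstrap_median, 0.02)
  expect_true(ov2$ci_low <= ov2$bootstrap_median &
                ov2$bootstrap_median <= ov2$ci_high)
})

test_that("bootstrap overlap is bit-identical under a fixed seed", {
  set.seed(3)
  a <- matrix(rnorm(240), ncol = 3)
  b <- matrix(rnorm(240, 0.3), ncol = 3)
  o1 <- bootstrap_overlap(a, b, n_boot = 25, seed = 99, grid_shape = 16)
  o2 <- bootstrap_overlap(a, b, n_boot = 25, seed = 99, grid_shape = 16)
  expect_identical(o1, o2)
  expect_error(bootstrap_overlap(a, b, n_boot = 0), "n_boot")
  expect_error(bootstrap_overlap(a[1, , drop = FALSE], b), "at least 2")
})
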