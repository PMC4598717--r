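make_maps <- function(n, dims = c(8, 8, 8), mu = 0, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) array(rnorm(prod(dims), mu), dims))
  })
}

test_that("voxelwise t-tests match stats::t.test at single voxels", {
  a <- make_maps(8, seed = 1); b <- make_maps(8, mu = 0.5, seed = 2)
  tm <- voxelwise_test(a, b, "independent")
  v <- c(3, 4, 5)
  av <- vapply(a, function(m) m[v[1], v[2], v[3]], numeric(1))
  bv <- vapply(b, function(m) m[v[1], v[2], v[3]], numeric(1))
  ref <- t.test(av, bv, var.equal = TRUE)
  expect_equal(tm$values[v[1], v[2], v[3]], unname(ref$statistic),
               tolerance = 1e-10)
  expect_equal(tm$df, 14)

  pt <- voxelwise_test(a, b, "paired")
  refp <- t.test(av, bv, paired = TRUE)
  expect_equal(pt$values[v[1], v[2], v[3]], unname(refp$statistic),
               tolerance = 1e-10)
  expect_equal(pt$df, 7)
})

test_that("group-label swap negates the t map; identical groups give zero", {
  a <- make_maps(6, seed = 3); b <- make_maps(6, seed = 4)
  t1 <- voxelwise_test(a, b, "independent")
  t2 <- voxelwise_test(b, a, "independent")
  expect_equal(t1$values, -t2$values, tolerance = 1e-10)
  tp <- voxelwise_test(a, a, "paired")
  expect_true(all(tp$values[!is.na(tp$values)] == 0 |
                    is.na(tp$values)))
})

test_that("covariate control works and collinearity errors", {
  a <- make_maps(10, seed = 5); b <- make_maps(10, seed = 6)
  cov_ok <- withr::with_seed(7, rnorm(20))
  tm <- voxelwise_test(a, b, "independent", covariate = cov_ok)
  expect_equal(tm$df, 17) # n - 3
  # single-voxel agreement with lm()
  v <- c(2, 2, 2)
  av <- vapply(a, function(m) m[v[1], v[2], v[3]], numeric(1))
  bv <- vapply(b, function(m) m[v[1], v[2], v[3]], numeric(1))
  y <- c(av, bv); g <- rep(c(1, 0), each = 10)
  ref <- summary(lm(y ~ g + I(cov_ok - mean(cov_ok))))$coefficients["g", "t value"]
  expect_equal(tm$values[v[1], v[2], v[3]], ref, tolerance = 1e-10)
  group_copy <- rep(c(1, 0), each = 10)
  expect_error(voxelwise_test(a, b, "independent", covariate = group_copy),
               "collinear")
})

test_that("null maps exceed the height threshold at the nominal rate", {
  withr::with_seed(11, {
    rates <- vapply(1:30, function(i) {
      a <- lapply(1:15, function(j) array(rnorm(512), c(8, 8, 8)))
      b <- lapply(1:15, function(j) array(rnorm(512), c(8, 8, 8)))
      tm <- voxelwise_test(a, b, "independent")
      mean(abs(tm$values) > qt(0.995, tm$df))
    }, numeric(1))
  })
  expect_lt(abs(mean(rates) - 0.01), 0.004)
})

test_that("smoothness estimation recovers white and smoothed noise", {
  mask <- brain_mask(c(16, 16, 16))
  white <- withr::with_seed(1, lapply(1:6, function(i) {
    array(rnorm(16^3), c(16, 16, 16))
  }))
  fw <- estimate_smoothness(white, mask, 2)
  expect_true(all(fw < 3.2)) # near the 2 mm voxel floor
  # larger grid for the smoothed case: kernel edge renormalisation
  # inflates apparent smoothness on very small masks
  mask20 <- brain_mask(c(20, 20, 20))
  smooth6 <- withr::with_seed(2, lapply(1:6, function(i) {
    gaussian_smooth_3d(array(rnorm(20^3), c(20, 20, 20)), 6, 2)
  }))
  fw6 <- estimate_smoothness(smooth6, mask20, 2)
  expect_true(all(abs(fw6 - 6) / 6 < 0.15))
  expect_error(estimate_smoothness(white, array(TRUE, c(3, 3, 3)), 2),
               "too small")
  const <- lapply(1:3, function(i) array(1, c(16, 16, 16)))
  expect_error(estimate_smoothness(const, mask, 2), "zero variance")
})

test_that("monte-carlo extent threshold matches a brute-force oracle at fwhm 0", {
  # independent oracle: direct simulation with its own thresholding and a
  # hand-rolled single-linkage component search
  dims <- c(10, 10, 10)
  mask <- array(TRUE, dims)
  thr <- cluster_extent_threshold(mask, fwhm_mm = 0, height_p = 0.01,
                                  alpha = 0.05, n_sim = 2000, seed = 42,
                                  voxel_mm = 2, connectivity = 26)
  oracle_max <- withr::with_seed(99, vapply(1:2000, function(i) {
    z <- array(rnorm(prod(dims)), dims)
    z <- (z - mean(z)) / sd(z)
    supra <- which(abs(z) > qnorm(0.995), arr.ind = TRUE)
    if (nrow(supra) == 0) return(0L)
    sign_z <- sign(z)[abs(z) > qnorm(0.995)]
    # single-linkage: same sign + chebyshev distance 1
    n <- nrow(supra); parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && sign_z[i] == sign_z[j] &&
          max(abs(supra[i, ] - supra[j, ])) <= 1) {
        parent[find(i)] <- find(j)
      }
    }
    max(tabulate(vapply(seq_len(n), find, integer(1))))
  }, numeric(1)))
  k_grid <- seq_len(max(oracle_max) + 1)
  k_oracle <- k_grid[which(vapply(k_grid, function(k) mean(oracle_max >= k),
                                  numeric(1)) <= 0.05)[1]]
  expect_lte(abs(thr$k_min - k_oracle), 1)
})

test_that("extent threshold is monotone in smoothness and trivial at alpha 1", {
  mask <- brain_mask(c(12, 12, 12))
  t0 <- cluster_extent_threshold(mask, 0, 0.01, 0.05, 1000, seed = 1)
  t6 <- cluster_extent_threshold(mask, 6, 0.01, 0.05, 1000, seed = 1)
  expect_gte(t6$k_min, t0$k_min)
  t_all <- cluster_extent_threshold(mask, 0, 0.01, 1.0, 1000, seed = 1)
  expect_equal(t_all$k_min, 1L)
  expect_error(cluster_extent_threshold(mask, 0, 0.01, 1e-5, 1000, seed = 1),
               "unreachable")
  expect_error(cluster_extent_threshold(mask, 0, 0.01, 0.05, 500, seed = 1),
               "n_sim")
})

test_that("k_min is seed-reproducible and stable as n_sim grows", {
  mask <- brain_mask(c(12, 12, 12))
  a <- cluster_extent_threshold(mask, 4, 0.01, 0.05, 2000, seed = 7)
  b <- cluster_extent_threshold(mask, 4, 0.01, 0.05, 2000, seed = 7)
  expect_identical(a$max_sizes, b$max_sizes)
  big <- cluster_extent_threshold(mask, 4, 0.01, 0.05, 4000, seed = 8)
  expect_lte(abs(a$k_min - big$k_min), 2)
})

test_that("cluster extraction respects connectivity and extent", {
  dims <- c(10, 10, 10)
  tv <- array(0, dims)
  tv[2:7, 2:7, 2:7] <- 10 # 216-voxel blob
  tm <- stat_map(tv, "t", df = 28)
  cl <- extract_clusters(tm, height_p = 0.01, k_min = 128)
  expect_equal(nrow(cl), 1)
  expect_true(cl$survives_fwe)
  expect_equal(cl$size, 216)

  none <- extract_clusters(stat_map(array(0, dims), "t", df = 28),
                           height_p = 0.01, k_min = 10)
  expect_equal(nrow(none), 0)

  # two cubes sharing only a corner: one cluster at 26-connectivity,
  # two at 6-connectivity
  corner <- array(0, dims)
  corner[2:3, 2:3, 2:3] <- 8
  corner[4:5, 4:5, 4:5] <- 8
  cm <- stat_map(corner, "t", df = 28)
  expect_equal(nrow(extract_clusters(cm, height_p = 0.01, k_min = 1,
                                     connectivity = 26)), 1)
  expect_equal(nrow(extract_clusters(cm, height_p = 0.01, k_min = 1,
                                     connectivity = 6)), 2)
})

test_that("bayesian group estimation flags clear differences and centred nulls", {
  withr::with_seed(21, {
    a <- rnorm(15, 3); b <- rnorm(15, 0)
  })
  post <- bayes_group_diff(a, b, seed = 1, n_adapt = 300, n_burn = 300,
                           n_iter = 800)
  expect_gt(post$hdi_lower, 0) # HDI excludes 0
  expect_equal(post$mean_diff, 3, tolerance = 0.8)
  expect_true(post$converged)

  same <- bayes_group_diff(a, a, seed = 2, n_adapt = 300, n_burn = 300,
                           n_iter = 800)
  expect_lt(abs(same$mean_diff), 0.5)
  expect_lt(same$hdi_lower, 0)
  expect_gt(same$hdi_upper, 0)
  expect_error(bayes_group_diff(rep(1, 5), rep(1, 5)), "zero variance")
  expect_error(bayes_group_diff(1:2, 1:5), ">= 3")
  gl <- glance(post)
  expect_true(all(c("mean_diff", "hdi_lower", "hdi_upper", "ess") %in%
                    names(gl)))
})
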