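test_that("z_transform matches its closed form and affine invariance", {
  m <- array(0, c(3, 3, 3)); mask <- array(FALSE, c(3, 3, 3))
  m[1:3] <- c(1, 2, 3); mask[1:3] <- TRUE
  z <- z_transform(m, mask)
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)

  withr::with_seed(1, big <- array(rnorm(27), c(3, 3, 3)))
  full <- array(TRUE, c(3, 3, 3))
  expect_equal(z_transform(big, full), z_transform(2.5 * big + 7, full),
               tolerance = 1e-12)
  expect_error(z_transform(array(1, c(3, 3, 3)), full), "constant")
  expect_error(z_transform(big, array(TRUE, c(2, 2, 2))), "dimensions")
})

test_that("LOOCV separates well-separated clusters and matches libSVM", {
  skip_if_not_installed("e1071")
  sp <- separated_features(n_per = 15, sep = 10, seed = 1)
  res <- loocv_classify(sp$X, sp$labels)
  expect_equal(res$accuracy, 1.0)
  # brute-force nearest-centroid oracle agrees at this separation
  nc <- vapply(seq_len(30), function(h) {
    mu1 <- colMeans(sp$X[-h, , drop = FALSE][sp$labels[-h] == "MLD", ])
    mu2 <- colMeans(sp$X[-h, , drop = FALSE][sp$labels[-h] == "TD", ])
    pred <- if (sum((sp$X[h, ] - mu1)^2) < sum((sp$X[h, ] - mu2)^2))
      "MLD" else "TD"
    pred == sp$labels[h]
  }, logical(1))
  expect_equal(mean(nc), 1.0)

  # fold-level agreement with the reference libSVM implementation on
  # harder problems
  for (s in 1:5) {
    sp2 <- separated_features(n_per = 10, p = 12, sep = 1, seed = s)
    ours <- loocv_classify(sp2$X, sp2$labels)
    ref <- vapply(seq_len(20), function(h) {
      m <- e1071::svm(sp2$X[-h, ], factor(sp2$labels[-h]), kernel = "linear",
                      cost = 1, scale = FALSE)
      as.character(predict(m, sp2$X[h, , drop = FALSE]))
    }, character(1))
    expect_equal(ours$folds$predicted, ref)
  }
})

test_that("label-independent features classify at chance on average", {
  accs <- vapply(1:60, function(s) {
    withr::with_seed(s, {
      X <- matrix(rnorm(30 * 10), 30, 10)
      y <- rep(c("a", "b"), each = 15)
    })
    loocv_classify(X, y)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("duplicated subjects with both labels are indiscriminable", {
  # every pattern appears once per class, so no genuine signal exists;
  # LOOCV on such data shows the classic anti-learning artifact (the
  # held-out subject's twin carries the opposite label), so accuracy
  # falls at or below chance and the permutation test finds nothing
  withr::with_seed(9, X <- matrix(rnorm(10 * 6), 10, 6))
  X2 <- rbind(X, X)
  y2 <- c(rep("a", 10), rep("b", 10))
  res <- permutation_test(X2, y2, n_perm = 199, seed = 3)
  expect_lte(res$accuracy, 0.5)
  expect_gt(res$p, 0.05)
})

test_that("classifier input validation", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(loocv_classify(X, c("a", "a", "a", "b")), ">= 2")
  expect_error(loocv_classify(X, c("a", "b", "c", "a")), "binary")
  X[1, 1] <- NA
  expect_error(loocv_classify(X, c("a", "a", "b", "b")), "missing")
})

test_that("permutation p follows the add-one formula and is reproducible", {
  sp <- separated_features(n_per = 8, sep = 10, seed = 3)
  res <- permutation_test(sp$X, sp$labels, n_perm = 999, seed = 5)
  # observed accuracy 1.0 beats every null permutation
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$p, (1 + sum(res$null_accuracies >= 1)) / 1000)
  expect_lte(res$p, 5 / 1000)

  res2 <- permutation_test(sp$X, sp$labels, n_perm = 999, seed = 5)
  expect_identical(res$null_accuracies, res2$null_accuracies)
  res3 <- permutation_test(sp$X, sp$labels, n_perm = 999, seed = 6)
  expect_false(identical(res$null_accuracies, res3$null_accuracies))
  expect_error(permutation_test(sp$X, sp$labels, n_perm = 50), "100")
})

test_that("classification is invariant to per-subject global scaling after z-transform", {
  cfg <- tiny_config(seed = 4)
  coh <- generate_cohort(cfg)
  man <- coh$manifest[coh$manifest$session == "pre", ]
  mask <- coh$mask
  f1 <- feature_matrix(man$map, mask)
  scaled <- lapply(seq_along(man$map), function(i) {
    m <- man$map[[i]]
    m$values <- m$values * (1 + i / 10) + i
    m
  })
  f2 <- feature_matrix(scaled, mask)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("tidiers summarise classification results", {
  sp <- separated_features(n_per = 5, sep = 10, seed = 2)
  res <- permutation_test(sp$X, sp$labels, n_perm = 199, seed = 1)
  td <- tidy(res)
  expect_true(all(c("fold", "truth", "predicted", "correct") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$accuracy, res$accuracy)
  expect_equal(gl$n_perm, 199)
})
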