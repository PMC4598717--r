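test_that("default schedule has 12 trials per condition and increasing onsets", {
  ev <- generate_design(sim_config(), accuracy = 0.8, seed = 7)
  expect_equal(sum(ev$trial_type == "addition"), 12)
  expect_equal(sum(ev$trial_type == "control"), 12)
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(ev$duration == 9.5))
  # schedule fits the derived run length (300 s for the default design)
  expect_lte(max(ev$onset + ev$duration), 300)
})

test_that("degenerate and reproducible schedules behave as specified", {
  empty <- generate_design(sim_config(trials_per_condition_per_run = 0))
  expect_equal(nrow(empty), 0)

  a <- generate_design(sim_config(), 0.8, seed = 7)
  b <- generate_design(sim_config(), 0.8, seed = 7)
  expect_identical(a, b)

  expect_error(
    generate_design(sim_config(run_length_seconds = 360,
                               trials_per_condition_per_run = 20)),
    "overflow")
  expect_error(sim_config(run_length_seconds = 100), "overflow")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_per_group = 0), "positive")
  expect_error(sim_config(plasticity_gain_coupling = 1.5), "\\[0, 1\\]")
  bad_regions <- default_aberrant_regions_for_test(retention = 1.2)
  expect_error(sim_config(aberrant_regions = bad_regions), "\\[0, 1\\]")
  outside <- default_aberrant_regions_for_test(center = c(1, 1, 1))
  expect_error(sim_config(aberrant_regions = outside), "inside the grid")
})

test_that("same seed gives a bit-identical cohort", {
  cfg <- tiny_config(seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$manifest$accuracy, b$manifest$accuracy)
  expect_identical(lapply(a$manifest$map, function(m) m$values),
                   lapply(b$manifest$map, function(m) m$values))
})

test_that("cohort structure matches the two-group two-session design", {
  coh <- generate_cohort(sim_config(n_per_group = 15, seed = 2,
                                    grid_shape = c(12, 14, 12),
                                    aberrant_regions =
                                      default_aberrant_regions_for_test(),
                                    task_regions = tiny_config()$task_regions))
  expect_equal(nrow(coh$manifest), 60) # 2 groups x 15 x 2 sessions
  expect_equal(nrow(coh$ground_truth), 30)
  gt <- coh$ground_truth
  expect_true(all(gt$normalization >= 0))
  mld <- gt[gt$group == "MLD", ]
  td <- gt[gt$group == "TD", ]
  # MLD pre amplitudes exceed TD amplitudes in aberrant regions by construction
  expect_true(all(vapply(mld$amplitude_pre, min, numeric(1)) > 0))
  expect_true(all(vapply(td$amplitude_pre, max, numeric(1)) == 0))
  # post amplitudes are pre x retention
  for (i in seq_len(nrow(mld))) {
    expect_equal(mld$amplitude_post[[i]],
                 mld$amplitude_pre[[i]] * mld$retention[i])
  }
})

test_that("zero coupling leaves normalization and gain uncorrelated", {
  rs <- vapply(1:40, function(s) {
    gt <- plastimap:::sample_ground_truth(
      tiny_config(seed = s, plasticity_gain_coupling = 0,
                  n_per_group = 15))
    m <- gt[gt$group == "MLD", ]
    cor(m$normalization, m$gain_true)
  }, numeric(1))
  # sampling distribution of r at n = 15 under independence:
  # |r| < 0.35 for ~95% of draws (Fisher z SD = 1/sqrt(12))
  expect_gte(mean(abs(rs) < 0.35), 0.80)
  expect_lt(abs(mean(rs)), 0.12)
})

test_that("configured coupling shows up in the latent ground truth", {
  rs <- vapply(1:40, function(s) {
    gt <- plastimap:::sample_ground_truth(
      tiny_config(seed = 100 + s, plasticity_gain_coupling = 0.6,
                  n_per_group = 15))
    m <- gt[gt$group == "MLD", ]
    cor(m$normalization, m$gain_true)
  }, numeric(1))
  expect_gt(median(rs), 0.3)
})

test_that("map noise has the configured in-mask scale and smooth fields differ by seed", {
  cfg <- tiny_config(seed = 1)
  mask <- brain_mask(cfg$grid_shape)
  f1 <- withr::with_seed(1, plastimap:::smooth_noise_field(
    cfg$grid_shape, 6, 2, mask, sd = 2))
  f2 <- withr::with_seed(2, plastimap:::smooth_noise_field(
    cfg$grid_shape, 6, 2, mask, sd = 2))
  expect_equal(sd(f1[mask]), 2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1, f2)))
})

test_that("gaussian smoothing preserves constants and reduces roughness", {
  const <- array(3, c(10, 10, 10))
  expect_equal(gaussian_smooth_3d(const, 6, 2), const)
  withr::with_seed(5, x <- array(rnorm(1000), c(10, 10, 10)))
  sm <- gaussian_smooth_3d(x, 8, 2)
  expect_lt(sd(sm), sd(x))
  expect_identical(gaussian_smooth_3d(x, 0, 2), x)
})
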