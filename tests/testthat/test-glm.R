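test_that("canonical HRF peaks near 5-6 s with a late undershoot", {
  tt <- seq(0, 32, by = 0.1)
  h <- canonical_hrf(tt)
  expect_equal(max(h), 1)
  expect_gt(tt[which.max(h)], 4)
  expect_lt(tt[which.max(h)], 7)
  expect_lt(min(h[tt > 10 & tt < 25]), 0) # undershoot
  expect_equal(canonical_hrf(c(-1, 40)), c(0, 0))
})

test_that("design matrix has the expected structure for correct-only events", {
  ev <- tibble::tibble(
    onset = c(seq(5, 115, by = 10), seq(125, 235, by = 10)),
    duration = 9.5,
    trial_type = rep(c("addition", "control"), each = 12),
    correct = TRUE, rt = 1000)
  expect_warning(expect_warning(
    des <- build_design(ev, n_volumes = 150, tr = 2), "incorrect"),
    "incorrect")
  # 2 sub-conditions x (HRF + derivative) + drifts + intercept
  expect_equal(sum(grepl("correct$", des$names)), 2)
  expect_equal(sum(grepl("deriv$", des$names)), 2)
  expect_true("intercept" %in% des$names)
  expect_equal(des$rank, ncol(des$X))
  # single event at t = 0: response peaks in the 6-10 s window
  # (boxcar of 9.5 s convolved with an HRF peaking at ~5 s)
  one <- suppressWarnings(build_design(
    tibble::tibble(onset = 0, duration = 9.5, trial_type = "addition",
                   correct = TRUE, rt = 1000), 40, 2))
  hrf_col <- one$X[, one$condition_columns$addition_correct]
  t_peak <- (which.max(hrf_col) - 1) * 2
  expect_gte(t_peak, 6); expect_lte(t_peak, 10)
})

test_that("design matrix rejects events beyond the run and empty schedules fail at contrast", {
  ev <- tibble::tibble(onset = 295, duration = 9.5, trial_type = "addition",
                       correct = TRUE, rt = 1000)
  expect_error(build_design(ev, n_volumes = 150, tr = 2), "past the end")
  empty <- generate_design(sim_config(trials_per_condition_per_run = 0))
  des <- suppressWarnings(build_design(empty, n_volumes = 30, tr = 2))
  expect_equal(length(des$condition_columns), 0)
  dat <- array(rnorm(4 * 4 * 4 * 30), c(4, 4, 4, 30))
  fit <- fit_glm(dat, des)
  expect_error(contrast_map(fit), "unavailable")
})

test_that("noiseless simulation recovers the true amplitudes to 1e-6", {
  cfg <- tiny_config(seed = 2, bold_noise_sd = 0, motion_spike_rate = 0)
  ev <- generate_design(cfg, accuracy = 0.75, seed = 3)
  dims <- cfg$grid_shape
  amp_add <- array(0, dims); amp_con <- array(0, dims)
  amp_add[4:6, 4:6, 4:6] <- 2.0
  amp_con[4:6, 4:6, 4:6] <- 1.0
  run <- simulate_bold(ev, list(addition = amp_add, control = amp_con), cfg,
                       seed = 4)
  des <- suppressWarnings(
    build_design(ev, n_volumes = dim(run$data)[4], tr = cfg$tr_seconds))
  fit <- fit_glm(run, des)
  in_region <- array(FALSE, dims); in_region[4:6, 4:6, 4:6] <- TRUE
  idx <- which(in_region[run$mask])
  ac <- fit$betas[des$condition_columns$addition_correct, idx]
  cc <- fit$betas[des$condition_columns$control_correct, idx]
  expect_lt(max(abs(ac - 2.0)), 1e-6)
  expect_lt(max(abs(cc - 1.0)), 1e-6)
  # incorrect-trial columns (if present) carry the same amplitude
  if ("addition_incorrect" %in% names(des$condition_columns)) {
    ai <- fit$betas[des$condition_columns$addition_incorrect, idx]
    expect_lt(max(abs(ai - 2.0)), 1e-6)
  }
  cm <- contrast_map(fit)
  expect_lt(max(abs(cm$contrast$values[in_region & run$mask] - 1.0)), 1e-6)
})

test_that("duplicated design columns are reported as rank deficiency", {
  ev <- generate_design(tiny_config(), 0.9, seed = 1)
  des <- suppressWarnings(build_design(ev, 60, 2))
  des$X <- cbind(des$X, dup = des$X[, 1])
  des$names <- colnames(des$X)
  dat <- array(rnorm(4^3 * 60), c(4, 4, 4, 60))
  expect_error(fit_glm(dat, des), "rank deficient")
})

test_that("null-run t statistics follow the nominal Student-t exceedance", {
  cfg <- tiny_config(seed = 9, bold_noise_sd = 1, motion_spike_rate = 0,
                     smoothness_fwhm_mm = 0, ar1_rho = 0)
  ev <- generate_design(cfg, 0.8, seed = 10)
  zero <- array(0, cfg$grid_shape)
  run <- simulate_bold(ev, list(addition = zero, control = zero), cfg,
                       seed = 11)
  des <- suppressWarnings(
    build_design(ev, dim(run$data)[4], cfg$tr_seconds))
  fit <- fit_glm(run, des)
  cm <- contrast_map(fit)
  tv <- cm$t$values[run$mask]
  expect_lt(abs(mean(tv)), 0.05)
  exceed <- mean(abs(tv) > qt(0.995, fit$df))
  # ~768 voxels in the mask; binomial SE at p = 0.01 is ~0.4%
  expect_lt(abs(exceed - 0.01), 0.012)
})

test_that("trial order does not change the design and contrasts antisymmetrise", {
  ev <- generate_design(tiny_config(), 0.9, seed = 20)
  des1 <- suppressWarnings(build_design(ev, 60, 2))
  des2 <- suppressWarnings(build_design(ev[sample(nrow(ev)), ], 60, 2))
  expect_equal(des1$X, des2$X)

  cfg <- tiny_config(seed = 21, motion_spike_rate = 0)
  bumps <- plastimap:::precompute_bumps(cfg)
  amps <- plastimap:::amplitude_maps_for(cfg, 1.5, bumps)
  run <- simulate_bold(ev, amps, cfg, seed = 22)
  des <- suppressWarnings(build_design(ev, dim(run$data)[4], 2))
  fit <- fit_glm(run, des)
  fwd <- contrast_map(fit, c(addition_correct = 1, control_correct = -1))
  rev <- contrast_map(fit, c(addition_correct = -1, control_correct = 1))
  expect_equal(fwd$contrast$values, -rev$contrast$values)
  expect_equal(fwd$t$values, -rev$t$values)
})

test_that("run averaging combines contrasts by fixed effects and is identity for one run", {
  cfg <- tiny_config(seed = 30, motion_spike_rate = 0)
  ev1 <- generate_design(cfg, 0.9, seed = 31)
  ev2 <- generate_design(cfg, 0.9, seed = 32)
  bumps <- plastimap:::precompute_bumps(cfg)
  amps <- plastimap:::amplitude_maps_for(cfg, 1.5, bumps)
  runs <- list(simulate_bold(ev1, amps, cfg, seed = 33),
               simulate_bold(ev2, amps, cfg, seed = 34))
  cons <- lapply(1:2, function(r) {
    des <- suppressWarnings(build_design(
      list(ev1, ev2)[[r]], dim(runs[[r]]$data)[4], 2))
    contrast_map(fit_glm(runs[[r]], des))
  })
  avg <- average_runs(cons)
  expect_equal(avg$contrast$values,
               (cons[[1]]$contrast$values + cons[[2]]$contrast$values) / 2)
  expect_equal(avg$df, cons[[1]]$df + cons[[2]]$df)
  expect_identical(average_runs(cons[1]), cons[[1]])
  # t-averaging variant
  avg_t <- average_runs(cons, method = "t")
  expect_equal(avg_t$t$values,
               (cons[[1]]$t$values + cons[[2]]$t$values) / 2)
})
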