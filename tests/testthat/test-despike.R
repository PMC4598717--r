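test_that("displacement combines translations and rotations at 65 mm radius", {
  tr <- flat_motion(4)
  expect_equal(displacement(tr), rep(0, 4))

  tr$x[3] <- 1.562
  d <- displacement(tr)
  expect_equal(d[3], 1.562)
  expect_equal(d[4], 1.562) # return jump

  tr2 <- flat_motion(3)
  tr2$yaw[2] <- 1 # one degree of yaw
  expect_equal(displacement(tr2)[2], 65 * pi / 180, tolerance = 1e-12)
})

test_that("displacement validates its input", {
  tr <- flat_motion(3)
  expect_error(displacement(tr[1, ]), "two volumes")
  tr$x <- c(0, NA, 0)
  expect_error(displacement(tr), "finite")
  bad <- tibble::tibble(x = 1:3, y = 1:3)
  expect_error(displacement(bad), "lacks")
})

test_that("despike repairs flagged volumes and leaves clean ones untouched", {
  dims <- c(6, 6, 6); nv <- 100
  withr::with_seed(1, data <- array(rnorm(prod(dims) * nv, 100), c(dims, nv)))
  tr <- flat_motion(nv)
  tr$x[50] <- 2.5 # single spike
  data[, , , 50] <- data[, , , 50] + 10

  out <- despike(data, tr)
  expect_equal(sort(out$report$flagged), c(50, 51))
  expect_equal(out$report$repaired_fraction, 0.02)
  # volume 50 replaced by its neighbours: spike amplitude gone
  expect_lt(abs(mean(out$run[, , , 50]) - 100), 1)
  # unflagged volumes are bit-identical
  untouched <- setdiff(seq_len(nv), out$report$flagged)
  expect_identical(out$run[, , , untouched], data[, , , untouched])
})

test_that("despike is idempotent and clean runs pass through bit-identically", {
  dims <- c(6, 6, 6); nv <- 60
  withr::with_seed(2, data <- array(rnorm(prod(dims) * nv, 100), c(dims, nv)))
  tr <- flat_motion(nv)
  clean <- despike(data, tr)
  expect_identical(clean$run, data)
  expect_equal(length(clean$report$flagged), 0)

  tr$y[20] <- -3
  once <- despike(data, tr)
  twice <- despike(once$run, tr)
  expect_identical(twice$run, once$run)
})

test_that("despike handles edge volumes and global-signal spikes", {
  dims <- c(6, 6, 6); nv <- 30
  withr::with_seed(3, data <- array(rnorm(prod(dims) * nv, 100), c(dims, nv)))
  tr <- flat_motion(nv)
  tr$x[2] <- 5 # makes volumes 2 and 3 motion-flagged; volume 1 via signal
  data[, , , 1] <- data[, , , 1] * 1.10 # 10% global-signal spike at the edge
  out <- despike(data, tr)
  expect_true(all(c(1, 2, 3) %in% out$report$flagged))
  # edge volume copies the nearest unflagged volume
  expect_identical(out$run[, , , 1], out$run[, , , 4])
  expect_error(despike(data, dplyr::mutate(tr, x = 100 * seq_len(nv))),
               "unrecoverable")
})

test_that("qc_gate enforces both inclusion boundaries strictly", {
  qc <- tibble::tibble(
    subject_id = c("s1", "s2", "s3", "s4"),
    n_volumes = 100, n_repaired = c(19, 20, 5, 5))
  beh <- tibble::tibble(
    subject_id = c("s1", "s2", "s3", "s4"),
    accuracy = c(0.9, 0.9, 0.50, 0.51))
  gate <- qc_gate(qc, beh)
  expect_equal(gate$include, c(TRUE, FALSE, FALSE, TRUE))
  expect_match(gate$reason[2], "frames")
  expect_match(gate$reason[3], "accuracy")
  expect_error(qc_gate(qc[1:3, ], beh), "missing QC")
})

test_that("simulated spikes are detected with full sensitivity", {
  cfg <- tiny_config(seed = 5, motion_spike_rate = 0.05)
  ev <- generate_design(cfg, 0.8, seed = 5)
  bumps <- plastimap:::precompute_bumps(cfg)
  amps <- plastimap:::amplitude_maps_for(cfg, 1.0, bumps)
  run <- simulate_bold(ev, amps, cfg, seed = 6)
  expect_gt(length(run$spiked_volumes), 0)
  out <- despike(run)
  expect_true(all(run$spiked_volumes %in% out$report$flagged))
  # repair restores spiked volumes to the noise band
  gs <- apply(out$run$data, 4, function(v) mean(v[run$mask]))
  expect_lt(max(abs(gs[run$spiked_volumes] - median(gs))),
            3 * stats::sd(gs))
})

test_that("a spike-free simulation yields a zero repair fraction", {
  cfg <- tiny_config(seed = 7, motion_spike_rate = 0)
  ev <- generate_design(cfg, 0.8, seed = 7)
  bumps <- plastimap:::precompute_bumps(cfg)
  amps <- plastimap:::amplitude_maps_for(cfg, 1.0, bumps)
  run <- simulate_bold(ev, amps, cfg, seed = 8)
  out <- despike(run)
  expect_equal(out$report$repaired_fraction, 0)
})
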