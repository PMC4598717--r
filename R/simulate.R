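#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set for a two-group (MLD, TD) by
#' two-session (pre, post) synthetic fMRI cohort. The defaults encode the
#' emulated study conditions: 15 subjects per group, two runs per session,
#' 12 arithmetic-verification (Addition) and 12 number-identity (Control)
#' trials per run with a 9.5 s trial window, 0.5 s fixation, six jittered
#' 10 s rests, TR of 2 s, a 24 x 28 x 24 grid at 2 mm, and a set of
#' "aberrant" regions that are overactivated in the MLD group before
#' tutoring and retain on average 20% of that overactivation afterwards.
#'
#' @param grid_shape Voxels per axis.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param n_per_group Subjects per group.
#' @param tr_seconds Repetition time in seconds.
#' @param trial_window_seconds Problem presentation window (boxcar length).
#' @param fixation_seconds Fixation duration preceding each problem.
#' @param trials_per_condition_per_run Trials per condition per run.
#' @param n_runs Runs per session.
#' @param n_rests Rest periods per run.
#' @param rest_seconds Rest duration in seconds.
#' @param run_length_seconds Optional fixed run length; the default derives
#'   it from the schedule. A schedule longer than this value is rejected.
#' @param aberrant_regions Data frame with one row per region and columns
#'   `center` (list of voxel coordinates), `radius_mm`, `pre_effect`
#'   (MLD overactivation amplitude before tutoring), `post_retention_mean`
#'   and `post_retention_sd` (fraction of the pre effect retained after
#'   tutoring).
#' @param task_regions Data frame of regions activated by the task in both
#'   groups (columns `center`, `radius_mm`, `amplitude`).
#' @param base_region_amplitude Task activation amplitude shared by both
#'   groups inside the aberrant regions.
#' @param noise_sd In-mask standard deviation of the session-specific map
#'   noise (activation-map units).
#' @param subject_pattern_sd Standard deviation of each subject's stable
#'   idiosyncratic activation pattern.
#' @param smoothness_fwhm_mm Spatial smoothness (FWHM) of all noise fields.
#' @param ar1_rho Temporal AR(1) autocorrelation of BOLD noise.
#' @param bold_noise_sd Per-volume BOLD noise standard deviation.
#' @param control_amplitude_frac Control-condition amplitude as a fraction
#'   of the task-region amplitude.
#' @param signature_gain Strength of the spatial "signature" texture
#'   multiplicatively modulating the aberrant overactivation (`0` gives
#'   spatially uniform region effects).
#' @param signature_group_share Fraction of the signature-texture variance
#'   shared by the whole MLD group; the remainder is subject-specific but
#'   stable across sessions, so it contributes to within-group pattern
#'   variability and to pre-to-post change, not to group discriminability.
#' @param reorg_gain Amplitude of the idiosyncratic post-tutoring
#'   reorganization component: each MLD subject's post map gains a fresh
#'   subject-specific smooth pattern inside the aberrant regions scaled by
#'   `reorg_gain` times their normalization magnitude, emulating
#'   individual functional reorganization accompanying normalization
#'   (zero when retention is 1).
#' @param plasticity_gain_coupling Latent correlation `rho` between
#'   per-subject normalization magnitude and accuracy gain in the MLD group.
#' @param severity_sd Between-subject SD of the multiplicative severity
#'   factor scaling MLD overactivation.
#' @param accuracy_pre_mean,accuracy_pre_sd Named (`MLD`, `TD`) moments of
#'   pre-tutoring Addition accuracy.
#' @param gain_logit_mean,gain_logit_sd Named (`MLD`, `TD`) moments of the
#'   logit-scale accuracy change from pre to post.
#' @param rt_pre_mean_ms,rt_between_sd_ms,rt_change_ms,rt_change_sd_ms
#'   Reaction-time model: per-group pre-tutoring means, between-subject SD,
#'   and pre-to-post reduction (mean, SD), all in milliseconds.
#' @param motion_spike_rate Fraction of volumes receiving an injected
#'   motion spike in BOLD mode.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_per_group = 4, seed = 1)
#' cfg$n_per_group
sim_config <- function(grid_shape = c(24, 28, 24),
                       voxel_mm = 2,
                       n_per_group = 15,
                       tr_seconds = 2,
                       trial_window_seconds = 9.5,
                       fixation_seconds = 0.5,
                       trials_per_condition_per_run = 12,
                       n_runs = 2,
                       n_rests = 6,
                       rest_seconds = 10,
                       run_length_seconds = NULL,
                       aberrant_regions = default_aberrant_regions(),
                       task_regions = default_task_regions(),
                       base_region_amplitude = 0.5,
                       noise_sd = 0.7,
                       subject_pattern_sd = 0.5,
                       smoothness_fwhm_mm = 6,
                       ar1_rho = 0.3,
                       bold_noise_sd = 1.0,
                       control_amplitude_frac = 0.4,
                       signature_gain = 0.7,
                       signature_group_share = 0.3,
                       reorg_gain = 0.9,
                       plasticity_gain_coupling = 0.6,
                       severity_sd = 0.10,
                       accuracy_pre_mean = c(MLD = 0.70, TD = 0.85),
                       accuracy_pre_sd = c(MLD = 0.08, TD = 0.06),
                       gain_logit_mean = c(MLD = 1.0, TD = 0.1),
                       gain_logit_sd = c(MLD = 0.6, TD = 0.4),
                       rt_pre_mean_ms = c(MLD = 4900, TD = 4600),
                       rt_between_sd_ms = 600,
                       rt_change_ms = c(MLD = 150, TD = 700),
                       rt_change_sd_ms = 350,
                       motion_spike_rate = 0.02,
                       seed = 1) {
  cfg <- list(
    grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
    n_per_group = as.integer(n_per_group), tr_seconds = tr_seconds,
    trial_window_seconds = trial_window_seconds,
    fixation_seconds = fixation_seconds,
    trials_per_condition_per_run = as.integer(trials_per_condition_per_run),
    n_runs = as.integer(n_runs), n_rests = as.integer(n_rests),
    rest_seconds = rest_seconds, run_length_seconds = run_length_seconds,
    aberrant_regions = canonical_regions(aberrant_regions),
    task_regions = tibble::as_tibble(task_regions),
    base_region_amplitude = base_region_amplitude,
    noise_sd = noise_sd, subject_pattern_sd = subject_pattern_sd,
    smoothness_fwhm_mm = smoothness_fwhm_mm, ar1_rho = ar1_rho,
    bold_noise_sd = bold_noise_sd,
    control_amplitude_frac = control_amplitude_frac,
    signature_gain = signature_gain,
    signature_group_share = signature_group_share,
    reorg_gain = reorg_gain,
    plasticity_gain_coupling = plasticity_gain_coupling,
    severity_sd = severity_sd,
    accuracy_pre_mean = accuracy_pre_mean, accuracy_pre_sd = accuracy_pre_sd,
    gain_logit_mean = gain_logit_mean, gain_logit_sd = gain_logit_sd,
    rt_pre_mean_ms = rt_pre_mean_ms, rt_between_sd_ms = rt_between_sd_ms,
    rt_change_ms = rt_change_ms, rt_change_sd_ms = rt_change_sd_ms,
    motion_spike_rate = motion_spike_rate, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_aberrant_regions <- function() {
  tibble::tibble(
    name = c("parietal_L", "parietal_R", "ventral_TO"),
    center = list(c(7, 19, 14), c(17, 19, 14), c(12, 8, 9)),
    radius_mm = c(8, 8, 8),
    pre_effect = c(2.0, 2.6, 3.2),
    post_retention_mean = 0.2,
    post_retention_sd = 0.3
  )
}

default_task_regions <- function() {
  tibble::tibble(
    name = c("frontal_L", "frontal_R"),
    center = list(c(8, 14, 18), c(16, 14, 18)),
    radius_mm = c(8, 8),
    amplitude = c(2.0, 2.0)
  )
}

canonical_regions <- function(regions) {
  r <- tibble::as_tibble(regions)
  needed <- c("center", "radius_mm", "pre_effect",
              "post_retention_mean", "post_retention_sd")
  missing <- setdiff(needed, names(r))
  if (length(missing) > 0) {
    abort(paste0("aberrant_regions lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"name" %in% names(r)) r$name <- paste0("region", seq_len(nrow(r)))
  r
}

validate_sim_config <- function(cfg) {
  pos <- c("n_per_group", "tr_seconds", "trial_window_seconds", "n_runs",
           "rest_seconds", "voxel_mm", "noise_sd")
  for (f in pos) {
    if (any(cfg[[f]] <= 0)) abort(paste0("sim_config: `", f, "` must be positive"))
  }
  if (cfg$trials_per_condition_per_run < 0 || cfg$n_rests < 0) {
    abort("sim_config: trial and rest counts must be non-negative")
  }
  rho <- cfg$plasticity_gain_coupling
  if (rho < 0 || rho > 1) {
    abort("sim_config: plasticity_gain_coupling must lie in [0, 1]")
  }
  reg <- cfg$aberrant_regions
  if (any(reg$post_retention_mean < 0 | reg$post_retention_mean > 1)) {
    abort("sim_config: post_retention_mean must lie in [0, 1]")
  }
  for (i in seq_len(nrow(reg))) {
    ctr <- reg$center[[i]]
    rad <- reg$radius_mm[i] / cfg$voxel_mm
    if (length(ctr) != 3 || any(ctr - rad < 1) ||
        any(ctr + rad > cfg$grid_shape)) {
      abort(paste0("sim_config: region ", i, " does not lie inside the grid"))
    }
  }
  if (!is.null(cfg$run_length_seconds)) {
    need <- schedule_seconds(cfg)
    if (need > cfg$run_length_seconds) {
      abort(paste0("sim_config: schedule needs ", need,
                   " s but run_length_seconds is ", cfg$run_length_seconds,
                   " s (schedule overflow)"))
    }
  }
  invisible(cfg)
}

schedule_seconds <- function(cfg) {
  n_trials <- 2L * cfg$trials_per_condition_per_run
  n_trials * (cfg$fixation_seconds + cfg$trial_window_seconds) +
    cfg$n_rests * cfg$rest_seconds
}

run_length_seconds <- function(cfg) {
  cfg$run_length_seconds %||% schedule_seconds(cfg)
}

run_n_volumes <- function(cfg) {
  as.integer(ceiling(run_length_seconds(cfg) / cfg$tr_seconds))
}

#' Generate one run's trial schedule
#'
#' Interleaves Addition and Control trials in random order with rest
#' periods at jittered positions (minimum separation of two trials between
#' rests), samples per-trial correctness from the subject's true accuracy,
#' and draws reaction times for responded trials.
#'
#' @param config A [sim_config()].
#' @param accuracy True probability of a correct response on Addition
#'   trials; Control trials use `min(accuracy + 0.2, 0.99)`.
#' @param rt_mean_ms Median-scale reaction time in milliseconds.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A tibble with columns `onset`, `duration`, `trial_type`
#'   (`"addition"`/`"control"`), `correct` and `rt` (ms), ordered by onset.
#' @export
#' @examples
#' ev <- generate_design(sim_config(), accuracy = 0.8, seed = 7)
#' table(ev$trial_type)
generate_design <- function(config, accuracy = 0.8, rt_mean_ms = 4500,
                            seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_(seed, {
    n_per <- config$trials_per_condition_per_run
    n_trials <- 2L * n_per
    if (n_trials == 0L) {
      return(tibble(onset = numeric(0), duration = numeric(0),
                    trial_type = character(0), correct = logical(0),
                    rt = numeric(0)))
    }
    trial_type <- sample(rep(c("addition", "control"), each = n_per))
    rest_after <- jittered_rest_slots(n_trials, config$n_rests)

    trial_len <- config$fixation_seconds + config$trial_window_seconds
    onset <- numeric(n_trials)
    t_cur <- 0
    for (i in seq_len(n_trials)) {
      onset[i] <- t_cur + config$fixation_seconds
      t_cur <- t_cur + trial_len
      t_cur <- t_cur + config$rest_seconds * sum(rest_after == i)
    }
    total <- t_cur + config$rest_seconds * sum(rest_after == 0)
    if (total > run_length_seconds(config) + 1e-9) {
      abort(paste0("generate_design: schedule of ", total,
                   " s overflows the run length of ",
                   run_length_seconds(config), " s"))
    }

    p_correct <- ifelse(trial_type == "addition", accuracy,
                        min(accuracy + 0.2, 0.99))
    correct <- runif(n_trials) < p_correct
    rt <- exp(rnorm(n_trials, mean = log(rt_mean_ms), sd = 0.25))
    rt <- pmin(pmax(rt, 300), config$trial_window_seconds * 1000 - 1)
    tibble(onset = onset, duration = config$trial_window_seconds,
           trial_type = trial_type, correct = correct, rt = round(rt, 1))
  })
}

# choose n_rests slots "after trial k" (k = 0 means before the first trial)
# with a minimum separation of 2 trials between consecutive rests
jittered_rest_slots <- function(n_trials, n_rests) {
  if (n_rests == 0) return(integer(0))
  for (try in 1:1000) {
    slots <- sort(sample(0:(n_trials - 1), n_rests))
    if (n_rests == 1 || all(diff(slots) >= 2)) return(slots)
  }
  abort("jittered_rest_slots: cannot place rests with the required separation")
}

# latent mean m such that E[clamp(N(m, s), 0, 1)] equals `target`, so the
# realized mean retention matches the configured value despite clamping
clamped_mean_adjust <- function(target, s) {
  if (s == 0) return(target)
  f <- function(m) {
    a <- (0 - m) / s; b <- (1 - m) / s
    m * (pnorm(b) - pnorm(a)) - s * (dnorm(b) - dnorm(a)) +
      (1 - pnorm(b)) - target
  }
  stats::uniroot(f, c(-2, 2), tol = 1e-10)$root
}

# latent per-subject ground truth for both groups.
# (normalization, gain) coupling: a bivariate standard normal with
# correlation rho drives retention (via -z1) and the logit-scale accuracy
# change (via z2), so that larger normalization accompanies larger gains.
sample_ground_truth <- function(config, seed = config$seed) {
  with_seed_(seed, {
    n <- config$n_per_group
    reg <- config$aberrant_regions
    rho <- config$plasticity_gain_coupling
    out <- list()
    for (grp in c("MLD", "TD")) {
      z1 <- rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
      severity <- pmax(rnorm(n, 1, config$severity_sd), 0.3)
      if (grp == "MLD") {
        mu_adj <- vapply(seq_len(nrow(reg)), function(r) {
          clamped_mean_adjust(reg$post_retention_mean[r],
                              reg$post_retention_sd[r])
        }, numeric(1))
        retention <- vapply(seq_len(n), function(i) {
          r <- mu_adj - reg$post_retention_sd * z1[i]
          mean(pmin(pmax(r, 0), 1))
        }, numeric(1))
        amp_pre <- lapply(seq_len(n), function(i) severity[i] * reg$pre_effect)
        amp_post <- lapply(seq_len(n), function(i) amp_pre[[i]] * retention[i])
        d_logit <- config$gain_logit_mean[["MLD"]] +
          config$gain_logit_sd[["MLD"]] * z2
        acc_pre <- pmin(pmax(
          rnorm(n, config$accuracy_pre_mean[["MLD"]],
                config$accuracy_pre_sd[["MLD"]]), 0.525), 0.95)
      } else {
        retention <- rep(1, n)
        amp_pre <- replicate(n, rep(0, nrow(reg)), simplify = FALSE)
        amp_post <- amp_pre
        d_logit <- rnorm(n, config$gain_logit_mean[["TD"]],
                         config$gain_logit_sd[["TD"]])
        acc_pre <- pmin(pmax(
          rnorm(n, config$accuracy_pre_mean[["TD"]],
                config$accuracy_pre_sd[["TD"]]), 0.55), 0.98)
      }
      acc_post <- plogis(qlogis(acc_pre) + d_logit)
      rt_pre <- rnorm(n, config$rt_pre_mean_ms[[grp]], config$rt_between_sd_ms)
      rt_post <- rt_pre - rnorm(n, config$rt_change_ms[[grp]],
                                config$rt_change_sd_ms)
      out[[grp]] <- tibble(
        subject_id = sprintf("%s%02d", grp, seq_len(n)),
        group = grp, severity = severity, retention = retention,
        amplitude_pre = amp_pre, amplitude_post = amp_post,
        normalization = vapply(seq_len(n), function(i) {
          mean(amp_pre[[i]] - amp_post[[i]])
        }, numeric(1)),
        accuracy_true_pre = acc_pre, accuracy_true_post = acc_post,
        gain_true = acc_post - acc_pre,
        rt_true_pre = pmax(rt_pre, 800), rt_true_post = pmax(rt_post, 800)
      )
    }
    bind_rows(out)
  })
}

# condition-amplitude maps (activation-map units) for one subject/session.
# The aberrant (group-difference) component is modulated by the fixed
# group-level signature texture so the overactivation has a consistent
# fine-grained topography rather than a spatially uniform blob.
amplitude_maps_for <- function(config, region_amps, bumps, texture = NULL) {
  add <- bumps$task_total +
    config$base_region_amplitude * bumps$aberrant_total
  aberr <- array(0, dim(add))
  for (r in seq_along(region_amps)) {
    aberr <- aberr + region_amps[r] * bumps$aberrant[[r]]
  }
  tex <- texture %||% bumps$signature
  if (!is.null(tex)) {
    aberr <- aberr * (1 + config$signature_gain * tex)
  }
  list(addition = add + aberr,
       control = config$control_amplitude_frac * bumps$task_total)
}

# subject-level aberration texture: group-shared plus subject-specific
# components, fixed across sessions
subject_texture <- function(config, bumps, subject_id) {
  if (is.null(bumps$signature) || config$signature_gain <= 0) return(NULL)
  a <- config$signature_group_share
  own <- with_seed_(substream_seed(config$seed, paste0("texture_", subject_id)),
                    smooth_noise_field(config$grid_shape,
                                       config$smoothness_fwhm_mm,
                                       config$voxel_mm,
                                       brain_mask(config$grid_shape), 1))
  sqrt(a) * bumps$signature + sqrt(1 - a) * own
}

# idiosyncratic post-tutoring reorganization: a subject-specific smooth
# pattern confined to the aberrant regions, scaled by the subject's
# normalization magnitude
reorg_field <- function(config, bumps, subject_id, normalization) {
  if (config$reorg_gain <= 0 || normalization <= 0) return(NULL)
  f <- with_seed_(substream_seed(config$seed, paste0("reorg_", subject_id)),
                  smooth_noise_field(config$grid_shape,
                                     config$smoothness_fwhm_mm,
                                     config$voxel_mm,
                                     brain_mask(config$grid_shape), 1))
  config$reorg_gain * normalization * bumps$aberrant_total * f
}

# precompute region bump fields (and, when requested, the fixed group-level
# signature texture of the aberration) for a config
precompute_bumps <- function(config, with_signature = FALSE) {
  dims <- config$grid_shape
  ab <- lapply(seq_len(nrow(config$aberrant_regions)), function(i) {
    region_bump(config$aberrant_regions$center[[i]],
                config$aberrant_regions$radius_mm[i], dims, config$voxel_mm)
  })
  ab_tot <- Reduce(`+`, ab, array(0, dims))
  tk <- array(0, dims)
  for (i in seq_len(nrow(config$task_regions))) {
    tk <- tk + config$task_regions$amplitude[i] *
      region_bump(config$task_regions$center[[i]],
                  config$task_regions$radius_mm[i], dims, config$voxel_mm)
  }
  sig <- NULL
  if (with_signature && config$signature_gain > 0) {
    sig <- with_seed_(substream_seed(config$seed, "signature"),
                      smooth_noise_field(dims, config$smoothness_fwhm_mm,
                                         config$voxel_mm, brain_mask(dims), 1))
  }
  list(aberrant = ab, aberrant_total = ab_tot, task_total = tk,
       signature = sig)
}

#' Simulate one BOLD run
#'
#' Forward model for the GLM: the voxelwise signal is the sum over
#' conditions of the condition amplitude map times the condition regressor
#' (a boxcar of the trial-window length at each onset convolved with the
#' canonical HRF, sampled at the TR), plus spatially smoothed AR(1)
#' Gaussian noise. Motion spikes are injected at `config$motion_spike_rate`
#' with frame-to-frame displacement exceeding the despiking threshold, and
#' the corresponding volumes are corrupted with a global intensity offset.
#'
#' @param events Event table from [generate_design()].
#' @param amplitudes List with 3-D arrays `addition` and `control` giving
#'   condition amplitudes in GLM beta units.
#' @param config A [sim_config()].
#' @param seed Integer seed, or `NULL`.
#' @return An object of class `bold_run`: list with `data` (4-D array),
#'   `tr`, `mask`, `motion` (per-volume translations in mm and rotations in
#'   degrees) and `spiked_volumes` (indices of injected spikes).
#' @export
simulate_bold <- function(events, amplitudes, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_(seed, {
    dims <- config$grid_shape
    nv <- run_n_volumes(config)
    mask <- brain_mask(dims)
    tr <- config$tr_seconds

    sig_t <- matrix(0, nrow = nv, ncol = 2) # addition, control
    for (j in c(1, 2)) {
      cond <- c("addition", "control")[j]
      ev <- events[events$trial_type == cond, , drop = FALSE]
      if (nrow(ev) > 0) {
        sig_t[, j] <- convolve_events(ev$onset, ev$duration, nv, tr)
      }
    }

    data <- array(0, dim = c(dims, nv))
    amp <- cbind(as.vector(amplitudes$addition), as.vector(amplitudes$control))
    flat <- amp %*% t(sig_t) # voxels x volumes
    if (config$bold_noise_sd > 0) {
      rho <- config$ar1_rho
      prev <- smooth_noise_field(dims, config$smoothness_fwhm_mm,
                                 config$voxel_mm, mask, config$bold_noise_sd)
      flat[, 1] <- flat[, 1] + as.vector(prev)
      for (t in 2:nv) {
        eps <- smooth_noise_field(dims, config$smoothness_fwhm_mm,
                                  config$voxel_mm, mask, config$bold_noise_sd)
        prev <- rho * prev + sqrt(1 - rho^2) * eps
        flat[, t] <- flat[, t] + as.vector(prev)
      }
    }

    motion <- tibble(
      x = cumsum(rnorm(nv, 0, 0.02)), y = cumsum(rnorm(nv, 0, 0.02)),
      z = cumsum(rnorm(nv, 0, 0.02)),
      pitch = cumsum(rnorm(nv, 0, 0.01)), roll = cumsum(rnorm(nv, 0, 0.01)),
      yaw = cumsum(rnorm(nv, 0, 0.01))
    )
    n_spike <- stats::rbinom(1, nv - 2, config$motion_spike_rate)
    # spikes are isolated events: enforce >= 2 volumes between them so
    # each one produces a detectable frame-to-frame jump
    spiked <- integer(0)
    candidates <- 2:(nv - 1)
    while (length(spiked) < n_spike && length(candidates) > 0) {
      v <- if (length(candidates) == 1) candidates else sample(candidates, 1)
      spiked <- c(spiked, v)
      candidates <- setdiff(candidates, (v - 2):(v + 2))
    }
    spiked <- sort(spiked)
    for (v in spiked) {
      motion$x[v] <- motion$x[v] + sample(c(-1, 1), 1) * runif(1, 1.8, 3.5)
      flat[, v] <- flat[, v] + 3 * max(config$bold_noise_sd, 0.5)
    }
    flat <- flat + 100 # baseline intensity so %-of-baseline QC is meaningful
    data <- array(t(flat), dim = c(nv, dims))
    data <- aperm(data, c(2, 3, 4, 1))

    structure(list(data = data, tr = tr, mask = mask, motion = motion,
                   spiked_volumes = spiked),
              class = "bold_run")
  })
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_run> ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " volumes, TR ", x$tr, " s, ",
      length(x$spiked_volumes), " injected spike(s)\n", sep = "")
  invisible(x)
}

#' Generate a complete synthetic cohort
#'
#' Draws per-subject ground truth (overactivation amplitudes, retention,
#' accuracy, reaction times), builds trial schedules, and produces either
#' session-level activation maps directly (`mode = "maps"`, the fast mode
#' used by most analyses) or full 4-D BOLD runs (`mode = "bold"`, which
#' exercises despiking and GLM estimation). Each activation map is the sum
#' of a shared task pattern, a subject-specific stable pattern, the
#' group/session-specific overactivation in the aberrant regions, and
#' spatially smoothed session noise.
#'
#' @param config A [sim_config()].
#' @param mode `"maps"` for precomputed session activation maps, `"bold"`
#'   for full BOLD time series.
#' @param dir Optional output directory; when given, maps are written as
#'   NIfTI, events as TSV, the manifest as CSV and the ground truth as JSON.
#' @param groups Which groups to generate (default both); analyses that
#'   only touch one group can skip the other's maps.
#' @return An object of class `cohort`: list with `manifest` (tibble with
#'   one row per subject x session: `subject_id`, `group`, `session`,
#'   `accuracy`, `rt_median_mean` and a `map` list-column in maps mode or a
#'   `runs` list-column in bold mode), `events` (nested tibble), `behavior`,
#'   `ground_truth`, `mask`, `config` and `mode`.
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(n_per_group = 3, seed = 1))
#' nrow(coh$manifest)
generate_cohort <- function(config, mode = c("maps", "bold"), dir = NULL,
                            groups = c("MLD", "TD")) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  groups <- match.arg(groups, several.ok = TRUE)
  gt <- sample_ground_truth(config, seed = substream_seed(config$seed, "truth"))
  gt <- gt[gt$group %in% groups, , drop = FALSE]
  dims <- config$grid_shape
  mask <- brain_mask(dims)
  bumps <- precompute_bumps(config, with_signature = TRUE)

  # stable subject patterns
  patt <- lapply(seq_len(nrow(gt)), function(i) {
    with_seed_(substream_seed(config$seed, paste0("pattern_", gt$subject_id[i])),
               smooth_noise_field(dims, config$smoothness_fwhm_mm,
                                  config$voxel_mm, mask,
                                  config$subject_pattern_sd))
  })

  rows <- list(); ev_rows <- list()
  for (i in seq_len(nrow(gt))) {
    texture <- if (gt$group[i] == "MLD") {
      subject_texture(config, bumps, gt$subject_id[i])
    } else NULL
    for (session in c("pre", "post")) {
      acc <- if (session == "pre") gt$accuracy_true_pre[i] else gt$accuracy_true_post[i]
      rt_ms <- if (session == "pre") gt$rt_true_pre[i] else gt$rt_true_post[i]
      amps <- if (session == "pre") gt$amplitude_pre[[i]] else gt$amplitude_post[[i]]
      sid <- gt$subject_id[i]

      run_events <- lapply(seq_len(config$n_runs), function(r) {
        generate_design(config, accuracy = acc, rt_mean_ms = rt_ms,
                        seed = substream_seed(config$seed,
                                              paste(sid, session, r, "ev")))
      })
      beh <- score_session(run_events)

      row <- tibble(subject_id = sid, group = gt$group[i], session = session,
                    accuracy = beh$accuracy, rt_median_mean = beh$rt)
      if (mode == "maps") {
        amap <- amplitude_maps_for(config, amps, bumps, texture)
        noise <- with_seed_(
          substream_seed(config$seed, paste(sid, session, "mapnoise")),
          smooth_noise_field(dims, config$smoothness_fwhm_mm,
                             config$voxel_mm, mask, config$noise_sd))
        vals <- amap$addition - amap$control + patt[[i]] + noise
        if (session == "post" && gt$group[i] == "MLD") {
          rf <- reorg_field(config, bumps, sid, gt$normalization[i])
          if (!is.null(rf)) vals <- vals + rf
        }
        vals[!mask] <- NA_real_
        row$map <- list(stat_map(vals, kind = "t", subject = sid,
                                 group = gt$group[i], session = session))
      } else {
        amap <- amplitude_maps_for(config, amps, bumps, texture)
        # the subject's stable pattern modulates the addition amplitude
        amap$addition <- amap$addition + patt[[i]]
        if (session == "post" && gt$group[i] == "MLD") {
          rf <- reorg_field(config, bumps, sid, gt$normalization[i])
          if (!is.null(rf)) amap$addition <- amap$addition + rf
        }
        runs <- lapply(seq_len(config$n_runs), function(r) {
          simulate_bold(run_events[[r]], amap, config,
                        seed = substream_seed(config$seed,
                                              paste(sid, session, r, "bold")))
        })
        row$runs <- list(runs)
      }
      rows[[length(rows) + 1]] <- row
      ev_rows[[length(ev_rows) + 1]] <- tibble(
        subject_id = sid, session = session, run = seq_len(config$n_runs),
        events = run_events)
    }
  }

  manifest <- bind_rows(rows)
  cohort <- structure(list(manifest = manifest, events = bind_rows(ev_rows),
                           ground_truth = gt, mask = mask, config = config,
                           mode = mode),
                      class = "cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$ground_truth), " subjects (",
      paste(unique(x$ground_truth$group), collapse = ", "),
      "), 2 sessions, mode = ", x$mode,
      ", seed = ", x$config$seed, "\n", sep = "")
  invisible(x)
}
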