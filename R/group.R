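#' Voxelwise group test
#'
#' Two-sample (independent, pooled variance), paired, or one-sample
#' voxelwise t-tests on subject-level maps, optionally controlling for a
#' subject-level covariate (independent design only; the covariate is
#' centred and the t statistic reported for the group term).
#'
#' @param maps_a,maps_b Lists of [stat_map()]s or 3-D arrays (`maps_b`
#'   omitted for a one-sample test). Paired designs match by position.
#' @param design `"independent"`, `"paired"` or `"one_sample"`.
#' @param covariate Optional numeric covariate, one value per map in
#'   `c(maps_a, maps_b)`.
#' @param mask Logical array; defaults to voxels finite in all maps.
#' @return A [stat_map()] of kind `"t"` with `df` set, plus attribute
#'   `"residuals"` (subjects x in-mask voxels matrix of model residuals)
#'   used for smoothness estimation.
#' @export
voxelwise_test <- function(maps_a, maps_b = NULL,
                           design = c("independent", "paired", "one_sample"),
                           covariate = NULL, mask = NULL) {
  design <- match.arg(design)
  A <- vapply(maps_a, function(m) as.vector(map_values(m)),
              numeric(length(map_values(maps_a[[1]]))))
  dims <- dim(map_values(maps_a[[1]]))
  if (design == "paired") {
    if (is.null(maps_b) || length(maps_b) != length(maps_a)) {
      abort("voxelwise_test: paired design requires matched maps_b")
    }
    sa <- vapply(maps_a, function(m) {
      if (inherits(m, "stat_map")) m$subject else NA_character_
    }, character(1))
    sb <- vapply(maps_b, function(m) {
      if (inherits(m, "stat_map")) m$subject else NA_character_
    }, character(1))
    if (!all(is.na(sa)) && !identical(sa, sb)) {
      abort("voxelwise_test: paired design has mismatched subjects")
    }
    B <- vapply(maps_b, function(m) as.vector(map_values(m)), numeric(nrow(A)))
    Y <- t(A - B)
    X <- matrix(1, nrow(Y), 1)
    cvec <- 1
  } else if (design == "one_sample") {
    Y <- t(A)
    X <- matrix(1, nrow(Y), 1)
    cvec <- 1
  } else {
    if (is.null(maps_b) || length(maps_b) < 2 || length(maps_a) < 2) {
      abort("voxelwise_test: independent design needs >= 2 maps per group")
    }
    B <- vapply(maps_b, function(m) as.vector(map_values(m)), numeric(nrow(A)))
    Y <- t(cbind(A, B))
    g <- c(rep(1, length(maps_a)), rep(0, length(maps_b)))
    X <- cbind(intercept = 1, group = g)
    if (!is.null(covariate)) {
      if (length(covariate) != nrow(Y)) {
        abort("voxelwise_test: covariate length does not match maps")
      }
      cv <- covariate - mean(covariate)
      if (qr(cbind(X, cv))$rank < ncol(X) + 1) {
        abort("voxelwise_test: covariate is collinear with the group term")
      }
      X <- cbind(X, covariate = cv)
    }
    cvec <- c(0, 1, rep(0, ncol(X) - 2))
  }

  if (is.null(mask)) {
    mask <- array(colSums(is.na(Y)) == 0, dim = dims)
  }
  Ym <- Y[, as.vector(mask), drop = FALSE]
  qx <- qr(X)
  betas <- qr.coef(qx, Ym)
  betas[is.na(betas)] <- 0
  res <- Ym - X %*% betas
  df <- nrow(Ym) - qx$rank
  if (df < 1) abort("voxelwise_test: no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  cXXc <- drop(t(cvec) %*% XtXinv %*% cvec)
  con <- drop(t(cvec) %*% betas)
  tval <- ifelse(sigma2 > 0, con / sqrt(sigma2 * cXXc), NA_real_)
  out <- stat_map(embed_in_mask(tval, mask), "t", df = df)
  attr(out, "residuals") <- res
  attr(out, "mask") <- mask
  out
}

#' Estimate spatial smoothness of residual maps
#'
#' Estimates the Gaussian-equivalent FWHM per axis from the variance of
#' spatial first differences of standardised residuals (the
#' Forman/Kiebel estimator used by Monte-Carlo cluster simulators).
#'
#' @param resid_maps List of 3-D residual arrays, or the `"residuals"`
#'   attribute of [voxelwise_test()] together with its mask.
#' @param mask Logical 3-D array.
#' @param voxel_mm Voxel size in mm.
#' @return Named numeric vector `c(x, y, z)` of FWHM estimates in mm.
#' @export
estimate_smoothness <- function(resid_maps, mask, voxel_mm = 2) {
  if (sum(mask) < 100) abort("estimate_smoothness: mask too small (<100 voxels)")
  if (is.matrix(resid_maps)) {
    resid_maps <- lapply(seq_len(nrow(resid_maps)), function(i) {
      embed_in_mask(resid_maps[i, ], mask)
    })
  }
  if (length(resid_maps) < 2) {
    abort("estimate_smoothness: at least two residual maps required")
  }
  dims <- dim(mask)
  tot_var <- 0
  diff_var <- c(x = 0, y = 0, z = 0)
  diff_n <- c(x = 0, y = 0, z = 0)
  n_val <- 0
  for (m in resid_maps) {
    v <- map_values(m)
    s <- sd(v[mask])
    if (!is.finite(s) || s == 0) {
      abort("estimate_smoothness: residual map has zero variance")
    }
    v <- v / s
    tot_var <- tot_var + sum(v[mask]^2); n_val <- n_val + sum(mask)
    for (ax in 1:3) {
      idx_lo <- slice.index(mask, ax) <= dims[ax] - 1
      lo <- mask & idx_lo
      hi_ok <- array(FALSE, dims)
      # neighbour along axis ax must also be in the mask
      shift <- function(a) {
        out <- array(FALSE, dims)
        if (ax == 1) out[1:(dims[1] - 1), , ] <- a[2:dims[1], , ]
        if (ax == 2) out[, 1:(dims[2] - 1), ] <- a[, 2:dims[2], ]
        if (ax == 3) out[, , 1:(dims[3] - 1)] <- a[, , 2:dims[3]]
        out
      }
      pair <- lo & shift(mask)
      if (!any(pair)) next
      shiftv <- function(a) {
        out <- array(NA_real_, dims)
        if (ax == 1) out[1:(dims[1] - 1), , ] <- a[2:dims[1], , ]
        if (ax == 2) out[, 1:(dims[2] - 1), ] <- a[, 2:dims[2], ]
        if (ax == 3) out[, , 1:(dims[3] - 1)] <- a[, , 2:dims[3]]
        out
      }
      d <- (shiftv(v) - v)[pair]
      diff_var[ax] <- diff_var[ax] + sum(d^2)
      diff_n[ax] <- diff_n[ax] + length(d)
    }
  }
  s2 <- tot_var / n_val
  fwhm <- numeric(3)
  for (ax in 1:3) {
    vd <- diff_var[ax] / diff_n[ax]
    ratio <- 1 - vd / (2 * s2)
    fwhm[ax] <- if (ratio <= 0) {
      voxel_mm # white noise or rougher: resolution floor
    } else {
      voxel_mm * sqrt(-2 * log(2) / log(ratio))
    }
  }
  stats::setNames(fwhm, c("x", "y", "z"))
}

#' Match a smoothing kernel to an estimated smoothness
#'
#' The spatial-derivative smoothness estimator is slightly biased on
#' finite masked grids, and the cluster-extent null is steeply sensitive
#' to the kernel. Because the data and the Monte-Carlo engine share the
#' same smoothing operator, the bias cancels if the engine's kernel is
#' chosen so that its own fields reproduce the estimated smoothness:
#' this helper measures the estimator on reference fields smoothed at
#' the target value and returns the bias-corrected kernel.
#'
#' @param fwhm_mm Estimated smoothness of the data (mm).
#' @param mask Logical 3-D array.
#' @param voxel_mm Voxel size (mm).
#' @param seed Integer seed for the reference fields.
#' @param n_fields Reference fields used to measure the estimator.
#' @return Adjusted kernel FWHM in mm.
#' @export
match_smoothing_kernel <- function(fwhm_mm, mask, voxel_mm = 2, seed = 1,
                                   n_fields = 20) {
  target <- mean(fwhm_mm)
  ref <- with_seed_(seed, lapply(seq_len(n_fields), function(i) {
    gaussian_smooth_3d(array(rnorm(prod(dim(mask))), dim(mask)),
                       target, voxel_mm)
  }))
  realized <- mean(estimate_smoothness(ref, mask, voxel_mm))
  max(target + (target - realized), 0)
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates null statistic maps (white Gaussian noise smoothed to the
#' given FWHM and standardised within the mask), thresholds them at the
#' voxelwise height threshold, records the maximum same-sign cluster size,
#' and returns the smallest extent `k_min` whose family-wise exceedance
#' probability is at most `alpha`.
#'
#' @param mask Logical 3-D array.
#' @param fwhm_mm Smoothness of the simulated null maps (mm FWHM; scalar
#'   or per-axis vector, averaged).
#' @param height_p Voxelwise height threshold (two-sided when
#'   `two_sided = TRUE`).
#' @param alpha Cluster-level family-wise error rate.
#' @param n_sim Number of simulated null maps (>= 1000).
#' @param seed Integer seed.
#' @param voxel_mm Voxel size (mm).
#' @param connectivity 6, 18 or 26.
#' @param two_sided Threshold `|z|` and cluster each sign separately.
#' @param df When supplied, simulate proper Student-t statistic fields
#'   with this many degrees of freedom (each built from `df + 1` smoothed
#'   noise fields) instead of Gaussian fields. At low df the spatially
#'   smooth standard-error denominator makes t-field exceedances cluster
#'   more than Gaussian ones at the same voxelwise rate, so a Gaussian
#'   null is anticonservative for cluster extent; supply the analysis df
#'   for calibrated family-wise control.
#' @return Object of class `cluster_threshold`: `k_min`, `max_sizes`,
#'   and the simulation parameters.
#' @export
cluster_extent_threshold <- function(mask, fwhm_mm, height_p = 0.01,
                                     alpha = 0.01, n_sim = 10000, seed = 1,
                                     voxel_mm = 2, connectivity = 26,
                                     two_sided = TRUE, df = NULL) {
  stopifnot(height_p > 0, height_p < 1, alpha > 0, alpha <= 1)
  if (n_sim < 1000) abort("cluster_extent_threshold: n_sim >= 1000 required")
  if (alpha < 1 / n_sim) {
    abort(paste0("cluster_extent_threshold: alpha = ", alpha,
                 " is unreachable with n_sim = ", n_sim,
                 "; increase n_sim"))
  }
  fwhm <- mean(fwhm_mm)
  dims <- dim(mask)
  thr_val <- if (is.null(df)) {
    if (two_sided) qnorm(1 - height_p / 2) else qnorm(1 - height_p)
  } else {
    if (two_sided) qt(1 - height_p / 2, df) else qt(1 - height_p, df)
  }
  zthr <- thr_val
  max_sizes <- integer(n_sim)
  with_seed_(seed, {
    for (s in seq_len(n_sim)) {
      if (is.null(df)) {
        f <- array(rnorm(prod(dims)), dim = dims)
        if (fwhm > 0) f <- gaussian_smooth_3d(f, fwhm, voxel_mm)
        v <- f[mask]
        f <- (f - mean(v)) / sd(v)
      } else {
        # one-sample t field: df + 1 smoothed noise fields
        m <- df + 1L
        flds <- matrix(rnorm(prod(dims) * m), ncol = m)
        if (fwhm > 0) {
          for (k in seq_len(m)) {
            flds[, k] <- as.vector(gaussian_smooth_3d(
              array(flds[, k], dims), fwhm, voxel_mm))
          }
        }
        mu <- rowMeans(flds)
        sdv <- sqrt((rowSums(flds^2) - m * mu^2) / (m - 1))
        f <- array(mu / (sdv / sqrt(m)), dims)
      }
      biggest <- 0L
      supra_pos <- array(f > zthr & mask, dims)
      if (any(supra_pos)) {
        lab <- .label_components(supra_pos, dims, connectivity)
        biggest <- max(tabulate(lab[lab > 0]))
      }
      if (two_sided) {
        supra_neg <- array(f < -zthr & mask, dims)
        if (any(supra_neg)) {
          lab <- .label_components(supra_neg, dims, connectivity)
          biggest <- max(biggest, max(tabulate(lab[lab > 0])))
        }
      }
      max_sizes[s] <- biggest
    }
  })
  k_grid <- seq_len(max(max_sizes) + 1L)
  exceed <- vapply(k_grid, function(k) mean(max_sizes >= k), numeric(1))
  k_min <- k_grid[which(exceed <= alpha)[1]]
  structure(list(k_min = k_min, max_sizes = max_sizes, fwhm_mm = fwhm,
                 height_p = height_p, alpha = alpha, n_sim = n_sim,
                 seed = seed, connectivity = connectivity,
                 two_sided = two_sided, df = df, n_mask = sum(mask)),
            class = "cluster_threshold")
}

#' @export
print.cluster_threshold <- function(x, ...) {
  cat("<cluster_threshold> k_min = ", x$k_min, " voxels (height p = ",
      x$height_p, ", alpha = ", x$alpha, ", fwhm = ",
      round(x$fwhm_mm, 2), " mm, ", x$n_sim, " simulations)\n", sep = "")
  invisible(x)
}

#' Extract suprathreshold clusters from a t map
#'
#' Thresholds the t map at the voxelwise height threshold (both signs when
#' `two_sided = TRUE`), labels connected components within each sign, and
#' marks clusters at least `k_min` voxels large as surviving family-wise
#' correction.
#'
#' @param t_map A [stat_map()] of kind `"t"` or a 3-D array.
#' @param df Residual degrees of freedom (defaults to the map's).
#' @param height_p Voxelwise height threshold.
#' @param k_min Cluster extent threshold (voxels), e.g. from
#'   [cluster_extent_threshold()].
#' @param connectivity 6, 18 or 26.
#' @param two_sided Threshold `|t|`.
#' @param return_masks Attach a list of per-cluster voxel masks as the
#'   `"masks"` attribute of the result.
#' @return A tibble with one row per cluster: `cluster`, `direction`
#'   (`"A>B"`/`"B>A"`), `size`, `peak_x`, `peak_y`, `peak_z`, `peak_t`,
#'   `survives_fwe`; empty when nothing is suprathreshold.
#' @export
extract_clusters <- function(t_map, df = NULL, height_p = 0.01, k_min = 1,
                             connectivity = 26, two_sided = TRUE,
                             return_masks = FALSE) {
  vals <- map_values(t_map)
  df <- df %||% (if (inherits(t_map, "stat_map")) t_map$df else NULL)
  if (is.null(df)) abort("extract_clusters: df required")
  dims <- dim(vals)
  tthr <- if (two_sided) qt(1 - height_p / 2, df) else qt(1 - height_p, df)
  out <- list(); masks <- list()
  dirs <- if (two_sided) c("A>B", "B>A") else "A>B"
  for (dir in dirs) {
    supra <- if (dir == "A>B") vals > tthr else vals < -tthr
    supra[is.na(supra)] <- FALSE
    if (!any(supra)) next
    lab <- .label_components(supra, dims, connectivity)
    for (cl in seq_len(max(lab))) {
      idx <- which(lab == cl)
      tv <- vals[idx]
      peak_lin <- idx[which.max(abs(tv))]
      pk <- arrayInd(peak_lin, dims)
      out[[length(out) + 1]] <- tibble(
        direction = dir, size = length(idx),
        peak_x = pk[1], peak_y = pk[2], peak_z = pk[3],
        peak_t = vals[peak_lin], survives_fwe = length(idx) >= k_min)
      if (return_masks) masks[[length(masks) + 1]] <- array(lab == cl, dims)
    }
  }
  if (length(out) == 0) {
    res <- tibble(cluster = integer(0), direction = character(0),
                  size = integer(0), peak_x = integer(0), peak_y = integer(0),
                  peak_z = integer(0), peak_t = numeric(0),
                  survives_fwe = logical(0))
    if (return_masks) attr(res, "masks") <- list()
    return(res)
  }
  res <- bind_rows(out)
  ord <- order(res$size, decreasing = TRUE)
  res <- res[ord, ]
  res$cluster <- seq_len(nrow(res))
  res <- dplyr::relocate(res, "cluster")
  if (return_masks) attr(res, "masks") <- masks[ord]
  res
}

# voxel mask of surviving clusters (union over directions)
cluster_mask <- function(t_map, df = NULL, height_p = 0.01, k_min = 1,
                         connectivity = 26, two_sided = TRUE) {
  vals <- map_values(t_map)
  df <- df %||% (if (inherits(t_map, "stat_map")) t_map$df else NULL)
  dims <- dim(vals)
  tthr <- if (two_sided) qt(1 - height_p / 2, df) else qt(1 - height_p, df)
  keep <- array(FALSE, dims)
  for (sgn in if (two_sided) c(1, -1) else 1) {
    supra <- if (sgn > 0) vals > tthr else vals < -tthr
    supra[is.na(supra)] <- FALSE
    if (!any(supra)) next
    lab <- .label_components(supra, dims, connectivity)
    sizes <- tabulate(lab[lab > 0])
    big <- which(sizes >= k_min)
    keep <- keep | array(lab %in% big & lab > 0, dims)
  }
  keep
}

best_model_string <- "
model {
  for (i in 1:Na) { ya[i] ~ dt(mu[1], tau[1], nu) }
  for (i in 1:Nb) { yb[i] ~ dt(mu[2], tau[2], nu) }
  for (g in 1:2) {
    mu[g] ~ dnorm(mu0, 1 / (1000 * sd0^2))
    sigma[g] ~ dunif(sd0 / 1000, sd0 * 1000)
    tau[g] <- 1 / pow(sigma[g], 2)
  }
  nu <- nuMinusOne + 1
  nuMinusOne ~ dexp(1 / 29)
}"

#' Bayesian two-group estimation of a mean difference
#'
#' Robust Bayesian estimation of the difference between two group means:
#' each group is modelled with a Student-t likelihood sharing a normality
#' parameter (shifted-exponential prior, mean 30), broad normal priors on
#' the means scaled to the pooled data, and broad uniform priors on the
#' group standard deviations. Sampled with JAGS.
#'
#' @param a,b Numeric vectors (>= 3 values each).
#' @param seed Integer seed for the MCMC.
#' @param n_chains,n_adapt,n_burn,n_iter MCMC settings (total retained
#'   samples = `n_chains * n_iter`).
#' @param hdi_prob Probability mass of the highest-density interval.
#' @return Object of class `posterior_summary`: `mean_diff`, `hdi_lower`,
#'   `hdi_upper`, `ess`, `psrf`, `converged`, `n_samples` and the
#'   posterior `samples` of the difference.
#' @export
bayes_group_diff <- function(a, b, seed = 1, n_chains = 3, n_adapt = 500,
                             n_burn = 500, n_iter = 2000, hdi_prob = 0.95) {
  if (length(a) < 3 || length(b) < 3) {
    abort("bayes_group_diff: >= 3 values per group required")
  }
  pooled <- c(a, b)
  sd0 <- sd(pooled)
  if (sd0 == 0) abort("bayes_group_diff: pooled data have zero variance")
  data_list <- list(ya = a, yb = b, Na = length(a), Nb = length(b),
                    mu0 = mean(pooled), sd0 = sd0)
  inits <- lapply(seq_len(n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = substream_seed(seed, paste0("chain", ch)))
  })
  jm <- rjags::jags.model(textConnection(best_model_string), data = data_list,
                          inits = inits, n.chains = n_chains,
                          n.adapt = n_adapt, quiet = TRUE)
  stats::update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("mu"), n.iter = n_iter,
                              progress.bar = "none")
  diffs <- lapply(samp, function(ch) as.numeric(ch[, "mu[1]"] - ch[, "mu[2]"]))
  diff_mcmc <- coda::as.mcmc.list(lapply(diffs, coda::mcmc))
  all_diff <- unlist(diffs)
  hdi <- coda::HPDinterval(coda::mcmc(all_diff), prob = hdi_prob)
  ess <- sum(coda::effectiveSize(diff_mcmc))
  psrf <- tryCatch(coda::gelman.diag(diff_mcmc, autoburnin = FALSE)$psrf[1, 1],
                   error = function(e) NA_real_)
  structure(list(mean_diff = mean(all_diff),
                 hdi_lower = unname(hdi[1, "lower"]),
                 hdi_upper = unname(hdi[1, "upper"]),
                 hdi_prob = hdi_prob, ess = unname(ess), psrf = psrf,
                 converged = is.finite(psrf) && psrf < 1.1,
                 n_samples = length(all_diff), samples = all_diff),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary> mean difference ", signif(x$mean_diff, 4),
      ", ", 100 * x$hdi_prob, "% HDI [", signif(x$hdi_lower, 4), ", ",
      signif(x$hdi_upper, 4), "], ESS ", round(x$ess),
      if (!x$converged) " (NOT CONVERGED)", "\n", sep = "")
  invisible(x)
}
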