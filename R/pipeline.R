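#' Read / validate a cohort manifest
#'
#' The manifest registers one row per subject, session (and optionally
#' run) with group labels, behavioural scores and map paths. Unknown
#' columns are preserved.
#'
#' @param path CSV path.
#' @param require_accuracy Error when the `accuracy` column is absent.
#' @return A validated tibble.
#' @export
read_manifest <- function(path, require_accuracy = TRUE) {
  m <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("subject_id", "group", "session")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0) {
    abort(paste0("read_manifest: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (require_accuracy && !"accuracy" %in% names(m)) {
    abort("read_manifest: missing `accuracy` column")
  }
  bad_group <- setdiff(unique(m$group), c("MLD", "TD"))
  if (length(bad_group) > 0) {
    abort(paste0("read_manifest: unknown group label(s): ",
                 paste(bad_group, collapse = ", ")))
  }
  key_cols <- intersect(c("subject_id", "session", "run"), names(m))
  key <- do.call(paste, c(m[key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    abort("read_manifest: duplicate (subject, session, run) entries")
  }
  m
}

#' @rdname read_manifest
#' @param manifest Manifest tibble (list columns are dropped on write).
#' @export
write_manifest <- function(manifest, path) {
  flat <- manifest[, !vapply(manifest, is.list, logical(1)), drop = FALSE]
  write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

# write a cohort's files: NIfTI maps, TSV events, CSV manifest, JSON truth
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  if (cohort$mode == "maps") {
    paths <- character(nrow(man))
    for (i in seq_len(nrow(man))) {
      paths[i] <- file.path(dir, paste0(man$subject_id[i], "_",
                                        man$session[i], "_t.nii.gz"))
      write_stat_map(man$map[[i]], paths[i], cohort$config$voxel_mm)
    }
    man$path <- paths
  }
  ev <- cohort$events
  for (i in seq_len(nrow(ev))) {
    f <- file.path(dir, paste0(ev$subject_id[i], "_", ev$session[i], "_run",
                               ev$run[i], "_events.tsv"))
    utils::write.table(ev$events[[i]], f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  gt <- cohort$ground_truth
  gt$amplitude_pre <- lapply(gt$amplitude_pre, identity)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Run the full normalization-analysis pipeline on a synthetic cohort
#'
#' Executes the study stages in dependency order: cohort simulation,
#' (in BOLD mode) despiking, QC gating and GLM contrast estimation,
#' behavioural statistics, voxelwise pre-tutoring group inference with
#' Monte-Carlo cluster-extent correction, pattern classification of
#' MLD vs TD at each session within the pre-tutoring group-difference
#' mask, Bayesian estimation of post-tutoring group differences on
#' cluster-mean values, and the BPI-gain correlation. Every stochastic
#' stage derives its seed from the configuration seed, so rerunning with
#' the same configuration reproduces all numbers exactly.
#'
#' @param config A [sim_config()].
#' @param mode `"maps"` (fast) or `"bold"` (full time-series).
#' @param n_perm Label permutations for the classifier null.
#' @param n_sim Monte-Carlo simulations for the cluster-extent threshold
#'   (simulated as Student-t fields at the group-analysis degrees of
#'   freedom, so cluster-level error control holds at low df).
#' @param height_p Voxelwise height threshold.
#' @param cluster_alpha Cluster-level family-wise error rate.
#' @param connectivity Cluster connectivity (6, 18 or 26).
#' @param out_dir Optional directory for the JSON report (and cohort
#'   files).
#' @return Object of class `plastimap_report`.
#' @export
run_pipeline <- function(config = sim_config(), mode = c("maps", "bold"),
                         n_perm = 10000, n_sim = 2000, height_p = 0.01,
                         cluster_alpha = 0.01, connectivity = 26,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  t0 <- Sys.time()
  cohort <- generate_cohort(config, mode = mode)
  qc <- NULL
  if (mode == "bold") {
    cohort <- glm_stage(cohort)
    qc <- cohort$qc
  }
  man <- cohort$manifest
  beh <- behavior_stats(man)

  # pre-tutoring group inference -> group-difference mask
  pre_mld <- man$map[man$group == "MLD" & man$session == "pre"]
  pre_td <- man$map[man$group == "TD" & man$session == "pre"]
  tmap_pre <- voxelwise_test(pre_mld, pre_td, design = "independent",
                             mask = cohort$mask)
  fwhm <- estimate_smoothness(attr(tmap_pre, "residuals"), cohort$mask,
                              config$voxel_mm)
  kernel <- match_smoothing_kernel(mean(fwhm), cohort$mask, config$voxel_mm,
                                   seed = substream_seed(config$seed, "kmatch"))
  thr <- cluster_extent_threshold(cohort$mask, kernel, height_p,
                                  cluster_alpha, n_sim = n_sim,
                                  seed = substream_seed(config$seed, "mc_null"),
                                  voxel_mm = config$voxel_mm,
                                  connectivity = connectivity,
                                  df = tmap_pre$df)
  clusters <- extract_clusters(tmap_pre, height_p = height_p,
                               k_min = thr$k_min, connectivity = connectivity,
                               return_masks = TRUE)
  cl_masks <- attr(clusters, "masks")
  mask_gd <- cluster_mask(tmap_pre, height_p = height_p, k_min = thr$k_min,
                          connectivity = connectivity)
  if (!any(mask_gd)) {
    abort(paste0("run_pipeline: no pre-tutoring group-difference cluster ",
                 "survived correction; downstream pattern stages need a ",
                 "non-empty mask"))
  }

  mvpa <- list()
  for (session in c("pre", "post")) {
    sess <- man[man$session == session, ]
    feats <- feature_matrix(sess$map, mask_gd)
    mvpa[[session]] <- permutation_test(
      feats, sess$group, n_perm = n_perm,
      seed = substream_seed(config$seed, paste0("mvpa_", session)))
  }

  # Bayesian estimation on post-tutoring cluster means (largest clusters)
  surv_idx <- which(clusters$survives_fwe)
  bayes <- list()
  post <- man[man$session == "post", ]
  for (ci in head(surv_idx, 3)) {
    cmask <- cl_masks[[ci]]
    vals <- vapply(post$map, function(m) mean(map_values(m)[cmask]),
                   numeric(1))
    bayes[[paste0("cluster", clusters$cluster[ci])]] <- bayes_group_diff(
      vals[post$group == "MLD"], vals[post$group == "TD"],
      seed = substream_seed(config$seed, paste0("bayes", ci)))
  }

  records <- bpi_records(man, mask_gd, group = "MLD")
  bpi_cor <- relate_bpi_to_gain(records)

  report <- structure(list(
    config = config, mode = mode, behavior = beh, qc = qc,
    group_t_map = tmap_pre, smoothness_fwhm_mm = fwhm,
    cluster_threshold = thr, clusters = clusters, mask = mask_gd,
    mvpa = mvpa, bayes_post = bayes, bpi = records, bpi_gain = bpi_cor,
    seed = config$seed, elapsed_s = as.numeric(Sys.time() - t0, units = "secs")
  ), class = "plastimap_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# bold-mode stage: despike + QC + GLM + run-averaged t maps
glm_stage <- function(cohort) {
  man <- cohort$manifest
  cfg <- cohort$config
  qc_rows <- list()
  maps <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    runs <- man$runs[[i]]
    ev <- cohort$events[cohort$events$subject_id == man$subject_id[i] &
                          cohort$events$session == man$session[i], ]
    cons <- list()
    for (r in seq_along(runs)) {
      ds <- despike(runs[[r]])
      qc_rows[[length(qc_rows) + 1]] <- tibble(
        subject_id = man$subject_id[i], session = man$session[i], run = r,
        n_volumes = ds$report$n_volumes,
        n_repaired = length(ds$report$flagged))
      # empty incorrect-trial sub-conditions are routine at high accuracy
      design <- suppressWarnings(
        build_design(ev$events[ev$run == r][[1]],
                     n_volumes = dim(runs[[r]]$data)[4],
                     tr = cfg$tr_seconds))
      fit <- fit_glm(ds$run, design)
      cons[[r]] <- contrast_map(fit, subject = man$subject_id[i],
                                group = man$group[i],
                                session = man$session[i], run = r)
    }
    maps[[i]] <- average_runs(cons)$t
  }
  man$map <- maps
  man$runs <- NULL
  cohort$manifest <- man
  cohort$qc <- bind_rows(qc_rows)
  cohort
}

# serialise the report's numeric content to JSON (deterministic)
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  glances <- lapply(report$mvpa, function(m) {
    list(accuracy = m$accuracy, p = m$p, n_perm = m$n_perm)
  })
  payload <- list(
    seed = report$seed, mode = report$mode,
    behavior = report$behavior,
    smoothness_fwhm_mm = as.list(report$smoothness_fwhm_mm),
    k_min = report$cluster_threshold$k_min,
    clusters = report$clusters,
    mvpa = glances,
    bayes_post = lapply(report$bayes_post, function(b) {
      list(mean_diff = b$mean_diff, hdi = c(b$hdi_lower, b$hdi_upper))
    }),
    bpi = report$bpi,
    bpi_gain = report$bpi_gain)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @export
print.plastimap_report <- function(x, ...) {
  cat("== plastimap pipeline report (seed ", x$seed, ", mode ", x$mode,
      ") ==\n", sep = "")
  acc <- x$behavior[x$behavior$measure == "accuracy", ]
  gain <- acc[acc$comparison == "MLD post vs pre", ]
  cat(sprintf("MLD accuracy gain: t(%d) = %.3f, p = %.4g, d = %.2f\n",
              gain$df, gain$t, gain$p, gain$d))
  cat(sprintf("Pre-tutoring clusters surviving FWE: %d (k_min = %d)\n",
              sum(x$clusters$survives_fwe), x$cluster_threshold$k_min))
  for (s in names(x$mvpa)) {
    m <- x$mvpa[[s]]
    cat(sprintf("MVPA %s: accuracy %.2f%%, permutation p = %.4g\n",
                s, 100 * m$accuracy, m$p))
  }
  cat(sprintf("BPI-gain correlation: r = %.3f, p = %.4g (n = %d)\n",
              x$bpi_gain$r, x$bpi_gain$p, x$bpi_gain$n))
  invisible(x)
}
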