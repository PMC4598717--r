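#' Scan-to-scan head displacement
#'
#' Combines the frame-to-frame change in the three translations (mm) and
#' three rotations (degrees, converted to arc length on a 65 mm-radius
#' sphere, the common head-size convention) into a single Euclidean
#' displacement per volume. The first volume's displacement is 0.
#'
#' @param trace Data frame with columns `x`, `y`, `z` (mm) and `pitch`,
#'   `roll`, `yaw` (degrees), one row per volume.
#' @param radius_mm Sphere radius for the rotation-to-arc conversion.
#' @param per_axis If `TRUE`, return the maximum absolute per-axis change
#'   instead of the combined Euclidean norm.
#' @return Numeric vector of displacements (mm), one per volume.
#' @export
#' @examples
#' tr <- tibble::tibble(x = c(0, 1.6, 1.6), y = 0, z = 0,
#'                      pitch = 0, roll = 0, yaw = 0)
#' displacement(tr)
displacement <- function(trace, radius_mm = 65, per_axis = FALSE) {
  need <- c("x", "y", "z", "pitch", "roll", "yaw")
  missing <- setdiff(need, names(trace))
  if (length(missing) > 0) {
    abort(paste0("displacement: trace lacks ", paste(missing, collapse = ", ")))
  }
  lens <- vapply(need, function(f) length(trace[[f]]), numeric(1))
  if (length(unique(lens)) != 1) {
    abort("displacement: trace fields have unequal lengths")
  }
  if (nrow(trace) < 2) abort("displacement: at least two volumes required")
  if (!all(vapply(need, function(f) all(is.finite(trace[[f]])), logical(1)))) {
    abort("displacement: non-finite values in motion trace")
  }
  m <- cbind(trace$x, trace$y, trace$z,
             radius_mm * pi / 180 * cbind(trace$pitch, trace$roll, trace$yaw))
  d <- apply(abs(diff(m)), 1, if (per_axis) max else function(v) sqrt(sum(v^2)))
  c(0, d)
}

#' Repair motion- and signal-spike volumes
#'
#' Implements the volume-repair rule: volumes whose scan-to-scan
#' displacement exceeds 0.5 voxels (1.562 mm at the study resolution) or
#' whose global in-mask signal deviates from the run baseline by more than
#' 5% are replaced by linear interpolation between the nearest unflagged
#' neighbours (edge volumes copy the nearest unflagged volume). Unflagged
#' volumes are never modified, so the repair is idempotent.
#'
#' @param run A [simulate_bold()] `bold_run`, or a 4-D array.
#' @param trace Motion trace; defaults to `run$motion`.
#' @param mask Brain mask; defaults to `run$mask`.
#' @param displacement_mm Displacement threshold in mm.
#' @param global_frac Global-signal deviation threshold (fraction).
#' @param baseline `"median"` (run median, default) or `"previous"`
#'   (previous volume) as the 5% reference.
#' @param per_axis Use per-axis instead of combined displacement.
#' @return List with `run` (repaired, same class as input) and `report`, a
#'   list of class `qc_report`: per-volume `displacement`, `flagged`
#'   indices, `flag_reason`, `repaired_fraction` and `n_volumes`.
#' @export
despike <- function(run, trace = NULL, mask = NULL,
                    displacement_mm = 1.562, global_frac = 0.05,
                    baseline = c("median", "previous"), per_axis = FALSE) {
  baseline <- match.arg(baseline)
  if (inherits(run, "bold_run")) {
    trace <- trace %||% run$motion
    mask <- mask %||% run$mask
    data <- run$data
  } else {
    data <- run
    if (is.null(trace)) abort("despike: motion trace required for array input")
    if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  }
  nv <- dim(data)[4]
  if (nrow(trace) != nv) abort("despike: trace and run are not aligned")

  disp <- displacement(trace, per_axis = per_axis)
  flat <- matrix(data, ncol = nv)
  gs <- colMeans(flat[as.vector(mask), , drop = FALSE])
  ref <- if (baseline == "median") rep(median(gs), nv) else c(gs[1], gs[-nv])
  gs_dev <- abs(gs - ref) / abs(ref)

  flag_disp <- disp > displacement_mm
  flag_gs <- gs_dev > global_frac
  flagged <- which(flag_disp | flag_gs)
  if (length(flagged) == nv) {
    abort("despike: all volumes flagged; run is unrecoverable")
  }

  good <- setdiff(seq_len(nv), flagged)
  for (v in flagged) {
    before <- good[good < v]
    after <- good[good > v]
    if (length(before) == 0) {
      flat[, v] <- flat[, min(after)]
    } else if (length(after) == 0) {
      flat[, v] <- flat[, max(before)]
    } else {
      b <- max(before); a <- min(after)
      w <- (v - b) / (a - b)
      flat[, v] <- (1 - w) * flat[, b] + w * flat[, a]
    }
  }
  repaired <- array(flat, dim = dim(data))

  report <- structure(list(
    displacement = disp, global_signal = gs,
    flagged = flagged,
    flag_reason = tibble(
      volume = flagged,
      motion = flag_disp[flagged],
      global_signal = flag_gs[flagged]),
    repaired_fraction = length(flagged) / nv,
    n_volumes = nv), class = "qc_report")

  if (inherits(run, "bold_run")) {
    run$data <- repaired
    list(run = run, report = report)
  } else {
    list(run = repaired, report = report)
  }
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$n_volumes, " volumes, ", length(x$flagged),
      " flagged (", round(100 * x$repaired_fraction, 1), "%)\n", sep = "")
  invisible(x)
}

#' Apply the study inclusion criteria
#'
#' Excludes subjects whose total interpolated-frame fraction reaches 20%
#' or whose in-scanner accuracy is not strictly above 50%, reporting the
#' reason for each exclusion.
#'
#' @param qc Tibble with columns `subject_id`, `n_volumes`, `n_repaired`
#'   (one row per run; rows are pooled within subject).
#' @param behavior Tibble with columns `subject_id` and `accuracy` (rows
#'   pooled by minimum within subject).
#' @param max_frame_fraction Exclusion boundary for interpolated frames
#'   (excluded when the pooled fraction is `>=` this value).
#' @param min_accuracy Accuracy must be strictly greater than this value.
#' @return Tibble: `subject_id`, `frame_fraction`, `accuracy`, `include`,
#'   `reason` (`NA` when included).
#' @export
qc_gate <- function(qc, behavior, max_frame_fraction = 0.20,
                    min_accuracy = 0.50) {
  need_qc <- c("subject_id", "n_volumes", "n_repaired")
  if (length(setdiff(need_qc, names(qc))) > 0) {
    abort("qc_gate: qc needs subject_id, n_volumes, n_repaired")
  }
  if (length(setdiff(c("subject_id", "accuracy"), names(behavior))) > 0) {
    abort("qc_gate: behavior needs subject_id, accuracy")
  }
  subjects <- unique(c(qc$subject_id, behavior$subject_id))
  miss_qc <- setdiff(subjects, qc$subject_id)
  miss_beh <- setdiff(subjects, behavior$subject_id)
  if (length(miss_qc) > 0 || length(miss_beh) > 0) {
    abort(paste0("qc_gate: missing QC or behaviour for subject(s): ",
                 paste(c(miss_qc, miss_beh), collapse = ", ")))
  }
  qcs <- qc |>
    group_by(.data$subject_id) |>
    summarise(frame_fraction = sum(.data$n_repaired) / sum(.data$n_volumes))
  beh <- behavior |>
    group_by(.data$subject_id) |>
    summarise(accuracy = min(.data$accuracy))
  out <- left_join(qcs, beh, by = "subject_id")
  out$motion_fail <- out$frame_fraction >= max_frame_fraction
  out$accuracy_fail <- !(out$accuracy > min_accuracy)
  out$include <- !(out$motion_fail | out$accuracy_fail)
  out$reason <- ifelse(
    out$include, NA_character_,
    paste0(ifelse(out$motion_fail, ">=20% frames interpolated", ""),
           ifelse(out$motion_fail & out$accuracy_fail, "; ", ""),
           ifelse(out$accuracy_fail, "accuracy <= 50%", "")))
  select(out, "subject_id", "frame_fraction", "accuracy", "include", "reason")
}
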