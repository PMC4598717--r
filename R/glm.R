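#' Build an event-related design matrix
#'
#' Each modelled sub-condition (Addition/Control crossed with
#' correct/incorrect) contributes a boxcar of the trial-window length at
#' each onset convolved with the canonical HRF, plus a temporal-derivative
#' column (orthogonalised to its HRF column) to absorb voxelwise latency
#' differences. Rest periods are not modelled. Discrete-cosine drift
#' regressors (128 s cutoff) and an intercept are appended. Empty
#' sub-conditions are omitted with a warning; contrasts referencing them
#' fail at the contrast stage.
#'
#' @param events Event table with `onset`, `duration`, `trial_type`,
#'   `correct`.
#' @param n_volumes Number of volumes in the run.
#' @param tr Repetition time (s).
#' @param drift_cutoff_s High-pass drift cutoff in seconds.
#' @param derivative Include temporal-derivative columns.
#' @return Object of class `design_matrix`: `X` (volumes x regressors),
#'   `names`, `condition_columns` (map from sub-condition to HRF column),
#'   `tr`, `rank`.
#' @export
#' @examples
#' ev <- generate_design(sim_config(), 0.8, seed = 1)
#' des <- build_design(ev, n_volumes = 150, tr = 2)
#' dim(des$X)
build_design <- function(events, n_volumes, tr, drift_cutoff_s = 128,
                         derivative = TRUE) {
  run_len <- n_volumes * tr
  if (nrow(events) > 0 && any(events$onset + events$duration > run_len)) {
    abort("build_design: event extends past the end of the run")
  }
  subconds <- c(addition_correct = NA, control_correct = NA,
                addition_incorrect = NA, control_incorrect = NA)
  cols <- list(); nm <- character(0); cond_cols <- list()
  for (ttype in c("addition", "control")) {
    for (corr in c(TRUE, FALSE)) {
      label <- paste0(ttype, "_", if (corr) "correct" else "incorrect")
      ev <- events[events$trial_type == ttype & events$correct == corr, ,
                   drop = FALSE]
      if (nrow(ev) == 0) {
        warn(paste0("build_design: no events for sub-condition `", label,
                    "`; column omitted"))
        next
      }
      h <- convolve_events(ev$onset, ev$duration, n_volumes, tr,
                           kernel = canonical_hrf)
      cols[[length(cols) + 1]] <- h
      nm <- c(nm, label)
      cond_cols[[label]] <- length(cols)
      if (derivative) {
        d <- convolve_events(ev$onset, ev$duration, n_volumes, tr,
                             kernel = hrf_derivative)
        # orthogonalise the derivative to its HRF column
        d <- d - h * sum(d * h) / sum(h * h)
        cols[[length(cols) + 1]] <- d
        nm <- c(nm, paste0(label, "_deriv"))
      }
    }
  }
  # discrete cosine drift basis, SPM convention
  n_drift <- max(0, floor(2 * run_len / drift_cutoff_s))
  t_idx <- seq_len(n_volumes) - 0.5
  for (k in seq_len(n_drift)) {
    cols[[length(cols) + 1]] <- cos(pi * k * t_idx / n_volumes)
    nm <- c(nm, paste0("drift", k))
  }
  cols[[length(cols) + 1]] <- rep(1, n_volumes)
  nm <- c(nm, "intercept")

  X <- do.call(cbind, cols)
  colnames(X) <- nm
  r <- qr(X)$rank
  structure(list(X = X, names = nm, condition_columns = cond_cols,
                 tr = tr, rank = r, n_volumes = n_volumes),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", x$n_volumes, " volumes x ", ncol(x$X),
      " regressors (rank ", x$rank, "), TR ", x$tr, " s\n",
      "  sub-conditions: ", paste(names(x$condition_columns), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Fit the voxelwise GLM
#'
#' Ordinary least squares per voxel. Residual degrees of freedom are
#' `n_volumes - rank(X)`.
#'
#' @param run A `bold_run` or 4-D array.
#' @param design A [build_design()] result.
#' @param mask Brain mask (defaults to the run's).
#' @return Object of class `glm_fit`: `betas` (regressors x voxels),
#'   `sigma2`, `df`, `XtXinv`, `design`, `mask`, `dims`, plus residual
#'   maps access via `residuals = TRUE` refits.
#' @export
fit_glm <- function(run, design, mask = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  if (inherits(run, "bold_run")) {
    mask <- mask %||% run$mask
    data <- run$data
  } else {
    data <- run
    if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  }
  X <- design$X
  if (design$rank < ncol(X)) {
    qx <- qr(X)
    bad <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    abort(paste0("fit_glm: design is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  nv <- dim(data)[4]
  if (nv != nrow(X)) abort("fit_glm: run length does not match design")
  Y <- matrix(data, ncol = nv)[as.vector(mask), , drop = FALSE]
  Y <- t(Y) # volumes x voxels
  qx <- qr(X)
  betas <- qr.coef(qx, Y)
  res <- Y - X %*% betas
  df <- nv - design$rank
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  structure(list(betas = betas, sigma2 = sigma2, df = df, XtXinv = XtXinv,
                 design = design, mask = mask, dims = dim(data)[1:3],
                 residuals = res),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> ", ncol(x$betas), " voxels, ", nrow(x$betas),
      " regressors, residual df ", x$df, "\n", sep = "")
  invisible(x)
}

# embed an in-mask vector into a 3-D array (NA outside)
embed_in_mask <- function(values, mask) {
  out <- array(NA_real_, dim = dim(mask))
  out[mask] <- values
  out
}

#' Contrast and t maps from a GLM fit
#'
#' The contrast is a named weight vector over HRF sub-condition columns
#' (derivative columns are excluded); the default is Addition-correct
#' minus Control-correct. Voxels with zero residual variance yield an
#' undefined t and are masked out with a count reported as an attribute.
#'
#' @param fit A [fit_glm()] result.
#' @param contrast Named numeric vector of weights over sub-condition
#'   names.
#' @param subject,group,session,run Provenance for the output maps.
#' @return List of class `contrast_result`: `contrast` and `t`
#'   ([stat_map()]s), `variance` (3-D array), `df`,
#'   `n_undefined` (zero-residual-variance voxels).
#' @export
contrast_map <- function(fit, contrast = c(addition_correct = 1,
                                           control_correct = -1),
                         subject = NA, group = NA, session = NA, run = NA) {
  stopifnot(inherits(fit, "glm_fit"))
  cond_cols <- fit$design$condition_columns
  missing <- setdiff(names(contrast), names(cond_cols))
  if (length(missing) > 0) {
    abort(paste0("contrast_map: contrast references unavailable ",
                 "sub-condition(s): ", paste(missing, collapse = ", "),
                 " (empty or not modelled)"))
  }
  w <- numeric(ncol(fit$design$X))
  for (nmc in names(contrast)) w[cond_cols[[nmc]]] <- contrast[[nmc]]
  con <- drop(t(w) %*% fit$betas)
  cvc <- drop(t(w) %*% fit$XtXinv %*% w)
  v <- fit$sigma2 * cvc
  tval <- ifelse(v > 0, con / sqrt(v), NA_real_)
  n_undef <- sum(v <= 0)
  structure(list(
    contrast = stat_map(embed_in_mask(con, fit$mask), "contrast", subject,
                        group, session, run),
    t = stat_map(embed_in_mask(tval, fit$mask), "t", subject, group,
                 session, run, df = fit$df),
    variance = embed_in_mask(v, fit$mask),
    df = fit$df, n_undefined = n_undef), class = "contrast_result")
}

#' Combine per-run contrast results across runs
#'
#' The default averages the runs' contrast maps and recomputes the t map
#' by fixed-effects combination (summed contrasts over the square root of
#' summed variances); `method = "t"` instead averages the per-run t maps
#' directly.
#'
#' @param results List of [contrast_map()] results for the same subject.
#' @param method `"contrast"` (default) or `"t"`.
#' @return A `contrast_result` with the combined maps (`df` summed).
#' @export
average_runs <- function(results, method = c("contrast", "t")) {
  method <- match.arg(method)
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "contrast_result")))
  if (length(results) == 1) return(results[[1]])
  n <- length(results)
  con <- Reduce(`+`, lapply(results, function(r) r$contrast$values)) / n
  v <- Reduce(`+`, lapply(results, function(r) r$variance)) / n^2
  df <- sum(vapply(results, function(r) r$df, numeric(1)))
  if (method == "contrast") {
    tvals <- ifelse(v > 0, con / sqrt(v), NA_real_)
  } else {
    tvals <- Reduce(`+`, lapply(results, function(r) r$t$values)) / n
  }
  proto <- results[[1]]$contrast
  structure(list(
    contrast = stat_map(con, "contrast", proto$subject, proto$group,
                        proto$session, NA_integer_),
    t = stat_map(tvals, "t", proto$subject, proto$group, proto$session,
                 NA_integer_, df = df),
    variance = v, df = df,
    n_undefined = sum(v <= 0, na.rm = TRUE)), class = "contrast_result")
}
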