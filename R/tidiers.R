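#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a classification result
#'
#' @param x A `classification_result`.
#' @param ... Unused.
#' @return Fold-level tibble: `fold`, `truth`, `predicted`, `correct`.
#' @export
tidy.classification_result <- function(x, ...) {
  mutate(x$folds, correct = .data$truth == .data$predicted)
}

#' @rdname tidy.classification_result
#' @return For `glance`: a one-row tibble with `accuracy`, `p`, `n`,
#'   `n_perm`, `cost`.
#' @export
glance.classification_result <- function(x, ...) {
  tibble(accuracy = x$accuracy, p = x$p %||% NA_real_, n = nrow(x$folds),
         n_perm = x$n_perm %||% NA_integer_, cost = x$cost)
}

#' Tidy a Bayesian group-difference posterior
#'
#' @param x A `posterior_summary`.
#' @param ... Unused.
#' @return For `tidy`: posterior draws of the mean difference; for
#'   `glance`: a one-row summary.
#' @export
tidy.posterior_summary <- function(x, ...) {
  tibble(draw = seq_along(x$samples), mean_diff = x$samples)
}

#' @rdname tidy.posterior_summary
#' @export
glance.posterior_summary <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, hdi_lower = x$hdi_lower,
         hdi_upper = x$hdi_upper, hdi_prob = x$hdi_prob, ess = x$ess,
         psrf = x$psrf, converged = x$converged)
}

#' Summarise a Monte-Carlo cluster threshold
#'
#' @param x A `cluster_threshold`.
#' @param ... Unused.
#' @return One-row tibble with `k_min` and the simulation parameters.
#' @export
glance.cluster_threshold <- function(x, ...) {
  tibble(k_min = x$k_min, height_p = x$height_p, alpha = x$alpha,
         fwhm_mm = x$fwhm_mm, n_sim = x$n_sim, n_mask = x$n_mask,
         connectivity = x$connectivity, two_sided = x$two_sided)
}
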