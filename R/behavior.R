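#' Score a session's in-scanner behaviour
#'
#' Accuracy is the proportion of correct Addition trials pooled over runs;
#' reaction time is the mean across runs of the per-run median RT of
#' correctly solved Addition trials. A run with no correct Addition trials
#' contributes no RT and is flagged rather than silently scored as zero.
#'
#' @param events A list of per-run event tables (as from
#'   [generate_design()]), or a single event table with a `run` column.
#' @param task Label recorded on the summary.
#' @return A one-row tibble: `accuracy`, `rt` (ms, `NA` if undefined in all
#'   runs), `n_runs`, `rt_undefined_runs`, `task`.
#' @export
#' @examples
#' ev <- list(generate_design(sim_config(), 0.8, seed = 1),
#'            generate_design(sim_config(), 0.8, seed = 2))
#' score_session(ev)
score_session <- function(events, task = "in_scanner_verification") {
  if (is.data.frame(events)) {
    if (!"run" %in% names(events)) {
      events <- list(events)
    } else {
      events <- split(events, events$run)
    }
  }
  if (length(events) < 1) abort("score_session: at least one run required")
  add <- lapply(events, function(e) e[e$trial_type == "addition", , drop = FALSE])
  n_corr <- sum(vapply(add, function(e) sum(e$correct), numeric(1)))
  n_tot <- sum(vapply(add, nrow, numeric(1)))
  accuracy <- if (n_tot > 0) n_corr / n_tot else NA_real_
  run_medians <- vapply(add, function(e) {
    r <- e$rt[e$correct]
    if (length(r) == 0) NA_real_ else median(r)
  }, numeric(1))
  undefined <- sum(is.na(run_medians))
  rt <- if (all(is.na(run_medians))) NA_real_ else mean(run_medians, na.rm = TRUE)
  tibble(accuracy = accuracy, rt = rt, n_runs = length(events),
         rt_undefined_runs = undefined, task = task)
}

#' Two-sided t-test with Cohen's d
#'
#' Computes a standard two-sided t-test (paired, or independent with
#' pooled variance) and converts the t statistic to Cohen's d:
#' `|t| / sqrt(n)` for paired designs and `|t| * sqrt(1/n1 + 1/n2)` for
#' independent designs (the pooled-SD equivalent).
#'
#' @param a,b Numeric samples (for paired designs, matched by position).
#' @param design `"paired"` or `"independent"`.
#' @return A one-row tibble: `t`, `df`, `p`, `d`, `design`, `n1`, `n2`.
#' @export
#' @examples
#' ttest_effect(rnorm(15, 1), rnorm(15), design = "independent")
ttest_effect <- function(a, b, design = c("paired", "independent")) {
  design <- match.arg(design)
  if (length(a) < 2 || length(b) < 2) {
    abort("ttest_effect: each sample needs n >= 2")
  }
  if (design == "paired" && length(a) != length(b)) {
    abort("ttest_effect: paired design requires equal lengths")
  }
  if (design == "paired") {
    diffs <- a - b
    if (sd(diffs) == 0) {
      abort("ttest_effect: zero variance of paired differences; t undefined")
    }
    ht <- t.test(a, b, paired = TRUE)
    n <- length(a)
    d <- abs(unname(ht$statistic)) / sqrt(n)
  } else {
    if (sd(a) == 0 && sd(b) == 0) {
      abort("ttest_effect: both samples have zero variance; t undefined")
    }
    ht <- t.test(a, b, var.equal = TRUE)
    d <- abs(unname(ht$statistic)) * sqrt(1 / length(a) + 1 / length(b))
  }
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, d = d, design = design,
         n1 = length(a), n2 = length(b))
}

#' Convert a printed t statistic to Cohen's d
#'
#' The conversion used for reported effect sizes: `d = |t| / sqrt(n)` for
#' paired designs and `d = |t| * sqrt(1/n1 + 1/n2)` for independent
#' designs.
#'
#' @param t t statistic.
#' @param n Sample size (pairs) for paired designs.
#' @param n1,n2 Group sizes for independent designs.
#' @param design `"paired"` or `"independent"`.
#' @return Cohen's d (non-negative).
#' @export
#' @examples
#' cohen_d_from_t(3.323, n = 15, design = "paired")
cohen_d_from_t <- function(t, n = NULL, n1 = NULL, n2 = NULL,
                           design = c("paired", "independent")) {
  design <- match.arg(design)
  if (design == "paired") {
    stopifnot(!is.null(n))
    abs(t) / sqrt(n)
  } else {
    stopifnot(!is.null(n1), !is.null(n2))
    abs(t) * sqrt(1 / n1 + 1 / n2)
  }
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample K-S test against a normal distribution with moments
#' estimated from the data. Because the parameters are estimated, the
#' default uses the Lilliefors-corrected p-value; the uncorrected
#' plug-in K-S variant is available via `method = "ks"`.
#'
#' @param x Numeric vector, `n >= 4`, non-constant.
#' @param method `"lilliefors"` (default) or `"ks"`.
#' @return A one-row tibble: `statistic`, `p`, `method`, `n`.
#' @export
ks_normality <- function(x, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  if (length(x) < 4) abort("ks_normality: n >= 4 required")
  if (sd(x) == 0) abort("ks_normality: constant input is degenerate")
  if (method == "lilliefors") {
    ht <- nortest::lillie.test(x)
  } else {
    ht <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  }
  tibble(statistic = unname(ht$statistic), p = ht$p.value,
         method = method, n = length(x))
}

#' Pearson correlation with two-sided p
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, non-constant.
#' @return A one-row tibble: `r`, `p`, `n`, `conf.low`, `conf.high`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("pearson: unequal lengths")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("pearson: n >= 3 required")
  if (sd(x) == 0 || sd(y) == 0) abort("pearson: constant vector")
  ht <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  ci <- if (!is.null(ht$conf.int)) ht$conf.int else c(NA_real_, NA_real_)
  tibble(r = unname(ht$estimate), p = ht$p.value, n = length(x),
         conf.low = ci[1], conf.high = ci[2])
}

#' Behavioural group comparisons for a cohort manifest
#'
#' Reproduces the study-style behavioural table: within-group pre/post
#' paired comparisons and between-group independent comparisons at each
#' session, for accuracy and reaction time, with Cohen's d for each.
#'
#' @param manifest Tibble with columns `subject_id`, `group`, `session`,
#'   `accuracy`, `rt_median_mean`.
#' @return A tibble with one row per test: `measure`, `comparison`,
#'   `design`, `t`, `df`, `p`, `d`, `n1`, `n2`.
#' @export
behavior_stats <- function(manifest) {
  need <- c("subject_id", "group", "session", "accuracy", "rt_median_mean")
  missing <- setdiff(need, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("behavior_stats: manifest lacks ", paste(missing, collapse = ", ")))
  }
  wide <- function(measure) {
    m <- manifest[order(manifest$subject_id), ]
    list(
      mld_pre = m[[measure]][m$group == "MLD" & m$session == "pre"],
      mld_post = m[[measure]][m$group == "MLD" & m$session == "post"],
      td_pre = m[[measure]][m$group == "TD" & m$session == "pre"],
      td_post = m[[measure]][m$group == "TD" & m$session == "post"]
    )
  }
  out <- list()
  for (measure in c("accuracy", "rt_median_mean")) {
    w <- wide(measure)
    tests <- list(
      list("MLD post vs pre", w$mld_post, w$mld_pre, "paired"),
      list("TD post vs pre", w$td_post, w$td_pre, "paired"),
      list("MLD vs TD at pre", w$mld_pre, w$td_pre, "independent"),
      list("MLD vs TD at post", w$mld_post, w$td_post, "independent"),
      list("MLD post vs TD pre", w$mld_post, w$td_pre, "independent"),
      list("MLD post vs TD post", w$mld_post, w$td_post, "independent")
    )
    for (ts in tests) {
      res <- ttest_effect(ts[[2]], ts[[3]], design = ts[[4]])
      res$measure <- measure
      res$comparison <- ts[[1]]
      out[[length(out) + 1]] <- res
    }
  }
  dplyr::relocate(bind_rows(out), "measure", "comparison")
}
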