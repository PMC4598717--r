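#' Brain Plasticity Index
#'
#' One minus the in-mask Pearson correlation between a subject's
#' z-transformed pre- and post-intervention activation patterns: 0 means
#' the pattern is unchanged, values approaching 2 mean it has inverted,
#' and higher values indicate greater functional plasticity. Both maps
#' are z-transformed with the same convention as the pattern classifier,
#' so the index is invariant to positive affine rescaling of either map.
#'
#' @param pre_map,post_map [stat_map()]s or 3-D arrays on the same grid.
#' @param mask Logical 3-D array (the pre-tutoring group-difference mask).
#' @return The BPI value in `[0, 2]`.
#' @export
#' @examples
#' m <- array(rnorm(27), c(3, 3, 3))
#' bpi(m, m, array(TRUE, c(3, 3, 3))) # identical maps: 0
bpi <- function(pre_map, post_map, mask) {
  pre <- map_values(pre_map); post <- map_values(post_map)
  if (!identical(dim(pre), dim(post))) {
    abort("bpi: pre and post maps have different dimensions")
  }
  if (!identical(dim(pre), dim(mask))) abort("bpi: mask mismatch")
  zp <- z_transform(pre, mask)
  zq <- z_transform(post, mask)
  1 - cor(zp, zq)
}

#' Per-subject BPI records for a cohort
#'
#' Computes the BPI for each subject of the requested group from the
#' manifest's pre- and post-session maps, together with the performance
#' gain (post minus pre Addition accuracy).
#'
#' @param manifest Cohort manifest with `subject_id`, `group`, `session`,
#'   `accuracy` and a `map` list-column.
#' @param mask Logical 3-D array.
#' @param group Group to score (default `"MLD"`).
#' @return Tibble: `subject_id`, `bpi`, `accuracy_pre`, `accuracy_post`,
#'   `performance_gain`.
#' @export
bpi_records <- function(manifest, mask, group = "MLD") {
  m <- manifest[manifest$group == group, , drop = FALSE]
  if (!"map" %in% names(m)) abort("bpi_records: manifest has no `map` column")
  subjects <- unique(m$subject_id)
  rows <- lapply(subjects, function(sid) {
    pre <- m[m$subject_id == sid & m$session == "pre", ]
    post <- m[m$subject_id == sid & m$session == "post", ]
    if (nrow(pre) != 1 || nrow(post) != 1) {
      abort(paste0("bpi_records: subject ", sid, " lacks a pre/post pair"))
    }
    tibble(subject_id = sid,
           bpi = bpi(pre$map[[1]], post$map[[1]], mask),
           accuracy_pre = pre$accuracy, accuracy_post = post$accuracy,
           performance_gain = post$accuracy - pre$accuracy)
  })
  bind_rows(rows)
}

#' Relate the BPI to performance gains
#'
#' Pearson correlation (two-sided) between per-subject BPI and accuracy
#' gain.
#'
#' @param records Tibble from [bpi_records()] (columns `bpi` and
#'   `performance_gain`).
#' @return One-row tibble: `r`, `p`, `n`, `conf.low`, `conf.high`.
#' @export
relate_bpi_to_gain <- function(records) {
  if (nrow(records) < 3) abort("relate_bpi_to_gain: n >= 3 records required")
  pearson(records$bpi, records$performance_gain)
}

#' Screen baseline covariates as predictors of gain
#'
#' Pearson r and uncorrected two-sided p for each baseline measure
#' against performance gain, with listwise deletion of missing values
#' (count reported per covariate).
#'
#' @param records Tibble with `subject_id` and `performance_gain`.
#' @param covariates Tibble with `subject_id` and one numeric column per
#'   baseline measure.
#' @return Tibble: `covariate`, `n`, `n_missing`, `r`, `p`.
#' @export
baseline_predictor_screen <- function(records, covariates) {
  if (!"subject_id" %in% names(covariates)) {
    abort("baseline_predictor_screen: covariates need subject_id")
  }
  merged <- left_join(records, covariates, by = "subject_id")
  vars <- setdiff(names(covariates), "subject_id")
  rows <- lapply(vars, function(vn) {
    x <- merged[[vn]]
    g <- merged$performance_gain
    keep <- !(is.na(x) | is.na(g))
    if (sum(keep) == 0) {
      abort(paste0("baseline_predictor_screen: covariate `", vn,
                   "` is entirely missing"))
    }
    ct <- pearson(x[keep], g[keep])
    tibble(covariate = vn, n = sum(keep), n_missing = sum(!keep),
           r = ct$r, p = ct$p)
  })
  bind_rows(rows)
}
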