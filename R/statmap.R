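#' Construct a statistical map
#'
#' A `stat_map` is a 3-D array of voxel values with provenance metadata:
#' the universal currency passed between GLM estimation, group inference,
#' pattern classification and the plasticity index. Values outside the
#' brain mask are `NA`.
#'
#' @param values 3-D numeric array.
#' @param kind One of `"beta"`, `"contrast"`, `"t"`, `"z"`.
#' @param subject,group,session,run Provenance fields (may be `NA`).
#' @param df Residual degrees of freedom for `t` maps (optional).
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, kind = c("t", "contrast", "beta", "z"),
                     subject = NA_character_, group = NA_character_,
                     session = NA_character_, run = NA_integer_, df = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.array(values), length(dim(values)) == 3)
  structure(list(values = values, kind = kind, subject = subject,
                 group = group, session = session, run = run, df = df),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$values)
  cat("<stat_map:", x$kind, "> ", paste(d, collapse = " x "),
      if (!is.na(x$subject)) paste0(" subject=", x$subject),
      if (!is.na(x$session)) paste0(" session=", x$session),
      if (!is.null(x$df)) paste0(" df=", x$df), "\n", sep = "")
  invisible(x)
}

# accept a stat_map or bare array and return the array
map_values <- function(m) {
  if (inherits(m, "stat_map")) m$values else m
}

#' Write / read a statistical map as NIfTI-1
#'
#' @param map A [stat_map()] or 3-D array.
#' @param path Output `.nii` or `.nii.gz` path.
#' @param voxel_mm Isotropic voxel size recorded in the header.
#' @return `write_stat_map` returns `path` invisibly; `read_stat_map`
#'   returns a [stat_map()].
#' @export
write_stat_map <- function(map, path, voxel_mm = 2) {
  v <- map_values(map)
  attr(v, "pixdim") <- rep(voxel_mm, 3)
  img <- RNifti::asNifti(v, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_stat_map
#' @param kind,subject,group,session,run Provenance recorded on the
#'   returned object.
#' @export
read_stat_map <- function(path, kind = "t", subject = NA, group = NA,
                          session = NA, run = NA) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  stat_map(vals, kind = kind, subject = subject, group = group,
           session = session, run = run)
}
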