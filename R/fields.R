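#' Separable 3-D Gaussian smoothing
#'
#' Smooths a 3-D array with an isotropic Gaussian kernel specified by its
#' full width at half maximum in millimetres. Smoothing is applied as three
#' one-dimensional convolutions with edge renormalisation (kernel rows sum
#' to one), so a constant field is left unchanged.
#'
#' @param x 3-D numeric array.
#' @param fwhm_mm Kernel FWHM in mm; `0` returns `x` unchanged.
#' @param voxel_mm Voxel edge length in mm (isotropic).
#' @return Smoothed array of the same dimension.
#' @export
gaussian_smooth_3d <- function(x, fwhm_mm, voxel_mm = 2) {
  stopifnot(length(dim(x)) == 3, fwhm_mm >= 0, voxel_mm > 0)
  if (fwhm_mm == 0) return(x)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  smooth_axis <- function(arr, axis) {
    n <- dim(arr)[axis]
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-((i - j)^2) / (2 * sigma^2)))
    K <- K / rowSums(K)
    d <- dim(arr)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    a <- K %*% matrix(a, nrow = n)
    a <- array(a, dim = d[perm])
    aperm(a, order(perm))
  }
  for (ax in 1:3) x <- smooth_axis(x, ax)
  x
}

# white noise field smoothed to the requested FWHM and rescaled so the
# in-mask standard deviation equals `sd`
smooth_noise_field <- function(dims, fwhm_mm, voxel_mm, mask, sd = 1) {
  f <- array(rnorm(prod(dims)), dim = dims)
  f <- gaussian_smooth_3d(f, fwhm_mm, voxel_mm)
  s <- stats::sd(f[mask])
  if (s == 0) return(f * 0)
  f / s * sd
}

#' Ellipsoidal brain mask for a simulation grid
#'
#' @param dims Integer vector of three grid dimensions.
#' @param fraction Semi-axis length as a fraction of each half-dimension.
#' @return Logical 3-D array.
#' @export
brain_mask <- function(dims, fraction = 0.9) {
  stopifnot(length(dims) == 3, all(dims >= 4))
  ctr <- (dims + 1) / 2
  semi <- (dims - 2) / 2 * fraction
  ix <- slice.index(array(0, dims), 1)
  iy <- slice.index(array(0, dims), 2)
  iz <- slice.index(array(0, dims), 3)
  ((ix - ctr[1]) / semi[1])^2 + ((iy - ctr[2]) / semi[2])^2 +
    ((iz - ctr[3]) / semi[3])^2 <= 1
}

# smooth unit-peak spherical bump centred at `center` (voxel coordinates)
region_bump <- function(center, radius_mm, dims, voxel_mm,
                        edge_fwhm_mm = 4) {
  ix <- slice.index(array(0, dims), 1)
  iy <- slice.index(array(0, dims), 2)
  iz <- slice.index(array(0, dims), 3)
  d2 <- (ix - center[1])^2 + (iy - center[2])^2 + (iz - center[3])^2
  b <- array(as.numeric(d2 <= (radius_mm / voxel_mm)^2), dim = dims)
  b <- gaussian_smooth_3d(b, edge_fwhm_mm, voxel_mm)
  if (max(b) > 0) b <- b / max(b)
  b
}
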