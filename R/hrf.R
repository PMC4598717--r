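#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF used throughout the package: a difference of two gamma
#' densities with a response peak at 6 s, an undershoot peaking at 16 s, a
#' peak-to-undershoot ratio of 1:6, and 32 s support. This is the standard
#' shape assumed by event-related GLM software.
#'
#' @param t Numeric vector of times in seconds (values outside `[0, 32]`
#'   return 0).
#' @return Numeric vector of HRF values, scaled so the peak is 1.
#' @export
#' @examples
#' tt <- seq(0, 32, by = 0.1)
#' plot(tt, canonical_hrf(tt), type = "l")
canonical_hrf <- function(t) {
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0 | t > 32] <- 0
  h / max(dgamma(seq(0, 32, by = 0.01), shape = 6, rate = 1) -
            dgamma(seq(0, 32, by = 0.01), shape = 16, rate = 1) / 6)
}

# temporal derivative of the canonical HRF (finite difference, 1 s shift,
# the usual latency regressor)
hrf_derivative <- function(t, delta = 1) {
  (canonical_hrf(t) - canonical_hrf(t - delta)) / delta
}

# Convolve a set of boxcar events with a kernel on an oversampled grid and
# sample at scan times. onsets/durations in seconds.
convolve_events <- function(onsets, durations, n_volumes, tr,
                            kernel = canonical_hrf, dt = tr / 16) {
  run_len <- n_volumes * tr
  grid <- seq(0, run_len + 32, by = dt)
  neural <- numeric(length(grid))
  for (k in seq_along(onsets)) {
    on <- (grid >= onsets[k]) & (grid < onsets[k] + durations[k])
    neural[on] <- neural[on] + 1
  }
  kern <- kernel(seq(0, 32, by = dt))
  sig <- convolve(neural, rev(kern), type = "open")[seq_along(grid)] * dt
  scan_times <- (seq_len(n_volumes) - 1) * tr
  idx <- round(scan_times / dt) + 1
  sig[idx]
}
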