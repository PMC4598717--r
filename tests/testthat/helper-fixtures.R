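# small shared fixtures, built in code

tiny_config <- function(seed = 1, n_per_group = 4, ...) {
  sim_config(grid_shape = c(12, 14, 12), n_per_group = n_per_group,
             trials_per_condition_per_run = 4, n_rests = 2,
             aberrant_regions = tibble::tibble(
               name = "blob", center = list(c(6, 7, 6)), radius_mm = 4,
               pre_effect = 1.5, post_retention_mean = 0.2,
               post_retention_sd = 0.15),
             task_regions = tibble::tibble(
               name = "task", center = list(c(6, 10, 6)), radius_mm = 4,
               amplitude = 2),
             seed = seed, ...)
}

flat_motion <- function(n) {
  tibble::tibble(x = numeric(n), y = numeric(n), z = numeric(n),
                 pitch = numeric(n), roll = numeric(n), yaw = numeric(n))
}

# two separated gaussian clouds for classifier tests
separated_features <- function(n_per = 15, p = 20, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
    X[seq_len(n_per), 1] <- X[seq_len(n_per), 1] + sep
    list(X = X, labels = rep(c("MLD", "TD"), each = n_per))
  })
}

default_aberrant_regions_for_test <- function(center = c(6, 7, 6),
                                              retention = 0.2) {
  tibble::tibble(name = "blob", center = list(center), radius_mm = 4,
                 pre_effect = 2, post_retention_mean = retention,
                 post_retention_sd = 0.1)
}
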