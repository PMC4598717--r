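#' z-transform a map within a mask
#'
#' Demeans and scales by the in-mask standard deviation (population
#' convention, divisor N), so that downstream pattern analyses are
#' independent of each subject's overall activation level and scale.
#'
#' @param map A [stat_map()] or 3-D array.
#' @param mask Logical 3-D array.
#' @return Numeric vector of z-scored in-mask values (one feature row).
#' @export
#' @examples
#' m <- array(1:27, c(3, 3, 3))
#' z_transform(m, array(TRUE, c(3, 3, 3)))[1:3]
z_transform <- function(map, mask) {
  vals <- map_values(map)
  if (!identical(dim(vals), dim(mask))) {
    abort("z_transform: map and mask dimensions differ")
  }
  v <- vals[mask]
  if (any(is.na(v))) abort("z_transform: NA values inside the mask")
  if (length(unique(v)) < 2) {
    abort("z_transform: map is constant within the mask")
  }
  s <- sqrt(mean((v - mean(v))^2)) # population SD
  (v - mean(v)) / s
}

#' Assemble a feature matrix from session maps
#'
#' One row per subject: the z-transformed in-mask pattern of that
#' subject's session map.
#'
#' @param maps List of [stat_map()]s or 3-D arrays.
#' @param mask Logical 3-D array (typically the pre-tutoring
#'   group-difference mask).
#' @return Matrix (subjects x in-mask voxels).
#' @export
feature_matrix <- function(maps, mask) {
  t(vapply(maps, z_transform, numeric(sum(mask)), mask = mask))
}

new_classification_result <- function(folds, accuracy, cost, labels,
                                      null_accuracies = NULL, p = NULL,
                                      n_perm = NULL, seed = NULL) {
  structure(list(folds = folds, accuracy = accuracy, cost = cost,
                 labels = labels, null_accuracies = null_accuracies,
                 p = p, n_perm = n_perm, seed = seed),
            class = "classification_result")
}

# features/labels -> gram matrix and +/-1 labels
prepare_classification <- function(features, labels, min_per_class = 2) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) abort("binary labels required")
  if (any(table(labels) < min_per_class)) {
    abort(paste0("each class needs >= ", min_per_class, " subjects"))
  }
  if (anyNA(features)) abort("features contain missing values")
  y <- ifelse(labels == levels(labels)[1], 1L, -1L)
  list(K = tcrossprod(as.matrix(features)), y = y, labels = labels)
}

#' Leave-one-out cross-validated pattern classification
#'
#' Trains a linear maximum-margin (soft-margin support-vector) classifier
#' on all subjects but one and predicts the held-out subject, repeating
#' for every subject; the classification accuracy is the mean fold
#' correctness. The solver is deterministic given the features, so
#' repeated calls agree exactly.
#'
#' @param features Subjects x voxels matrix (see [feature_matrix()]).
#' @param labels Binary group labels (factor or character).
#' @param cost Soft-margin cost parameter C.
#' @return Object of class `classification_result` with a fold table
#'   (`truth`, `predicted`) and `accuracy`.
#' @export
loocv_classify <- function(features, labels, cost = 1) {
  pc <- prepare_classification(features, labels)
  res <- .svm_loocv(pc$K, pc$y, cost)
  lev <- levels(pc$labels)
  folds <- tibble(
    fold = seq_along(pc$y),
    truth = as.character(pc$labels),
    predicted = ifelse(res$predicted > 0, lev[1], lev[2]))
  new_classification_result(folds, res$accuracy, cost, pc$labels)
}

#' Permutation test for classification accuracy
#'
#' Re-runs the full leave-one-out cross-validation under label
#' permutations to build the null distribution of accuracy. Labels are
#' shuffled once per permutation and reused across folds, preserving
#' exchangeability. The p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so it is never zero.
#'
#' @param features Subjects x voxels matrix.
#' @param labels Binary group labels.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @param cost Soft-margin cost parameter C.
#' @return A `classification_result` with `null_accuracies`, `p`,
#'   `n_perm` and `seed` filled in.
#' @export
permutation_test <- function(features, labels, n_perm = 10000, seed = 1,
                             cost = 1) {
  if (n_perm < 100) abort("permutation_test: n_perm >= 100 required")
  obs <- loocv_classify(features, labels, cost = cost)
  pc <- prepare_classification(features, labels)
  perms <- with_seed_(seed, {
    vapply(seq_len(n_perm), function(i) sample(pc$y), integer(length(pc$y)))
  })
  null_acc <- .svm_loocv_perm(pc$K, perms, cost)
  p <- (1 + sum(null_acc >= obs$accuracy - 1e-12)) / (1 + n_perm)
  new_classification_result(obs$folds, obs$accuracy, cost, pc$labels,
                            null_accuracies = null_acc, p = p,
                            n_perm = n_perm, seed = seed)
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> LOOCV accuracy ",
      sprintf("%.2f%%", 100 * x$accuracy),
      " (n = ", nrow(x$folds), ")", sep = "")
  if (!is.null(x$p)) {
    cat(", permutation p = ", signif(x$p, 3), " (", x$n_perm,
        " permutations)", sep = "")
  }
  cat("\n")
  invisible(x)
}
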