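# Shared multivariate machinery: epsilon-insensitive SVR, linear
# back-projection of dual coefficients onto training rows, k-fold averaged
# weight maps and Monte Carlo permutation z-scoring. Used identically for
# voxel features (VLSM) and edge features (CLSM).
#
# The kernel matrix depends only on the features, never on the permuted
# target, so it is computed once per data set and sliced per fold; this is
# what makes 10 000-iteration permutation runs tractable.

#' SVR configuration
#'
#' @param kernel `"gaussian"` (default; the radial basis kernel
#'   `exp(-||x - x'||^2 / kernel_scale^2)`) or `"linear"`.
#' @param kernel_scale Positive scale of the Gaussian kernel (default 1,
#'   i.e. features are used on their native scale).
#' @param box_constraint Positive SVM cost parameter C (default 1).
#' @param epsilon_tube Epsilon-insensitive tube half-width; `NULL` (default)
#'   means `0.1 * sd(target)`, which is 0.1 after target standardization.
#' @param n_folds Cross-validation folds (>= 2, default 5); final weight
#'   maps are the average of the per-fold maps.
#' @param n_permutations Monte Carlo permutations for z-scoring (>= 100;
#'   default 10000, reduce for desk-scale runs).
#' @param seed Integer seed driving fold assignment and permutations.
#' @param standardize_target Standardize the target to zero mean / unit
#'   variance before fitting (default TRUE; keeps the kernel scale and the
#'   epsilon tube comparable across behavioral measures).
#' @return Object of class `svr_config`.
#' @export
svr_config <- function(kernel = c("gaussian", "linear"), kernel_scale = 1,
                       box_constraint = 1, epsilon_tube = NULL,
                       n_folds = 5L, n_permutations = 10000L, seed = 1L,
                       standardize_target = TRUE) {
  kernel <- match.arg(kernel)
  if (kernel_scale <= 0) stop("kernel_scale must be > 0")
  if (box_constraint <= 0) stop("box_constraint must be > 0")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  structure(list(
    kernel = kernel, kernel_scale = kernel_scale,
    box_constraint = box_constraint, epsilon_tube = epsilon_tube,
    n_folds = as.integer(n_folds),
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed), standardize_target = isTRUE(standardize_target)
  ), class = "svr_config")
}

# Full kernel matrix for the configured kernel.
compute_kernel <- function(features, config) {
  if (config$kernel == "gaussian") {
    d2 <- as.matrix(stats::dist(features))^2
    exp(-d2 / config$kernel_scale^2)
  } else {
    tcrossprod(features)
  }
}

prepare_target <- function(target, config) {
  y <- as_target(target)
  sdy <- stats::sd(y)
  if (config$standardize_target) {
    y <- if (sdy > 0) as.numeric(scale(y)) else y - mean(y)
  }
  eps <- if (is.null(config$epsilon_tube))
    max(0.1 * stats::sd(y), 1e-8) else config$epsilon_tube
  list(y = y, eps = eps)
}

# Solve the eps-SVR dual on a (sub)kernel; returns the signed dual
# coefficient vector alpha over the training rows (0 off support vectors),
# so the decision function is f(x) = sum_i alpha_i K(x_i, x) + b.
fit_alpha <- function(K, y, C, eps) {
  # a target entirely inside the epsilon tube has the exact solution
  # alpha = 0 (constant predictor, zero loss)
  if (max(abs(y - mean(y))) <= eps) return(numeric(length(y)))
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "eps-svr",
                     C = C, epsilon = eps)
  a <- numeric(length(y))
  a[kernlab::SVindex(m)] <- unlist(kernlab::coef(m))
  a
}

#' Fit an epsilon-insensitive SVR
#'
#' @param features Subjects x features numeric matrix (finite, complete).
#' @param target Numeric vector or `residual_scores`.
#' @param config An `svr_config`.
#' @return Object of class `svr_fit` exposing the dual coefficients
#'   (`alpha`, signed, zero off the support vectors), the support-vector
#'   rows (`support`), the training features, and the kernlab model.
#' @export
fit_svr <- function(features, target, config = svr_config()) {
  features <- as.matrix(features)
  y <- as_target(target)
  if (nrow(features) < 5L) stop("need at least 5 subjects")
  if (nrow(features) != length(y)) stop("subjects misaligned between features and target")
  if (anyNA(features) || any(!is.finite(features))) stop("non-finite feature values")
  if (anyNA(y) || any(!is.finite(y))) stop("non-finite target values")
  pt <- prepare_target(y, config)
  K <- compute_kernel(features, config)
  if (max(abs(pt$y - mean(pt$y))) <= pt$eps) {
    model <- NULL
    alpha <- numeric(length(y))
  } else {
    model <- kernlab::ksvm(kernlab::as.kernelMatrix(K), pt$y,
                           type = "eps-svr",
                           C = config$box_constraint, epsilon = pt$eps)
    alpha <- numeric(length(y))
    alpha[kernlab::SVindex(model)] <- unlist(kernlab::coef(model))
  }
  structure(list(
    model = model, alpha = alpha,
    support = which(alpha != 0),
    features = features, config = config,
    target = pt$y, epsilon = pt$eps, kernel_matrix = K
  ), class = "svr_fit")
}

#' Back-project SVR dual coefficients onto feature space
#'
#' The per-feature weight is the linear sensitivity map
#' `w = X^T alpha = sum_i alpha_i x_i` over support vectors. For the linear
#' kernel this is the primal weight vector; for the Gaussian kernel it is
#' the standard linear back-projection convention of SVR-based
#' lesion-symptom mapping toolboxes (the kernel itself never defines a
#' finite-dimensional beta map).
#'
#' @param fit An `svr_fit`.
#' @param features Feature matrix (defaults to the training features; must
#'   be the matrix the model was fitted on).
#' @return Numeric weight vector, one entry per feature column.
#' @export
feature_weights <- function(fit, features = fit$features) {
  if (!inherits(fit, "svr_fit")) stop("feature_weights needs a fitted svr_fit")
  features <- as.matrix(features)
  if (nrow(features) != length(fit$alpha))
    stop("features do not match the rows the model was fitted on")
  drop(crossprod(features, fit$alpha))
}

# Fold assignment: permuted round-robin so fold sizes differ by at most 1.
assign_folds <- function(n, n_folds) {
  sample(rep_len(seq_len(n_folds), n))
}

# One cross-validated weight map given prepared y and precomputed kernel.
crossval_weights_prepared <- function(features, K, y, eps, config, fold_ids) {
  p <- ncol(features)
  acc <- numeric(p)
  for (f in seq_len(config$n_folds)) {
    tr <- which(fold_ids != f)
    a <- fit_alpha(K[tr, tr, drop = FALSE], y[tr],
                   config$box_constraint, eps)
    acc <- acc + drop(crossprod(features[tr, , drop = FALSE], a))
  }
  acc / config$n_folds
}

new_weight_map <- function(feature_ids, weights, z = NULL, null_mean = NULL,
                           null_sd = NULL, degenerate = NULL) {
  stopifnot(length(feature_ids) == length(weights))
  structure(list(
    feature_ids = feature_ids, weights = weights, z_scores = z,
    null_mean = null_mean, null_sd = null_sd, degenerate = degenerate
  ), class = "weight_map")
}

#' @export
print.weight_map <- function(x, ...) {
  cat("weight_map:", length(x$weights), "features",
      if (!is.null(x$z_scores)) "(with permutation z-scores)" else "", "\n")
  invisible(x)
}

#' Cross-validated averaged SVR weight map
#'
#' Subjects are partitioned into `n_folds` seeded disjoint folds; for each
#' fold the model is trained on the complement and its back-projected
#' weights recorded; the final map is the mean of the per-fold maps.
#'
#' @inheritParams fit_svr
#' @param fold_ids Optional explicit fold assignment (integer vector in
#'   `1..n_folds`); default is a seeded random partition.
#' @return A `weight_map` (no z-scores).
#' @export
crossval_weight_map <- function(features, target, config = svr_config(),
                                fold_ids = NULL) {
  features <- as.matrix(features)
  y0 <- as_target(target)
  n <- nrow(features)
  if (n < config$n_folds) stop("need n >= n_folds")
  pt <- prepare_target(y0, config)
  K <- compute_kernel(features, config)
  if (is.null(fold_ids)) {
    fold_ids <- with_seed(config$seed, assign_folds(n, config$n_folds))
  }
  if (min(table(factor(fold_ids, levels = seq_len(config$n_folds)))) < 2L)
    stop("every fold needs at least 2 subjects")
  w <- crossval_weights_prepared(features, K, pt$y, pt$eps, config, fold_ids)
  ids <- colnames(features)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(features)))
  new_weight_map(ids, w)
}

#' Z-score observed weights against a permutation null
#'
#' `z = (w - null_mean) / null_sd`; features with degenerate null sd get
#' z = 0 and are flagged.
#'
#' @param weights Observed weight vector.
#' @param null_mean,null_sd Per-feature null moments.
#' @param tol Relative floor below which the null sd counts as degenerate
#'   (scaled by `max(1, |null_mean|)` per feature).
#' @return List with `z` and logical `degenerate`.
#' @export
zscore_weights <- function(weights, null_mean, null_sd, tol = 1e-6) {
  stopifnot(length(weights) == length(null_mean),
            length(weights) == length(null_sd))
  degenerate <- !is.finite(null_sd) | null_sd < tol * pmax(1, abs(null_mean))
  z <- numeric(length(weights))
  z[!degenerate] <- (weights[!degenerate] - null_mean[!degenerate]) /
    null_sd[!degenerate]
  list(z = z, degenerate = degenerate)
}

#' Permutation z-scored SVR weight map
#'
#' The observed cross-validated weight map is compared to a Monte Carlo
#' null: for each permutation the target values are shuffled across
#' subjects (the features stay fixed), the fold assignment is re-randomized,
#' and the full cross-validated map recomputed. Per-feature z-scores are
#' `(w_true - mean_null) / sd_null`.
#'
#' @inheritParams crossval_weight_map
#' @param perm_matrix Optional explicit permutation index matrix
#'   (`n_permutations` x n); default is seeded uniform shuffling. With
#'   `refold = FALSE`, an identity row makes that null draw equal the true
#'   map exactly.
#' @param refold Re-randomize the fold assignment for every permutation
#'   (default TRUE), so the null distribution absorbs fold-partition
#'   variance as well as target-exchange variance; `FALSE` reuses the true
#'   run's folds throughout.
#' @return A `weight_map` with `z_scores`, `null_mean`, `null_sd` and a
#'   `degenerate` flag per feature.
#' @export
permutation_zscores <- function(features, target, config = svr_config(),
                                perm_matrix = NULL, refold = TRUE) {
  features <- as.matrix(features)
  y0 <- as_target(target)
  n <- nrow(features)
  if (n < config$n_folds) stop("need n >= n_folds")
  pt <- prepare_target(y0, config)
  K <- compute_kernel(features, config)
  p <- ncol(features)
  B <- if (is.null(perm_matrix)) config$n_permutations else nrow(perm_matrix)
  res <- with_seed(config$seed, {
    folds0 <- assign_folds(n, config$n_folds)
    w_true <- crossval_weights_prepared(features, K, pt$y, pt$eps, config,
                                        folds0)
    s1 <- numeric(p)
    s2 <- numeric(p)
    for (b in seq_len(B)) {
      perm <- if (is.null(perm_matrix)) sample.int(n) else perm_matrix[b, ]
      folds_b <- if (refold) assign_folds(n, config$n_folds) else folds0
      wb <- crossval_weights_prepared(features, K, pt$y[perm], pt$eps,
                                      config, folds_b)
      s1 <- s1 + wb
      s2 <- s2 + wb^2
    }
    mu <- s1 / B
    sdv <- sqrt(pmax(s2 / B - mu^2, 0) * B / (B - 1))
    list(w = w_true, mu = mu, sd = sdv)
  })
  zs <- zscore_weights(res$w, res$mu, res$sd)
  ids <- colnames(features)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(features)))
  new_weight_map(ids, res$w, z = zs$z, null_mean = res$mu, null_sd = res$sd,
                 degenerate = zs$degenerate)
}
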