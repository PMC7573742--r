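test_that("svr_config validates its fields", {
  expect_error(svr_config(n_folds = 1), "n_folds")
  expect_error(svr_config(kernel_scale = 0), "kernel_scale")
  expect_error(svr_config(box_constraint = -1), "box_constraint")
  expect_error(svr_config(n_permutations = 50), "n_permutations")
  cfg <- svr_config()
  expect_equal(cfg$kernel, "gaussian")
  expect_equal(cfg$kernel_scale, 1)
  expect_equal(cfg$n_folds, 5L)
})

test_that("fitting is deterministic and degenerate targets give null weights", {
  set.seed(3)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- rnorm(20)
  f1 <- fit_svr(X, y, svr_config(seed = 1))
  f2 <- fit_svr(X, y, svr_config(seed = 1))
  expect_identical(f1$alpha, f2$alpha)
  # constant target carries no information: all weights essentially zero
  fc <- fit_svr(X, rep(2, 20), svr_config())
  expect_lt(max(abs(feature_weights(fc))), 1e-6)
  expect_error(fit_svr(X[1:3, ], y[1:3]), "5 subjects")
  X[1, 1] <- NA
  expect_error(fit_svr(X, y), "non-finite")
})

test_that("linear-kernel back-projection recovers the analytic slope sign", {
  set.seed(4)
  x <- rnorm(30)
  X <- cbind(x)
  y <- 2 * x
  f <- fit_svr(X, y, svr_config(kernel = "linear"))
  expect_gt(feature_weights(f)[1], 0)
})

test_that("back-projection equals the hand formula and respects symmetry", {
  # one support vector with alpha = 1 and row (1, 0, 2) -> weights (1, 0, 2)
  fake <- structure(list(alpha = c(1, 0, 0),
                         features = rbind(c(1, 0, 2), c(5, 5, 5), c(-1, 2, 0))),
                    class = "svr_fit")
  expect_equal(unname(feature_weights(fake)), c(1, 0, 2))
  # zero dual coefficients -> zero vector
  fake$alpha <- c(0, 0, 0)
  expect_equal(unname(feature_weights(fake)), c(0, 0, 0))
  # duplicated feature columns receive identical weights
  set.seed(5)
  X <- matrix(rnorm(25 * 3), 25, 3)
  X <- cbind(X, X[, 2])
  y <- rnorm(25)
  w <- feature_weights(fit_svr(X, y, svr_config()))
  expect_equal(w[2], w[4])
  expect_error(feature_weights(list()), "svr_fit")
})

test_that("gaussian-kernel weights agree with an independent SVR implementation", {
  skip_if_not_installed("e1071")
  set.seed(6)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- drop(X %*% c(2, -1, rep(0, 6))) + rnorm(30, 0, 0.2)
  cfg <- svr_config(kernel_scale = 1.5, box_constraint = 2,
                    epsilon_tube = 0.15, standardize_target = FALSE)
  w_ours <- feature_weights(fit_svr(X, y, cfg))
  m <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                  gamma = 1 / 1.5^2, cost = 2, epsilon = 0.15, scale = FALSE)
  w_ref <- drop(crossprod(X[m$index, , drop = FALSE], m$coefs))
  expect_equal(unname(w_ours), unname(w_ref), tolerance = 1e-6)
})

test_that("cross-validated maps average fold weights and flag tiny folds", {
  set.seed(7)
  n <- 30
  signal <- rbinom(n, 1, 0.5)
  X <- cbind(signal + rnorm(n, 0, 0.1), rnorm(n))
  y <- -2 * signal + rnorm(n, 0, 0.1)
  wm <- crossval_weight_map(X, y, svr_config(seed = 2))
  expect_s3_class(wm, "weight_map")
  expect_gt(abs(wm$weights[1]), abs(wm$weights[2]))
  expect_lt(wm$weights[1], 0)
  # same data, same fold assignment -> identical map
  wm2 <- crossval_weight_map(X, y, svr_config(seed = 2))
  expect_identical(wm$weights, wm2$weights)
  expect_error(crossval_weight_map(X, y, svr_config(n_folds = 16)),
               "at least 2")
})

test_that("z-scoring against injected nulls follows the formula", {
  zs <- zscore_weights(weights = c(-2, 3, 1), null_mean = c(0, 1, 1),
                       null_sd = c(1, 2, 0))
  expect_equal(zs$z, c(-2, 1, 0))
  expect_identical(zs$degenerate, c(FALSE, FALSE, TRUE))
})

test_that("permutation machinery honors explicit permutations", {
  set.seed(8)
  n <- 16
  X <- matrix(rbinom(n * 10, 1, 0.4), n, 10)
  y <- rnorm(n)
  cfg <- svr_config(n_permutations = 100, seed = 3)
  # all-identity permutation matrix with fixed folds: every null draw
  # equals the true map
  pm <- matrix(rep(seq_len(n), each = 120), nrow = 120, byrow = FALSE)
  wm <- permutation_zscores(X, y, cfg, perm_matrix = pm, refold = FALSE)
  expect_equal(wm$null_mean, wm$weights, tolerance = 1e-10)
  expect_true(all(wm$degenerate))
  expect_true(all(wm$z_scores == 0))
})

test_that("a permuted target is itself null-distributed", {
  set.seed(9)
  n <- 40
  X <- matrix(rbinom(n * 25, 1, 0.3), n, 25)
  y <- rnorm(n)
  y_shuffled <- sample(y)
  wm <- permutation_zscores(X, y_shuffled,
                            svr_config(n_permutations = 150, seed = 4))
  expect_lt(abs(mean(wm$z_scores)), 0.6)
  expect_lt(mean(abs(wm$z_scores) > 3), 0.05)
})

test_that("null-sd estimates stabilize as the permutation count grows", {
  set.seed(10)
  n <- 24
  X <- matrix(rbinom(n * 8, 1, 0.4), n, 8)
  y <- rnorm(n)
  spread <- vapply(c(100L, 400L), function(B) {
    sds <- vapply(1:4, function(s) {
      permutation_zscores(X, y, svr_config(n_permutations = B,
                                           seed = 70L + s))$null_sd
    }, numeric(ncol(X)))
    mean(apply(sds, 1L, stats::sd) / rowMeans(sds))
  }, numeric(1))
  expect_lt(spread[2], spread[1])
})

test_that("full permutation pipeline is deterministic given seed and config", {
  set.seed(11)
  X <- matrix(rbinom(20 * 12, 1, 0.4), 20, 12)
  y <- rnorm(20)
  cfg <- svr_config(n_permutations = 100, seed = 5)
  w1 <- permutation_zscores(X, y, cfg)
  w2 <- permutation_zscores(X, y, cfg)
  expect_identical(w1$z_scores, w2$z_scores)
  expect_identical(w1$null_sd, w2$null_sd)
})
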