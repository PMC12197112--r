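test_that("identity design recovers the soft-threshold closed form", {
  set.seed(7)
  y <- rnorm(12, sd = 2)
  for (w in c(0, 0.3, 1.5)) {
    fit <- bpdn(diag(12), y, w)
    expect_equal(coef(fit), soft_threshold(y, w), tolerance = 1e-10)
  }
})

test_that("weights at or above the correlation bound zero the solution", {
  set.seed(8)
  A <- matrix(rnorm(60), 10, 6)
  y <- rnorm(10)
  bound <- max(abs(crossprod(A, y)))
  expect_identical(coef(bpdn(A, y, bound)), numeric(6))
  expect_identical(coef(bpdn(A, y, bound * 1.5)), numeric(6))
  expect_gt(sum(coef(bpdn(A, y, bound * 0.9)) != 0), 0)
})

test_that("objective matches an independent convex solver on random
           instances", {
  skip_if_not_installed("glmnet")
  set.seed(123)
  for (i in 1:20) {
    n <- 8L; p <- 12L
    A <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    w <- 10^runif(1, -3, 0.5)
    mine <- bpdn(A, y, w)
    oracle <- glmnet::glmnet(A, y, lambda = w / n, standardize = FALSE,
                             intercept = FALSE, thresh = 1e-14,
                             maxit = 1e6)
    xo <- as.numeric(stats::coef(oracle))[-1]
    obj_o <- 0.5 * sum((y - A %*% xo)^2) + w * sum(abs(xo))
    expect_lt(abs(mine$objective - obj_o) / max(1, abs(obj_o)), 1e-6)
  }
})

test_that("solutions satisfy the subgradient optimality condition and the
           l1 norm shrinks along the weight ladder", {
  set.seed(42)
  A <- matrix(rnorm(40 * 25), 40, 25)
  y <- A %*% c(rep(2, 3), rep(0, 22)) + rnorm(40, sd = 0.3)
  ladder <- 10^seq(-3, 1, length.out = 9)
  norms <- numeric(length(ladder))
  for (i in seq_along(ladder)) {
    fit <- bpdn(A, y, ladder[i])
    # max |A'(y - Ax)| <= w + tol
    expect_lte(fit$kkt, 1e-6 * max(1, ladder[i]))
    norms[i] <- sum(abs(coef(fit)))
  }
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("degenerate problems are rejected with clear errors", {
  expect_error(bpdn(matrix(0, 4, 3), rnorm(4), 0), "unidentifiable")
  expect_error(bpdn(matrix(NA_real_, 4, 3), rnorm(4), 1), "non-finite")
  expect_error(bpdn(diag(3), 1:2, 1), "length")
  expect_error(bpdn(diag(3), 1:3, -1), "non-negative")
})

test_that("cross-validation folds are near-equal, seeded and reproducible", {
  set.seed(99)
  A <- matrix(rnorm(256 * 12), 256, 12)
  y <- A %*% c(3, -1, rep(0, 10)) + rnorm(256, sd = 0.2)
  ws <- weight_grid(1e-4, 10, length = 7)
  cv1 <- cv_bpdn(A, y, weights = ws, seed = 5)
  cv2 <- cv_bpdn(A, y, weights = ws, seed = 5)
  cv3 <- cv_bpdn(A, y, weights = ws, seed = 6)
  expect_identical(cv1$best_weight, cv2$best_weight)
  expect_identical(cv1$fold_id, cv2$fold_id)
  expect_false(identical(cv1$fold_id, cv3$fold_id))
  # 256 entries in 10 folds: six of 26 and four of 25
  expect_equal(as.integer(sort(table(cv1$fold_id))),
               c(rep(25L, 4), rep(26L, 6)))
  expect_true(cv1$best_weight %in% ws)
  expect_true(all(cv1$path$mse >= 0))
  expect_error(cv_bpdn(A[1:5, ], y[1:5], folds = 10), "folds")
})

test_that("sharp spectra prefer more sparsity than broad spectra", {
  # ground-truth CV scoring: a one-spike signal tolerates (and prefers)
  # a larger penalty than a broad overlapping-feature signal
  set.seed(2024)
  n <- 60L; p <- 40L
  A <- matrix(abs(rnorm(n * p)), n, p)
  broad <- exp(-0.5 * ((seq_len(p) - 20) / 8)^2)
  spike <- replace(numeric(p), 20, 1)
  ws <- weight_grid(1e-6, 1e6)
  pick <- function(x) {
    y <- A %*% x + rnorm(n, sd = 0.05 * max(A %*% x))
    cv_bpdn(A, y, weights = ws, ground_truth = x, seed = 1)$best_weight
  }
  expect_gte(pick(spike), pick(broad))
})
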