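test_that("kernel evaluations satisfy the closed forms", {
  for (k in c("laplacedot", "rbfdot")) {
    sp <- kernel_spec(k, sigma = 1)
    x <- rnorm(5)
    expect_equal(eval_kernel(sp, x, x), 1)
  }
  # rbf: sigma = 1, ||x - y||^2 = 1 -> exp(-1)
  sp <- kernel_spec("rbfdot", sigma = 1)
  expect_equal(eval_kernel(sp, c(0, 0), c(1, 0)), exp(-1), tolerance = 1e-12)
  # laplace: distance 2 at sigma 0.5 -> exp(-1)
  spl <- kernel_spec("laplacedot", sigma = 0.5)
  expect_equal(eval_kernel(spl, 0, 2), exp(-1), tolerance = 1e-12)
  expect_error(eval_kernel(sp, 1:3, 1:4), "equal length")
  expect_error(kernel_spec("rbfdot", sigma = -1), "sigma")
})

test_that("Gram matrices are symmetric positive semidefinite", {
  withr::with_seed(2, X <- matrix(rnorm(40 * 6), 40, 6))
  for (k in c("laplacedot", "rbfdot")) {
    sp <- median_heuristic_sigma(kernel_spec(k), X)
    K <- kernel_matrix(sp, X)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
    expect_equal(unname(diag(K)), rep(1, 40))
  }
})

test_that("median-heuristic bandwidth uses squared and plain distances", {
  withr::with_seed(3, X <- matrix(rnorm(30 * 4), 30, 4))
  d2 <- as.numeric(dist(X))^2
  sp_r <- median_heuristic_sigma(kernel_spec("rbfdot"), X)
  expect_equal(sp_r$sigma, 1 / median(d2), tolerance = 1e-10)
  sp_l <- median_heuristic_sigma(kernel_spec("laplacedot"), X)
  expect_equal(sp_l$sigma, 1 / median(sqrt(d2)), tolerance = 1e-10)
})

test_that("GPR posterior mean matches a dense linear-algebra oracle", {
  withr::with_seed(5, {
    X <- matrix(rnorm(5 * 3), 5, 3)
    y <- rnorm(5, 12, 2)
    Xnew <- matrix(rnorm(4 * 3), 4, 3)
  })
  nv <- 0.3
  m <- fit_gpr(X, y, kernel_spec("rbfdot", sigma = 0.2), noise_var = nv,
               jitter = 0, standardize = FALSE)
  pred <- predict_age(m, Xnew)
  # oracle: direct dense solve, independent of the Cholesky path
  K <- outer(1:5, 1:5, Vectorize(function(i, j)
    exp(-0.2 * sum((X[i, ] - X[j, ])^2))))
  Ks <- outer(1:4, 1:5, Vectorize(function(i, j)
    exp(-0.2 * sum((Xnew[i, ] - X[j, ])^2))))
  yc <- (y - mean(y)) / sd(y)
  oracle <- mean(y) + sd(y) * as.numeric(Ks %*% solve(K + nv * diag(5), yc))
  expect_lt(max(abs(pred - oracle)), 1e-10)
  # constant response: the model predicts the constant everywhere
  mc <- fit_gpr(X, rep(9, 5), kernel_spec("rbfdot", sigma = 0.2),
                standardize = FALSE)
  expect_equal(predict_age(mc, Xnew), rep(9, 4), tolerance = 1e-10)
})

test_that("GPR matches the reference kernel toolkit on shared settings", {
  library(kernlab)
  withr::with_seed(8, {
    X <- matrix(rnorm(40 * 6), 40, 6)
    y <- rnorm(40, 12, 2.5)
    Xnew <- matrix(rnorm(10 * 6), 10, 6)
  })
  sg <- 0.15
  # my fit solves (K + v I) a = (y - ybar)/ysd and predicts
  # ybar + ysd K* a, which is algebraically ybar + K*(K + v I)^-1 (y-ybar):
  # identical to the reference run on the centred response with var = v
  m <- fit_gpr(X, y, kernel_spec("rbfdot", sigma = sg), noise_var = 1,
               jitter = 0, standardize = FALSE)
  ref <- kernlab::gausspr(x = X, y = y - mean(y), scaled = FALSE,
                          kernel = "rbfdot", kpar = list(sigma = sg),
                          var = 1, variance.model = FALSE)
  ref_pred <- as.numeric(kernlab::predict(ref, Xnew)) + mean(y)
  expect_lt(max(abs(predict_age(m, Xnew) - ref_pred)), 1e-6)
})

test_that("GPR limits: interpolation at zero noise, mean at huge noise", {
  withr::with_seed(9, {
    X <- matrix(rnorm(12 * 4), 12, 4)
    y <- rnorm(12, 12, 2.5)
  })
  k <- kernel_spec("rbfdot", sigma = 0.1)
  m0 <- fit_gpr(X, y, k, noise_var = 1e-12, jitter = 0)
  expect_equal(predict_age(m0, X), y, tolerance = 1e-5)
  minf <- fit_gpr(X, y, k, noise_var = 1e10)
  expect_equal(predict_age(minf, X), rep(mean(y), 12), tolerance = 1e-5)
  # single training point at vanishing noise predicts its own label
  m1 <- fit_gpr(X[1, , drop = FALSE], y[1], k, noise_var = 1e-12)
  expect_equal(predict_age(m1, X[1, , drop = FALSE]), y[1],
               tolerance = 1e-6)
})

test_that("RVR recovers a sparse noiseless kernel expansion", {
  withr::with_seed(12, X <- matrix(rnorm(20 * 3), 20, 3))
  sp <- kernel_spec("rbfdot", sigma = 0.5)
  K <- kernel_matrix(sp, X)
  y <- as.numeric(K[, c(3, 7)] %*% c(2, -1))
  m <- fit_rvr(X, y, kernel_spec("rbfdot", sigma = 0.5),
               standardize = FALSE)
  expect_true(all(c(3, 7) %in% m$relevance_idx))
  pred <- predict_age(m, X)
  expect_lt(sqrt(mean((pred - y)^2)), 1e-3)
  # determinism: same fixture -> identical retained set
  m2 <- fit_rvr(X, y, kernel_spec("rbfdot", sigma = 0.5),
                standardize = FALSE)
  expect_identical(m$relevance_idx, m2$relevance_idx)
  expect_equal(m$mu, m2$mu)
})

test_that("converged RVR fits a recoverable signal better than one sweep", {
  withr::with_seed(12, X <- matrix(rnorm(20 * 3), 20, 3))
  sp <- kernel_spec("rbfdot", sigma = 0.5)
  y <- as.numeric(kernel_matrix(sp, X)[, c(3, 7)] %*% c(2, -1))
  m1 <- fit_rvr(X, y, sp, max_iter = 1, standardize = FALSE)
  mc <- fit_rvr(X, y, sp, max_iter = 500, standardize = FALSE)
  mse <- function(m) mean((predict_age(m, X) - y)^2)
  expect_lte(mse(mc), mse(m1) + 1e-10)
})

test_that("prediction contracts: empty input, column mismatch", {
  withr::with_seed(15, {
    X <- matrix(rnorm(10 * 3), 10, 3)
    y <- rnorm(10, 12, 2)
  })
  m <- fit_gpr(X, y, kernel_spec("laplacedot"))
  expect_identical(predict_age(m, X[0, , drop = FALSE]), numeric(0))
  expect_error(predict_age(m, matrix(0, 2, 5)), "columns")
})

test_that("fitted models round-trip through JSON serialisation", {
  withr::with_seed(21, {
    X <- matrix(rnorm(15 * 4), 15, 4)
    y <- rnorm(15, 12, 2)
    Xn <- matrix(rnorm(5 * 4), 5, 4)
  })
  for (alg in c("GPR", "RVR")) {
    m <- fit_age_model(alg, X, y, "rbfdot")
    path <- withr::local_tempfile(fileext = ".json")
    write_age_model(m, path)
    back <- read_age_model(path)
    expect_equal(predict_age(back, Xn), predict_age(m, Xn),
                 tolerance = 1e-12)
  }
})
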