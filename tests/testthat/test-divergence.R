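test_that("gaussian kernel matches its closed form and validates input", {
  expect_equal(gaussian_kernel(c(1, 2), c(1, 2), 3), 1)
  # distance sigma * sqrt(2) forces exp(-1)
  expect_equal(gaussian_kernel(0, sqrt(2) * 1.7, 1.7), exp(-1))
  expect_equal(gaussian_kernel(c(0, 0), c(3, 4), 5), exp(-0.5))
  expect_error(gaussian_kernel(c(0, 0), 1, 1), "same length")
  expect_error(gaussian_kernel(0, 1, 0), "positive")
  expect_error(gaussian_kernel(0, 1, -2), "positive")
})

test_that("kernel matrix is elementwise gaussian_kernel and saturates as sigma grows", {
  s <- matrix(c(0, 1), ncol = 1)
  K <- kernel_matrix(s, s, 1)
  expect_equal(K, matrix(c(1, exp(-0.5), exp(-0.5), 1), 2, 2))
  expect_equal(kernel_matrix(matrix(2, 1, 1), matrix(2, 1, 1), 0.3),
               matrix(1, 1, 1))
  expect_equal(kernel_matrix(s, s, 1e9), matrix(1, 2, 2), tolerance = 1e-12)
  expect_error(kernel_matrix(matrix(0, 1, 2), matrix(0, 1, 3), 1), "dimension")
})

test_that("h-hat is the column mean of the p-segment kernel matrix", {
  expect_equal(build_h_hat(matrix(1, 3, 4)), rep(1, 4))
  expect_equal(build_h_hat(diag(2)), c(0.5, 0.5))
  expect_equal(build_h_hat(matrix(c(0.2, 0.7), 1, 2)), c(0.2, 0.7))
})

test_that("H-hat collapses correctly at the alpha extremes", {
  Kp <- matrix(runif(12), 3, 4)
  Kq <- matrix(runif(20), 5, 4)
  expect_equal(build_H_hat(Kp, Kq, 1), crossprod(Kp) / 3)
  expect_equal(build_H_hat(Kp, Kq, 0), crossprod(Kq) / 5)
  expect_equal(build_H_hat(matrix(1, 1, 1), matrix(1, 1, 1), 0.3),
               matrix(1, 1, 1))
  expect_error(build_H_hat(Kp, Kq, 1.2), "alpha")
})

test_that("H-hat is exactly symmetric and positive semi-definite", {
  cases <- plsbd:::with_seed(11, lapply(1:20, function(i) {
    list(Kp = matrix(runif(5 * 6), 5, 6), Kq = matrix(runif(7 * 6), 7, 6),
         alpha = runif(1))
  }))
  for (cs in cases) {
    H <- build_H_hat(cs$Kp, cs$Kq, cs$alpha)
    expect_identical(max(abs(H - t(H))), 0)
    expect_gte(min(eigen(H, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("ridge solve returns the unique regularized solution with tiny residual", {
  expect_equal(solve_theta(matrix(1, 1, 1), 1, 1), 0.5)
  h <- c(0.3, -1, 2)
  expect_equal(solve_theta(matrix(0, 3, 3), h, 1), h)
  cases <- plsbd:::with_seed(5, lapply(1:10, function(i) {
    K <- matrix(rnorm(40), 8, 5)
    list(H = crossprod(K) / 8, h = runif(5), lam = 10^runif(1, -3, 0))
  }))
  for (cs in cases) {
    th <- solve_theta(cs$H, cs$h, cs$lam)
    resid <- sqrt(sum(((cs$H + diag(cs$lam, 5)) %*% th - cs$h)^2))
    expect_lte(resid, 1e-8 * sqrt(sum(cs$h^2)))
  }
  expect_error(solve_theta(matrix(NA_real_, 1, 1), 1, 1), "finite")
  expect_error(solve_theta(matrix(1, 1, 1), 1, 0), "positive")
})

test_that("ratio evaluation is the kernel expansion", {
  m <- list(centers = matrix(5, 1, 1), sigma = 2, theta = 2)
  expect_equal(evaluate_ratio(m, matrix(5, 1, 1)), 2)
  m0 <- list(centers = matrix(c(0, 1), 2, 1), sigma = 1, theta = c(0, 0))
  expect_equal(evaluate_ratio(m0, matrix(c(-1, 0, 3), 3, 1)), rep(0, 3))
  m2 <- list(centers = matrix(c(0, 1), 2, 1), sigma = 1, theta = c(1, 1))
  expect_equal(evaluate_ratio(m2, matrix(0, 1, 1)), 1 + exp(-0.5))
})

test_that("the divergence plug-in vanishes exactly on unit ratios and matches hand values", {
  for (a in seq(0, 0.9, by = 0.1)) {
    expect_identical(plsbd_score(rep(1, 5), rep(1, 7), a), 0)
  }
  expect_equal(plsbd_score(c(2, 2), c(0.5, 0.5), 0), 1)
  expect_equal(plsbd_score(c(1.5, 1.5), c(0.5, 0.5), 0.5), 1)
  expect_error(plsbd_score(1, 1, 1), "alpha")
  expect_error(plsbd_score(numeric(0), 1, 0.5), "non-empty")
  expect_error(plsbd_score(c(1, Inf), 1, 0.5), "finite")
})

test_that("alpha-relative Pearson plug-in and its lower-bound identity hold", {
  expect_equal(alpha_pearson_score(rep(1, 4)), 0)
  expect_equal(alpha_pearson_score(c(2, 2)), 0.5)
  # the offset identity linking the two plug-ins, exact to 1e-12
  for (cs in random_ratios(1000)) {
    lhs <- plsbd_score(cs$rp, cs$rq, cs$alpha)
    rhs <- alpha_pearson_score(cs$rp) +
      (2 - cs$alpha) / (2 * (1 - cs$alpha)) * (1 - mean(cs$rq))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})
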