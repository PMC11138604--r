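test_that("median heuristic enumerates small pair sets and errors on degenerate input", {
  expect_equal(median_heuristic(matrix(c(0, 1), 2, 1)), 1)
  expect_equal(median_heuristic(matrix(c(0, 1, 2), 3, 1)), 1)
  expect_equal(median_heuristic(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)), 5)
  expect_error(median_heuristic(matrix(1, 5, 2)), "identical")
  # large-n subsampled path is deterministic under a seed and close to truth
  x <- plsbd:::with_seed(2, matrix(rnorm(300), ncol = 1))
  m1 <- median_heuristic(x, seed = 7)
  m2 <- median_heuristic(x, seed = 7)
  expect_identical(m1, m2)
  expect_equal(m1, median(dist(x)), tolerance = 0.1)
})

test_that("center choice takes p-samples first, then seeded q-samples, capped at the pool", {
  yp <- matrix(1:10, 5, 2)
  yq <- matrix(101:110, 5, 2)
  expect_identical(choose_centers(yp, yq, 5), yp)
  expect_identical(choose_centers(yp, yq, 3), yp[1:3, ])
  all10 <- choose_centers(yp, yq, 50)
  expect_equal(nrow(all10), 10)
  expect_identical(all10[1:5, ], yp)
  expect_setequal(all10[6:10, 1], yq[, 1])
  expect_identical(choose_centers(yp, yq, 1), yp[1, , drop = FALSE])
  # q-fill order is seeded
  expect_identical(choose_centers(yp, yq, 8, seed = 3),
                   choose_centers(yp, yq, 8, seed = 3))
})

test_that("held-out objective is the quadratic loss without the ridge term", {
  expect_equal(cv_objective(0, matrix(2, 1, 1), 1), 0)
  expect_equal(cv_objective(1, matrix(2, 1, 1), 1), 0)
  expect_equal(cv_objective(1, matrix(2, 1, 1), 3), -2)
})

test_that("hyperparameter selection is deterministic, honours 1-point grids and tie-breaks", {
  yp <- plsbd:::with_seed(1, matrix(rnorm(30, 1), ncol = 1))
  yq <- plsbd:::with_seed(2, matrix(rnorm(30), ncol = 1))
  centers <- choose_centers(yp, yq, 20, seed = 1)
  one <- select_hyperparams(yp, yq, centers, alpha = 0.5,
                            sigma_grid = 0.8, lambda_grid = 0.1, seed = 1)
  expect_equal(one$sigma, 0.8)
  expect_equal(one$lambda, 0.1)
  a <- select_hyperparams(yp, yq, centers, alpha = 0.5,
                          sigma_grid = c(0.5, 1, 2), lambda_grid = 10^(-2:0), seed = 5)
  b <- select_hyperparams(yp, yq, centers, alpha = 0.5,
                          sigma_grid = c(0.5, 1, 2), lambda_grid = 10^(-2:0), seed = 5)
  expect_identical(a, b)
  # duplicated grid entries collapse; selection still lands on a grid point
  dup <- select_hyperparams(yp, yq, centers, alpha = 0.5,
                            sigma_grid = c(1, 1, 0.5, 2), lambda_grid = c(0.1, 0.1),
                            seed = 5)
  expect_true(dup$sigma %in% c(0.5, 1, 2))
  expect_equal(dup$lambda, 0.1)
})

test_that("the compiled fitting path agrees with the pure-R primitive composition", {
  yp <- plsbd:::with_seed(21, matrix(rnorm(40, 1.5), ncol = 2))
  yq <- plsbd:::with_seed(22, matrix(rnorm(40, 0), ncol = 2))
  centers <- choose_centers(yp, yq, 15, seed = 4)
  sigmas <- sort(c(0.7, 1.3, 2.5))
  lambdas <- sort(10^(-2:0))
  for (alpha in c(0, 0.5)) {
    ref <- ref_cv_fit(yp, yq, centers, alpha, sigmas, lambdas, n_folds = 4, seed = 9)
    got <- plsbd:::cv_fit_internal(yp, yq, centers, alpha, sigmas, lambdas,
                                   n_folds = 4, seed = 9)
    expect_equal(got$sigma, ref$sigma)
    expect_equal(got$lambda, ref$lambda)
    expect_equal(unname(got$cv), ref$cv, tolerance = 1e-10)
    expect_equal(got$theta, ref$theta, tolerance = 1e-8)
    expect_equal(got$rp, ref$rp, tolerance = 1e-8)
    expect_equal(got$rq, ref$rq, tolerance = 1e-8)
  }
})

test_that("fitted models have the right shapes and respond to separation", {
  yp <- plsbd:::with_seed(31, matrix(rnorm(50, 10), ncol = 1))
  yq <- plsbd:::with_seed(32, matrix(rnorm(50, 0), ncol = 1))
  fit <- density_ratio(yp, yq, alpha = 0.5, seed = 3)
  expect_s3_class(fit, "density_ratio")
  expect_length(fit$rp, 50)
  expect_length(fit$rq, 50)
  expect_length(coef(fit), nrow(fit$centers))
  expect_equal(predict(fit, yp), fit$rp, tolerance = 1e-10)
  # well-separated segments give a clearly positive divergence
  expect_gt(plsbd_score(fit$rp, fit$rq, 0.5), 0.5)
  # identical segments give a near-zero divergence
  y0 <- plsbd:::with_seed(33, matrix(rnorm(50), ncol = 1))
  fit0 <- density_ratio(y0, y0, alpha = 0.5, seed = 3)
  expect_lt(abs(plsbd_score(fit0$rp, fit0$rq, 0.5)), 0.05)
  # clipping floors the fitted ratios at zero
  fitc <- density_ratio(yp, yq, alpha = 0.5, seed = 3, clip_ratios = TRUE)
  expect_gte(min(c(fitc$rp, fitc$rq)), 0)
  # fold reduction warns when segments are smaller than n_folds
  expect_warning(density_ratio(yp[1:3, , drop = FALSE], yq[1:3, , drop = FALSE],
                               n_folds = 5, seed = 1),
                 "reducing cross-validation folds")
})

test_that("the fitted divergence is calibrated near zero under the null", {
  scores <- sapply(1:100, function(s) {
    yp <- plsbd:::with_seed(1000 + s, matrix(rnorm(50), ncol = 1))
    yq <- plsbd:::with_seed(2000 + s, matrix(rnorm(50), ncol = 1))
    fit <- density_ratio(yp, yq, alpha = 0.5, seed = s)
    plsbd_score(fit$rp, fit$rq, 0.5)
  })
  # centers sit at the p samples, so the fitted ratio is slightly shrunk at
  # the q samples: the null estimate carries a small positive bias of about
  # (1 - mean(rq)) / (2 * (1 - alpha)) at n = 50, far below signal scale (~2)
  expect_gt(mean(scores), -0.05)
  expect_lt(mean(scores), 0.15)
})

test_that("the plug-in tracks the population divergence for separated Gaussians", {
  # population value for N(0,1) vs N(10,1) under the equal mixture, from the
  # quadrature oracle (= 2 to quadrature accuracy)
  pop <- plsbd_quadrature(density_spec("gaussian", 10, 1),
                          density_spec("gaussian", 0, 1), 0.5)
  ok <- sapply(1:100, function(s) {
    yp <- plsbd:::with_seed(5000 + s, matrix(rnorm(200, 10), ncol = 1))
    yq <- plsbd:::with_seed(6000 + s, matrix(rnorm(200, 0), ncol = 1))
    fit <- density_ratio(yp, yq, alpha = 0.5, seed = s)
    est <- plsbd_score(fit$rp, fit$rq, 0.5)
    est > 0 && est > pop / 3 && est < pop * 3
  })
  expect_gte(sum(ok), 90)
})
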