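# closed form for the squared L2 distance between two Gaussian densities:
# int (p - q)^2 = 1/(2 s1 sqrt(pi)) + 1/(2 s2 sqrt(pi)) - 2 N(m1 - m2; 0, s1^2 + s2^2)
gaussian_l2sq <- function(m1, s1, m2, s2) {
  1 / (2 * s1 * sqrt(pi)) + 1 / (2 * s2 * sqrt(pi)) -
    2 * dnorm(m1 - m2, 0, sqrt(s1^2 + s2^2))
}

test_that("quadrature divergence of a density against itself is numerically zero", {
  p <- density_spec("gaussian", 0, 1)
  for (a in c(0, 0.3, 0.5, 0.9)) {
    expect_lte(abs(plsbd_quadrature(p, p, a)), 1e-10)
  }
  u <- density_spec("uniform", lower = -2, upper = 2)
  expect_lte(abs(plsbd_quadrature(u, u, 0.5)), 1e-10)
})

test_that("the equal-mixture divergence is symmetric in its arguments", {
  pairs <- plsbd:::with_seed(3, lapply(1:10, function(i) {
    list(p = density_spec("gaussian", runif(1, -5, 5), runif(1, 0.3, 3)),
         q = density_spec("gaussian", runif(1, -5, 5), runif(1, 0.3, 3)))
  }))
  for (pr in pairs) {
    expect_equal(plsbd_quadrature(pr$p, pr$q, 0.5),
                 plsbd_quadrature(pr$q, pr$p, 0.5), tolerance = 1e-8)
  }
})

test_that("quadrature reproduces independently computed reference values", {
  p <- density_spec("gaussian", 0, 1)
  q <- density_spec("gaussian", 1, 1)
  # frozen values from an independent quadrature implementation
  expect_equal(plsbd_quadrature(p, q, 0.5), 0.40810853126700064, tolerance = 1e-8)
  expect_equal(alpha_pearson_quadrature(p, q, 0.5), 0.10202713281675017,
               tolerance = 1e-8)
  # at the equal mixture the divergence is exactly 4x the alpha-relative one
  expect_equal(plsbd_quadrature(p, q, 0.5),
               4 * alpha_pearson_quadrature(p, q, 0.5), tolerance = 1e-9)
})

test_that("a uniform scaling measure reduces the divergence to a scaled L2 distance", {
  p <- density_spec("gaussian", 0, 1)
  q <- density_spec("gaussian", 1.5, 0.8)
  m <- density_spec("uniform", lower = -15, upper = 15)
  cdens <- 1 / 30
  expect_equal(plsbd_quadrature(p, q, m),
               gaussian_l2sq(0, 1, 1.5, 0.8) / (2 * cdens), tolerance = 1e-6)
  # a measure that vanishes where p != q is rejected
  narrow <- density_spec("uniform", lower = -1, upper = 1)
  expect_error(plsbd_quadrature(p, q, narrow), "vanishes")
})

test_that("the relative density ratio is bounded by 1/alpha", {
  grid <- seq(-30, 30, length.out = 4001)
  pairs <- plsbd:::with_seed(9, lapply(1:8, function(i) {
    c(runif(1, -10, 10), runif(1, 0.2, 5), runif(1, -10, 10), runif(1, 0.2, 5))
  }))
  for (pr in pairs) {
    for (a in c(0.1, 0.3, 0.5, 0.8, 1)) {
      p <- dnorm(grid, pr[1], pr[2])
      q <- dnorm(grid, pr[3], pr[4])
      r <- p / (a * p + (1 - a) * q)
      expect_lte(max(r, na.rm = TRUE), 1 / a + 1e-12)
    }
  }
})

test_that("the alpha-relative Pearson divergence lower-bounds the mixture divergence", {
  mus <- c(0.5, 1, 2, 4)
  sds <- c(0.5, 1, 2)
  for (mu in mus) {
    for (sd2 in sds) {
      p <- density_spec("gaussian", 0, 1)
      q <- density_spec("gaussian", mu, sd2)
      for (a in seq(0.1, 0.9, by = 0.2)) {
        dpl <- plsbd_quadrature(p, q, a)
        dape <- alpha_pearson_quadrature(p, q, a)
        expect_gte(dpl, dape + (a - 2) / (2 * a) - 1e-9)
      }
    }
  }
})

test_that("the divergence grows with mean separation", {
  p <- density_spec("gaussian", 0, 1)
  vals <- sapply(seq(0, 4, by = 0.5), function(mu) {
    plsbd_quadrature(p, density_spec("gaussian", mu, 1), 0.5)
  })
  expect_true(all(diff(vals) > 0))
})
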