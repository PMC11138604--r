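#' Piecewise-Gaussian benchmark series
#'
#' A univariate series of four length-100 segments drawn from
#' N(0,1), N(10,1), N(-5,1) and N(10,1): mean shifts at times 101, 201
#' and 301 with unit variance throughout.
#'
#' @param seed RNG seed.
#' @return A list with `x` (400 x 1 matrix), `change_points`
#'   (`c(101, 201, 301)`, the first time of each new regime) and a
#'   `description` of the regimes.
#' @export
simulate_gauss_segments <- function(seed = 1L) {
  means <- c(0, 10, -5, 10)
  x <- with_seed(seed, rnorm(400, mean = rep(means, each = 100), sd = 1))
  list(x = matrix(x, ncol = 1, dimnames = list(NULL, "y")),
       change_points = c(101L, 201L, 301L),
       description = "four length-100 segments: N(0,1), N(10,1), N(-5,1), N(10,1)")
}

#' AR(2) benchmark series with staircase noise-mean shifts
#'
#' The autoregression `y[t] = 0.6 y[t-1] - 0.5 y[t-2] + e[t]` with
#' `e[t] ~ N(mu[t], sd)` over 1000 time steps, `y[1] = y[2] = 0` (noise
#' enters from t = 3). The noise mean is a staircase: 0 for the first 100
#' steps, then incremented by 2 every 100 steps (`mu[t] = mu[t-100] + 2`),
#' reaching 18 in the last segment — nine change points at
#' 101, 201, ..., 901. The AR polynomial roots lie inside the unit circle,
#' so each segment is (asymptotically) stationary around `mu / 0.9`.
#'
#' @param seed RNG seed.
#' @param noise_sd innovation standard deviation (default 1; 0 gives the
#'   deterministic recursion with `e[t] = mu[t]`, useful for checking the
#'   fixed point `mu / (1 - 0.6 + 0.5)`).
#' @param mu_step noise-mean increment per segment (default 2; 0 gives a
#'   change-free weakly stationary AR(2) series).
#' @return A list with `x` (1000 x 1 matrix), `change_points`
#'   (`seq(101, 901, by = 100)`) and a `description`.
#' @export
simulate_ar2 <- function(seed = 1L, noise_sd = 1, mu_step = 2) {
  T_len <- 1000L
  mu <- mu_step * pmax(0, ceiling(seq_len(T_len) / 100) - 1)  # 0,0,...,2,...,18
  eps <- if (noise_sd > 0) {
    with_seed(seed, rnorm(T_len, mean = mu, sd = noise_sd))
  } else {
    mu
  }
  y <- numeric(T_len)
  for (t in 3:T_len) y[t] <- 0.6 * y[t - 1] - 0.5 * y[t - 2] + eps[t]
  list(x = matrix(y, ncol = 1, dimnames = list(NULL, "y")),
       change_points = seq(101L, 901L, by = 100L),
       description = "AR(2) phi = (0.6, -0.5); noise mean +2 every 100 steps (staircase to 18)")
}

#' High-dimensional benchmark with a sparse set of shifting covariates
#'
#' Emulates the omics regime: `d` covariates observed at `T` time points,
#' of which only `ceiling(frac_changing * d)` (seeded choice) undergo mean
#' shifts at shared change times while the rest stay i.i.d.
#' `N(0, noise_sd^2)` throughout. Each changing covariate gets a seeded
#' sign and its mean steps by `sign * shift` at every change time
#' (accumulating across changes), synchronously across the changing subset.
#'
#' @param T_len number of time points.
#' @param d number of covariates.
#' @param frac_changing fraction of covariates that shift, in `(0, 1]`.
#' @param change_times 1-based times at which the new regime starts.
#' @param shift mean-shift magnitude per change.
#' @param noise_sd observation noise standard deviation.
#' @param seed RNG seed.
#' @return A list with `x` (`T_len` x `d` matrix), `change_points`,
#'   `changing` (indices of the shifting covariates), `signs`, and a
#'   `description`.
#' @export
simulate_highdim <- function(T_len = 100L, d = 200L, frac_changing = 0.05,
                             change_times = c(26L, 51L, 76L), shift = 4,
                             noise_sd = 1, seed = 1L) {
  T_len <- as.integer(T_len); d <- as.integer(d)
  change_times <- sort(as.integer(change_times))
  if (!(frac_changing > 0 && frac_changing <= 1)) {
    stop("'frac_changing' must be in (0, 1]")
  }
  if (any(change_times <= 1L) || any(change_times > T_len)) {
    stop("'change_times' must lie in (1, T]")
  }
  n_change <- as.integer(ceiling(frac_changing * d))
  out <- with_seed(seed, {
    changing <- sort(sample.int(d, n_change))
    signs <- sample(c(-1, 1), n_change, replace = TRUE)
    x <- matrix(rnorm(T_len * d, 0, noise_sd), T_len, d)
    steps <- outer(seq_len(T_len), change_times, ">=")  # T x n_changes
    level <- rowSums(steps) * shift                     # 0, shift, 2*shift, ...
    for (j in seq_along(changing)) {
      x[, changing[j]] <- x[, changing[j]] + signs[j] * level
    }
    list(x = x, changing = changing, signs = signs)
  })
  colnames(out$x) <- paste0("g", seq_len(d))
  list(x = out$x, change_points = change_times, changing = out$changing,
       signs = out$signs,
       description = sprintf("%d of %d covariates shift by +-%g at %s (noise sd %g)",
                             n_change, d, shift,
                             paste(change_times, collapse = ", "), noise_sd))
}
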