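#' Specify a one-dimensional density for the quadrature oracle
#'
#' Lightweight container for the densities used by [plsbd_quadrature()] and
#' [alpha_pearson_quadrature()]. Only the families needed by the 1-D test
#' oracle are supported.
#'
#' @param family `"gaussian"` or `"uniform"`.
#' @param mean,sd Gaussian parameters (`sd > 0`).
#' @param lower,upper uniform support (`lower < upper`).
#' @return An object of class `"density_spec"`.
#' @export
density_spec <- function(family = c("gaussian", "uniform"), mean = 0, sd = 1,
                         lower = 0, upper = 1) {
  family <- match.arg(family)
  if (family == "gaussian") {
    if (!is.finite(sd) || sd <= 0) stop("'sd' must be positive")
    out <- list(family = family, mean = mean, sd = sd)
  } else {
    if (!(lower < upper)) stop("'lower' must be less than 'upper'")
    out <- list(family = family, lower = lower, upper = upper)
  }
  class(out) <- "density_spec"
  out
}

pdf_fun <- function(spec) {
  stopifnot(inherits(spec, "density_spec"))
  if (spec$family == "gaussian") {
    function(y) dnorm(y, spec$mean, spec$sd)
  } else {
    function(y) dunif(y, spec$lower, spec$upper)
  }
}

# mass of `spec` outside [lo, hi]
tail_mass <- function(spec, lo, hi) {
  if (spec$family == "gaussian") {
    pnorm(lo, spec$mean, spec$sd) + pnorm(hi, spec$mean, spec$sd, lower.tail = FALSE)
  } else {
    punif(lo, spec$lower, spec$upper) + punif(hi, spec$lower, spec$upper, lower.tail = FALSE)
  }
}

# effective numeric support: mean +- 12 sd for gaussians, exact for uniforms
spec_range <- function(spec) {
  if (spec$family == "gaussian") {
    c(spec$mean - 12 * spec$sd, spec$mean + 12 * spec$sd)
  } else {
    c(spec$lower, spec$upper)
  }
}

# piecewise adaptive quadrature: split at distribution landmarks so the
# adaptive rule converges even for well-separated components
piecewise_integrate <- function(f, lo, hi, landmarks, rel_tol) {
  brk <- sort(unique(pmin(pmax(c(lo, hi, landmarks), lo), hi)))
  total <- 0
  for (i in seq_len(length(brk) - 1L)) {
    if (brk[i + 1L] - brk[i] < .Machine$double.eps) next
    total <- total + integrate(f, brk[i], brk[i + 1L], rel.tol = rel_tol,
                               abs.tol = 1e-12, subdivisions = 500L,
                               stop.on.error = TRUE)$value
  }
  total
}

spec_landmarks <- function(spec) {
  if (spec$family == "gaussian") {
    spec$mean + spec$sd * c(-4, -1, 0, 1, 4)
  } else {
    c(spec$lower, spec$upper)
  }
}

#' Pearson-like scaled Bregman divergence by numerical quadrature
#'
#' Independent 1-D oracle for the divergence
#' \eqn{D_{PL}(p\|q;m) = \frac12 \int m(y) (p(y)/m(y) - q(y)/m(y))^2 dy}.
#' This routine integrates the definition directly and is used for testing
#' the plug-in estimator; the detection pipeline never calls it.
#'
#' @param p,q [density_spec()] objects.
#' @param m the scaling measure: either a [density_spec()] (e.g. a covering
#'   uniform) or a numeric mixture weight `alpha` in `[0, 1]`, meaning
#'   `m = alpha * p + (1 - alpha) * q`.
#' @param rel_tol relative tolerance passed to the adaptive quadrature.
#' @return The divergence value (non-negative up to quadrature error).
#' @export
plsbd_quadrature <- function(p, q, m = 0.5, rel_tol = 1e-10) {
  dp <- pdf_fun(p); dq <- pdf_fun(q)
  rng <- range(spec_range(p), spec_range(q))
  landmarks <- c(spec_landmarks(p), spec_landmarks(q))
  if (is.numeric(m)) {
    if (length(m) != 1L || m < 0 || m > 1) stop("mixture weight must be in [0, 1]")
    a <- m
    dm <- function(y) a * dp(y) + (1 - a) * dq(y)
  } else {
    stopifnot(inherits(m, "density_spec"))
    dm <- pdf_fun(m)
    landmarks <- c(landmarks, spec_landmarks(m))
    if (m$family == "uniform") {
      # outside a uniform scaling measure the integrand is 0/0; require the
      # measure to cover (numerically) all of p's and q's mass
      out_mass <- tail_mass(p, m$lower, m$upper) + tail_mass(q, m$lower, m$upper)
      if (out_mass > 1e-12) {
        stop("scaling measure 'm' vanishes where p != q: divergent integrand")
      }
      rng <- c(m$lower, m$upper)
    }
  }
  f <- function(y) {
    py <- dp(y); qy <- dq(y); my <- dm(y)
    num <- 0.5 * (py - qy)^2
    out <- ifelse(my > 0, num / ifelse(my > 0, my, 1), 0)
    if (any(num[my == 0] > 0)) stop("scaling measure vanishes where p != q")
    out
  }
  piecewise_integrate(f, rng[1L], rng[2L], landmarks, rel_tol)
}

#' Alpha-relative Pearson divergence by numerical quadrature
#'
#' Oracle for \eqn{D_{\alpha PE}(p \| q_\alpha) = \frac12 \int q_\alpha(y)
#' (p(y)/q_\alpha(y) - 1)^2 dy} with \eqn{q_\alpha = \alpha p + (1-\alpha) q},
#' the RuLSIF objective. Used in tests of the lower-bound relation to the
#' Pearson-like scaled Bregman divergence.
#'
#' @inheritParams plsbd_quadrature
#' @param alpha mixture weight in `[0, 1]`. `alpha = 0` gives the ordinary
#'   Pearson divergence (which may diverge for well-separated densities).
#' @return The divergence value.
#' @export
alpha_pearson_quadrature <- function(p, q, alpha = 0.5, rel_tol = 1e-10) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("'alpha' must be in [0, 1]")
  }
  dp <- pdf_fun(p); dq <- pdf_fun(q)
  rng <- range(spec_range(p), spec_range(q))
  landmarks <- c(spec_landmarks(p), spec_landmarks(q))
  f <- function(y) {
    py <- dp(y); qy <- dq(y)
    qa <- alpha * py + (1 - alpha) * qy
    num <- 0.5 * (py - qa)^2
    out <- ifelse(qa > 0, num / ifelse(qa > 0, qa, 1), 0)
    if (any(num[qa == 0] > 0)) stop("mixture density vanishes where p > 0")
    out
  }
  piecewise_integrate(f, rng[1L], rng[2L], landmarks, rel_tol)
}
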