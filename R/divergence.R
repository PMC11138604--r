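#' Gaussian kernel between two vectors
#'
#' Computes \eqn{K(u, v) = \exp(-\|u - v\|^2 / (2\sigma^2))}, the radial
#' basis kernel used throughout the density-ratio model.
#'
#' @param u,v numeric vectors of equal length.
#' @param sigma positive bandwidth.
#' @return A scalar in `(0, 1]`; exactly 1 iff `u == v`.
#' @examples
#' gaussian_kernel(c(0, 0), c(3, 4), 5)  # exp(-0.5)
#' @export
gaussian_kernel <- function(u, v, sigma) {
  if (length(u) != length(v)) stop("'u' and 'v' must have the same length")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("'sigma' must be a positive number")
  }
  exp(-sum((u - v)^2) / (2 * sigma^2))
}

#' Gaussian kernel matrix between samples and centers
#'
#' @param x n_s x D matrix of samples (rows).
#' @param centers n_c x D matrix of kernel centers (rows).
#' @param sigma positive bandwidth.
#' @return n_s x n_c matrix with entry (i, l) = `gaussian_kernel(x[i, ], centers[l, ], sigma)`.
#' @export
kernel_matrix <- function(x, centers, sigma) {
  x <- rbind(x); centers <- rbind(centers)
  storage.mode(x) <- "double"; storage.mode(centers) <- "double"
  if (ncol(x) != ncol(centers)) stop("samples and centers must have the same dimension")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("'sigma' must be a positive number")
  }
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Mean kernel vector h-hat
#'
#' Column means of the kernel matrix of the p-segment samples against the
#' centers: the linear term of the least-squares ratio-fitting objective.
#'
#' @param Kp n_p x n_c kernel matrix.
#' @return Length-n_c numeric vector.
#' @export
build_h_hat <- function(Kp) {
  Kp <- rbind(Kp)
  if (nrow(Kp) < 1L || ncol(Kp) < 1L) stop("'Kp' must be a non-empty matrix")
  colMeans(Kp)
}

#' Weighted Gram matrix H-hat
#'
#' The quadratic term of the ratio-fitting objective under the mixture
#' measure: `alpha * crossprod(Kp)/n_p + (1 - alpha) * crossprod(Kq)/n_q`.
#' Exactly symmetric and positive semi-definite.
#'
#' @param Kp,Kq kernel matrices of the p- and q-segment samples against a
#'   shared set of centers.
#' @param alpha mixture weight in `[0, 1]`.
#' @return n_c x n_c symmetric PSD matrix.
#' @export
build_H_hat <- function(Kp, Kq, alpha) {
  Kp <- rbind(Kp); Kq <- rbind(Kq)
  if (ncol(Kp) != ncol(Kq)) stop("'Kp' and 'Kq' must have the same number of columns")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("'alpha' must be in [0, 1]")
  }
  alpha * crossprod(Kp) / nrow(Kp) + (1 - alpha) * crossprod(Kq) / nrow(Kq)
}

#' Ridge-regularized solve for the kernel coefficients
#'
#' Solves `(H + lam * I) theta = h` by a symmetric positive-definite
#' Cholesky factorization (no explicit inverse). With `H` PSD and
#' `lam > 0` the solution is unique.
#'
#' @param H symmetric PSD matrix.
#' @param h right-hand-side vector.
#' @param lam positive ridge weight.
#' @return Coefficient vector `theta`.
#' @export
solve_theta <- function(H, h, lam) {
  H <- rbind(H)
  if (!all(is.finite(H)) || !all(is.finite(h))) stop("non-finite entries in 'H' or 'h'")
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    stop("'lam' must be a positive number")
  }
  A <- H + diag(lam, nrow(H))
  R <- chol(A)
  backsolve(R, backsolve(R, h, transpose = TRUE))
}

#' Evaluate a fitted density-ratio model at new points
#'
#' The kernel expansion \eqn{\hat r_\alpha(y) = \sum_l \theta_l K(y, c_l)}.
#' Values may be negative: the ridge solution is not constrained to be
#' non-negative (see [density_ratio()] and its `clip_ratios` option).
#'
#' @param model a list with elements `centers`, `sigma`, `theta` (as
#'   returned by [density_ratio()]).
#' @param points m x D matrix of evaluation points.
#' @return Length-m numeric vector of ratio values.
#' @export
evaluate_ratio <- function(model, points) {
  K <- kernel_matrix(points, model$centers, model$sigma)
  drop(K %*% model$theta)
}

#' Plug-in Pearson-like scaled Bregman divergence from ratio values
#'
#' Empirical estimate of the divergence from fitted relative density-ratio
#' values at the two segments:
#' \deqn{\hat D_{PL} = \frac{1}{2}\left(\bar r_p - \bar r_q\right) +
#'   \frac{1 - \bar r_q}{2(1-\alpha)},}
#' an algebraically equivalent grouping of
#' \eqn{\frac{1}{2 n_p}\sum_i \hat r_\alpha(y_i^p) -
#'  \frac{2-\alpha}{2(1-\alpha) n_q}\sum_j \hat r_\alpha(y_j^q) +
#'  \frac{1}{2(1-\alpha)}} that returns exactly 0 when all ratios are 1.
#'
#' @param rp,rq fitted ratio values at the p-segment and q-segment samples.
#' @param alpha mixture weight in `[0, 1)`; `alpha = 1` is rejected (the
#'   plug-in divides by `1 - alpha`).
#' @return The divergence estimate (may be negative for poor fits).
#' @seealso [alpha_pearson_score()] for the RuLSIF/uLSIF baseline score.
#' @export
plsbd_score <- function(rp, rq, alpha) {
  check_ratios(rp, rq, alpha)
  0.5 * (mean(rp) - mean(rq)) + (1 - mean(rq)) / (2 * (1 - alpha))
}

#' Plug-in alpha-relative Pearson divergence from ratio values
#'
#' First-moment plug-in of the alpha-relative Pearson divergence,
#' \eqn{\hat D_{\alpha PE} = \frac{1}{2 n_p}\sum_i \hat r_\alpha(y_i^p) - \frac12}.
#' Satisfies the exact identity
#' `plsbd_score(rp, rq, a) == alpha_pearson_score(rp) +
#'  (2 - a) / (2 * (1 - a)) * (1 - mean(rq))`,
#' i.e. the alpha-relative Pearson divergence (after an offset) lower-bounds
#' the Pearson-like scaled Bregman divergence. With `alpha = 0` this is the
#' ordinary Pearson-divergence plug-in used by uLSIF.
#'
#' @param rp fitted ratio values at the p-segment samples.
#' @param rq,alpha accepted (and validated when supplied) for interface
#'   symmetry with [plsbd_score()]; the estimate itself only involves `rp`.
#' @return The divergence estimate.
#' @export
alpha_pearson_score <- function(rp, rq = NULL, alpha = 0) {
  if (!is.null(rq)) check_ratios(rp, rq, alpha) else check_ratios(rp, rp, alpha)
  0.5 * mean(rp) - 0.5
}

check_ratios <- function(rp, rq, alpha) {
  if (length(rp) < 1L || length(rq) < 1L) stop("ratio vectors must be non-empty")
  if (!all(is.finite(rp)) || !all(is.finite(rq))) stop("ratio values must be finite")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1) {
    stop("'alpha' must be in [0, 1): the plug-in divides by 1 - alpha")
  }
  invisible(TRUE)
}
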