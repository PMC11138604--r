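#' Median-heuristic kernel bandwidth
#'
#' Median of the pairwise Euclidean distances among the samples, the
#' standard reference scale for Gaussian-kernel bandwidth grids. For more
#' than 2000 pairs a seeded random subsample of 2000 pairs is used.
#'
#' @param x n x D sample matrix (rows = samples).
#' @param seed seed for the pair subsample (only consulted when n(n-1)/2 >
#'   2000).
#' @return Positive scalar.
#' @export
median_heuristic <- function(x, seed = 1L) {
  x <- rbind(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples")
  n_pairs <- n * (n - 1) / 2
  if (n_pairs <= 2000) {
    d <- as.vector(dist(x))
  } else {
    d <- with_seed(seed, {
      i <- sample.int(n, 2000L, replace = TRUE)
      j <- sample.int(n - 1L, 2000L, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)
      sqrt(rowSums((x[i, , drop = FALSE] - x[j, , drop = FALSE])^2))
    })
  }
  m <- median(d)
  if (m <= 0) {
    stop("all samples are identical (median pairwise distance is 0); supply a fixed 'sigma_grid'")
  }
  m
}

#' Choose kernel centers for the ratio model
#'
#' Deterministic rule: take the p-segment samples first (in order), then
#' fill the remaining slots with q-segment samples in seeded random order,
#' without replacement, up to `min(n_basis, n_p + n_q)` centers.
#'
#' @param yp,yq p- and q-segment sample matrices.
#' @param n_basis requested number of centers.
#' @param seed seed for the q-sample shuffle.
#' @return n_c x D matrix of centers.
#' @export
choose_centers <- function(yp, yq, n_basis = 50L, seed = 1L) {
  yp <- rbind(yp); yq <- rbind(yq)
  if (nrow(yp) < 1L) stop("'yp' must contain at least one sample")
  n_basis <- as.integer(n_basis)
  if (n_basis < 1L) stop("'n_basis' must be >= 1")
  n_c <- min(n_basis, nrow(yp) + nrow(yq))
  if (n_c <= nrow(yp)) return(yp[seq_len(n_c), , drop = FALSE])
  extra <- n_c - nrow(yp)
  ord <- with_seed(seed, sample.int(nrow(yq)))
  rbind(yp, yq[ord[seq_len(extra)], , drop = FALSE])
}

#' Held-out least-squares objective for the ratio fit
#'
#' `J(theta) = 0.5 * t(theta) %*% H %*% theta - t(h) %*% theta`, the
#' least-squares ratio-matching loss evaluated on held-out `H`, `h`
#' (ridge penalty excluded at evaluation). Smaller is better.
#'
#' @param theta coefficient vector.
#' @param H held-out Gram matrix ([build_H_hat()]).
#' @param h held-out mean kernel vector ([build_h_hat()]).
#' @return Scalar objective value.
#' @export
cv_objective <- function(theta, H, h) {
  theta <- as.numeric(theta); h <- as.numeric(h)
  drop(0.5 * crossprod(theta, rbind(H) %*% theta) - crossprod(h, theta))
}

assign_folds <- function(n, n_folds, seed) {
  with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
}

resolve_grids <- function(yp, yq, sigma_grid, sigma_rel, lambda_grid, seed) {
  if (is.null(sigma_grid)) {
    sigma_grid <- sigma_rel * median_heuristic(rbind(yp, yq), seed = seed)
  }
  if (any(sigma_grid <= 0) || any(lambda_grid <= 0)) {
    stop("'sigma_grid' and 'lambda_grid' must be positive")
  }
  list(sigma = sort(unique(as.numeric(sigma_grid))),
       lambda = sort(unique(as.numeric(lambda_grid))))
}

#' Select kernel bandwidth and ridge weight by cross-validation
#'
#' Grid search over `(sigma, lambda)` by n-fold cross-validation. The p- and
#' q-segment samples are partitioned into folds separately (so every fold
#' contains both kinds); for each grid point the coefficients are fitted on
#' the training folds and scored with [cv_objective()] on the held-out
#' fold's Gram objects, averaged over folds. Ties are broken toward the
#' smaller `sigma`, then the smaller `lambda` (smoother, more regularized
#' models). Kernel centers are held fixed across the grid.
#'
#' @param yp,yq segment sample matrices.
#' @param centers kernel centers (e.g. from [choose_centers()]).
#' @param alpha mixture weight.
#' @param sigma_grid absolute bandwidth grid.
#' @param lambda_grid ridge-weight grid.
#' @param n_folds number of folds; silently reduced to `min(n_p, n_q)` when
#'   the segments are smaller (with a warning).
#' @param seed seed for the fold assignment.
#' @return A list with `sigma`, `lambda` (the selected values) and `cv`, the
#'   matrix of mean held-out objectives (rows = sigma, columns = lambda).
#' @export
select_hyperparams <- function(yp, yq, centers, alpha = 0.5,
                               sigma_grid, lambda_grid, n_folds = 5L, seed = 1L) {
  fit <- cv_fit_internal(rbind(yp), rbind(yq), rbind(centers), alpha,
                         sort(unique(as.numeric(sigma_grid))),
                         sort(unique(as.numeric(lambda_grid))), n_folds, seed)
  list(sigma = fit$sigma, lambda = fit$lambda, cv = fit$cv)
}

cv_fit_internal <- function(yp, yq, centers, alpha, sigmas, lambdas, n_folds, seed) {
  np <- nrow(yp); nq <- nrow(yq)
  n_folds <- as.integer(n_folds)
  nf <- min(n_folds, np, nq)
  if (nf < n_folds && length(sigmas) * length(lambdas) > 1L) {
    warning(sprintf("reducing cross-validation folds from %d to %d (segment sizes %d, %d)",
                    n_folds, nf, np, nq), call. = FALSE)
  }
  fold_p <- assign_folds(np, max(nf, 1L), derive_seed(seed, 1L)) - 1L
  fold_q <- assign_folds(nq, max(nf, 1L), derive_seed(seed, 2L)) - 1L
  res <- cv_fit_cpp(yp, yq, centers, sigmas, lambdas, alpha,
                    as.integer(fold_p), as.integer(fold_q), nf)
  cv <- res$cv
  dimnames(cv) <- list(signif(sigmas, 6), signif(lambdas, 6))
  list(sigma = sigmas[res$sigma_index], lambda = lambdas[res$lambda_index],
       theta = drop(res$theta), rp = drop(res$rp), rq = drop(res$rq),
       cv = cv, residual = res$residual)
}

#' Fit a kernel ridge density-ratio model for one segment pair
#'
#' Fits the relative density-ratio model
#' \eqn{\hat r_\alpha(y) = \sum_l \theta_l K(y, c_l)} between a "p" segment
#' and a "q" segment by regularized least squares against the mixture
#' measure \eqn{m_\alpha = \alpha p + (1 - \alpha) q}. Bandwidth and ridge
#' weight are selected by cross-validation (see [select_hyperparams()]),
#' then the model is refitted on all samples at the selected values.
#'
#' @param yp samples from the p distribution (matrix, rows = samples; a
#'   numeric vector is treated as one-dimensional samples).
#' @param yq samples from the q distribution.
#' @param alpha mixture weight in `[0, 1)`. `alpha = 0` estimates the plain
#'   ratio p/q (the uLSIF model).
#' @param n_basis number of kernel centers (default 50).
#' @param n_folds cross-validation folds (default 5).
#' @param sigma_grid absolute bandwidth grid, or `NULL` to use
#'   `sigma_rel * median_heuristic(rbind(yp, yq))`.
#' @param sigma_rel relative bandwidth multipliers (default
#'   `c(0.6, 0.8, 1, 1.2, 1.4)`).
#' @param lambda_grid ridge-weight grid (default `10^(-3:0)`).
#' @param seed seed governing center choice, fold assignment and the
#'   median-heuristic pair subsample.
#' @param clip_ratios floor fitted ratio values at 0. Off by default: the
#'   ridge solution can legitimately go negative and clipping would break
#'   the exact lower-bound identity between the two plug-in scores.
#' @return An object of class `"density_ratio"`: a list with `centers`,
#'   `sigma`, `lambda`, `theta`, `alpha`, fitted ratio values `rp`, `rq`,
#'   and the cross-validation table `cv`. Methods: [coef()], [predict()],
#'   [print()].
#' @examples
#' yp <- matrix(rnorm(50, 2), ncol = 1)
#' yq <- matrix(rnorm(50, 0), ncol = 1)
#' fit <- density_ratio(yp, yq, alpha = 0.5, seed = 7)
#' plsbd_score(fit$rp, fit$rq, fit$alpha)
#' @export
density_ratio <- function(yp, yq, alpha = 0.5, n_basis = 50L, n_folds = 5L,
                          sigma_grid = NULL, sigma_rel = c(0.6, 0.8, 1, 1.2, 1.4),
                          lambda_grid = 10^(-3:0), seed = 1L, clip_ratios = FALSE) {
  if (is.vector(yp) && is.numeric(yp)) yp <- matrix(yp, ncol = 1L)
  if (is.vector(yq) && is.numeric(yq)) yq <- matrix(yq, ncol = 1L)
  yp <- rbind(yp); yq <- rbind(yq)
  storage.mode(yp) <- "double"; storage.mode(yq) <- "double"
  if (ncol(yp) != ncol(yq)) stop("'yp' and 'yq' must have the same dimension")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1) {
    stop("'alpha' must be in [0, 1)")
  }
  grids <- resolve_grids(yp, yq, sigma_grid, sigma_rel, lambda_grid,
                         derive_seed(seed, 3L))
  centers <- choose_centers(yp, yq, n_basis, derive_seed(seed, 4L))
  fit <- cv_fit_internal(yp, yq, centers, alpha, grids$sigma, grids$lambda,
                         n_folds, seed)
  rp <- fit$rp; rq <- fit$rq
  if (clip_ratios) {
    rp <- pmax(rp, 0); rq <- pmax(rq, 0)
  }
  structure(list(centers = centers, sigma = fit$sigma, lambda = fit$lambda,
                 theta = fit$theta, alpha = alpha, rp = rp, rq = rq,
                 cv = fit$cv, residual = fit$residual,
                 n_p = nrow(yp), n_q = nrow(yq), clip_ratios = clip_ratios,
                 call = match.call()),
            class = "density_ratio")
}

#' @export
coef.density_ratio <- function(object, ...) object$theta

#' Evaluate a fitted density-ratio model
#'
#' @param object a [density_ratio()] fit.
#' @param newdata m x D matrix of points (defaults to the p-segment fitted
#'   values).
#' @param ... unused.
#' @return Numeric vector of ratio values.
#' @export
predict.density_ratio <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$rp)
  if (is.vector(newdata) && is.numeric(newdata)) {
    newdata <- matrix(newdata, ncol = ncol(object$centers))
  }
  r <- evaluate_ratio(object, newdata)
  if (isTRUE(object$clip_ratios)) r <- pmax(r, 0)
  r
}

#' @export
print.density_ratio <- function(x, ...) {
  cat("Kernel ridge density-ratio model\n")
  cat(sprintf("  alpha = %g, %d centers, sigma = %.4g, lambda = %.4g\n",
              x$alpha, nrow(x$centers), x$sigma, x$lambda))
  cat(sprintf("  segments: n_p = %d, n_q = %d; solve residual = %.2e\n",
              x$n_p, x$n_q, x$residual))
  cat(sprintf("  plug-in PLsBD score: %.5g\n",
              plsbd_score(x$rp, x$rq, x$alpha)))
  invisible(x)
}
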