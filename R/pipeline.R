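#' Sliding-window (Hankel) embedding of a time series
#'
#' Stacks `k` consecutive d-dimensional observations into one
#' `k * d`-dimensional sample per window start, so each embedded sample
#' captures local dynamics. Row `t` is the concatenation
#' `(y(t), y(t+1), ..., y(t+k-1))`, covariate-major within each time step.
#'
#' @param x time series: numeric vector, T x d matrix or data frame.
#' @param k window (subsequence) length.
#' @return `(T - k + 1) x (k * d)` matrix; row `t` depends only on times
#'   `t..t+k-1`.
#' @examples
#' embed_subsequences(c(1, 2, 3, 4), 2)  # rows (1,2), (2,3), (3,4)
#' @export
embed_subsequences <- function(x, k) {
  x <- as_series(x)
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  T_len <- nrow(x); d <- ncol(x)
  if (k > T_len) stop(sprintf("window length k = %d exceeds series length T = %d", k, T_len))
  n <- T_len - k + 1L
  out <- matrix(0, n, k * d)
  for (j in seq_len(k)) {
    out[, ((j - 1L) * d + 1L):(j * d)] <- x[j:(j + n - 1L), , drop = FALSE]
  }
  out
}

#' Extract the past/future segment pair at a reference point
#'
#' At reference point `t` the "q" segment is the `step` embedded samples
#' immediately before `t` and the "p" segment the `step` samples starting at
#' `t`, so the divergence at `t` contrasts the post-`t` distribution against
#' the pre-`t` one. The two index ranges are disjoint.
#'
#' @param samples embedded sample matrix from [embed_subsequences()].
#' @param t reference row index; must satisfy
#'   `step + 1 <= t <= nrow(samples) - step + 1`.
#' @param step number of samples per segment (`n_p = n_q = step`).
#' @return A list with matrices `yq` (rows `t-step .. t-1`) and `yp` (rows
#'   `t .. t+step-1`).
#' @export
segment_pair_at <- function(samples, t, step) {
  samples <- rbind(samples)
  t <- as.integer(t); step <- as.integer(step)
  if (step < 1L) stop("'step' must be >= 1")
  n <- nrow(samples)
  if (t < step + 1L || t > n - step + 1L) {
    stop(sprintf("reference point t = %d outside valid range [%d, %d]",
                 t, step + 1L, n - step + 1L))
  }
  list(yq = samples[(t - step):(t - 1L), , drop = FALSE],
       yp = samples[t:(t + step - 1L), , drop = FALSE])
}

#' Divergence score series along a time series
#'
#' Slides a reference point along the embedded series and, at each valid
#' point, fits the density-ratio model between the `step` subsequences
#' after and before it, then scores the configured divergence:
#' the Pearson-like scaled Bregman plug-in (`method = "plsbd"`), the
#' alpha-relative Pearson plug-in (`"rulsif"`), or the Pearson plug-in at
#' `alpha = 0` (`"ulsif"`).
#'
#' @param x time series (vector, T x d matrix or data frame).
#' @param method scoring divergence.
#' @param alpha mixture weight; forced to 0 for `method = "ulsif"`.
#' @param window subsequence length `k` for the embedding (default 5).
#' @param step samples per segment on each side of the reference point
#'   (default 50).
#' @param stride spacing between consecutive reference points (default 1).
#' @param symmetric also fit with the segment roles exchanged and add the
#'   two scores (default `FALSE`, forward-only).
#' @param n_basis,n_folds,sigma_grid,sigma_rel,lambda_grid,clip_ratios
#'   passed to [density_ratio()].
#' @param seed master seed; each reference point uses a sub-seed derived by
#'   a counter scheme, so scores do not depend on evaluation order.
#' @return A data frame with columns `t` (reference time, 1-based, equal to
#'   the start time of the first post-change subsequence) and `score`, with
#'   the configuration stored in attributes.
#' @export
score_series <- function(x, method = c("plsbd", "rulsif", "ulsif"), alpha = 0.5,
                         window = 5L, step = 50L, stride = 1L, symmetric = FALSE,
                         n_basis = 50L, n_folds = 5L,
                         sigma_grid = NULL, sigma_rel = c(0.6, 0.8, 1, 1.2, 1.4),
                         lambda_grid = 10^(-3:0), clip_ratios = FALSE, seed = 1L) {
  method <- match.arg(method)
  x <- as_series(x)
  window <- as.integer(window); step <- as.integer(step); stride <- as.integer(stride)
  if (method == "ulsif") alpha <- 0
  if (nrow(x) < window + 2L * step) {
    stop(sprintf("series too short: need T >= k + 2*step = %d, have %d",
                 window + 2L * step, nrow(x)))
  }
  E <- embed_subsequences(x, window)
  t_seq <- seq.int(step + 1L, nrow(E) - step + 1L, by = stride)
  one_score <- function(yp, yq, sub_seed) {
    fit <- density_ratio(yp, yq, alpha = alpha, n_basis = n_basis,
                         n_folds = n_folds, sigma_grid = sigma_grid,
                         sigma_rel = sigma_rel, lambda_grid = lambda_grid,
                         seed = sub_seed, clip_ratios = clip_ratios)
    if (method == "plsbd") plsbd_score(fit$rp, fit$rq, fit$alpha)
    else alpha_pearson_score(fit$rp, fit$rq, fit$alpha)
  }
  score <- vapply(t_seq, function(t) {
    seg <- segment_pair_at(E, t, step)
    s <- one_score(seg$yp, seg$yq, derive_seed(seed, t))
    if (symmetric) s <- s + one_score(seg$yq, seg$yp, derive_seed(seed, t + nrow(E)))
    s
  }, numeric(1))
  out <- data.frame(t = t_seq, score = score)
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  attr(out, "config") <- list(window = window, step = step, stride = stride,
                              symmetric = symmetric, n_basis = n_basis,
                              n_folds = n_folds, seed = seed)
  out
}

#' Extract change-point candidates from a score series
#'
#' Default thresholding follows the fraction-of-max rule: a reference point
#' is a candidate when its score reaches `eta * max(score)`. Maximal runs of
#' consecutive candidate points form candidate regions; runs separated by
#' fewer than `min_gap` reference points are merged, and each region is
#' summarized by its peak (first index on exact ties).
#'
#' An alternative `threshold_mode = "quantile"` uses the empirical
#' `eta`-quantile of the scores instead. Note that fraction-of-max
#' thresholding is relative: it flags at least one candidate even on
#' stationary data, so a warning is emitted unless an absolute
#' `score_floor` is supplied.
#'
#' @param scores a data frame with columns `t` and `score` (as returned by
#'   [score_series()]), or a numeric score vector.
#' @param eta threshold fraction in `(0, 1)`.
#' @param min_gap merge candidate runs separated by fewer than this many
#'   reference points.
#' @param threshold_mode `"maxfrac"` (default) or `"quantile"`.
#' @param score_floor optional absolute score floor; points below it are
#'   never candidates.
#' @param t reference time points when `scores` is a bare numeric vector.
#' @return A data frame with one row per candidate region: `peak`,
#'   `run_start`, `run_end` (reference times) and `score` (the peak score),
#'   sorted by peak time, with the threshold in `attr(, "threshold")`.
#' @export
detect_candidates <- function(scores, eta = 0.9, min_gap = 1L,
                              threshold_mode = c("maxfrac", "quantile"),
                              score_floor = NULL, t = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (is.data.frame(scores)) {
    t <- scores$t
    s <- scores$score
  } else {
    s <- as.numeric(scores)
    if (is.null(t)) t <- seq_along(s)
  }
  if (length(s) == 0L) stop("empty score series")
  if (!is.numeric(eta) || eta <= 0 || eta >= 1) stop("'eta' must be in (0, 1)")
  tau <- if (threshold_mode == "maxfrac") eta * max(s) else unname(quantile(s, eta))
  if (threshold_mode == "maxfrac" && is.null(score_floor)) {
    warning(paste("fraction-of-max thresholding is relative and flags at least",
                  "one candidate even on stationary data; supply 'score_floor'",
                  "or use threshold_mode = \"quantile\" if this matters"),
            call. = FALSE)
  }
  above <- s >= tau
  if (!is.null(score_floor)) above <- above & (s >= score_floor)
  if (all(above)) {
    warning("all scores are at or above the threshold: a single run spans the whole series",
            call. = FALSE)
  }
  runs <- score_runs(above)
  if (nrow(runs) > 1L && min_gap > 1L) {
    merged <- runs[1L, , drop = FALSE]
    for (i in 2L:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap < min_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
  }
  if (nrow(runs) == 0L) {
    out <- data.frame(peak = numeric(0), run_start = numeric(0),
                      run_end = numeric(0), score = numeric(0))
  } else {
    out <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
      idx <- runs$start[i]:runs$end[i]
      pk <- idx[which.max(s[idx])]
      data.frame(peak = t[pk], run_start = t[runs$start[i]],
                 run_end = t[runs$end[i]], score = s[pk])
    }))
  }
  attr(out, "threshold") <- tau
  attr(out, "threshold_mode") <- threshold_mode
  out
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end) indices
score_runs <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Sliding-window change-point detection
#'
#' The main detector: embeds the series ([embed_subsequences()]), scores
#' every reference point with the configured divergence ([score_series()]),
#' and extracts threshold-exceeding candidate regions
#' ([detect_candidates()]).
#'
#' @inheritParams score_series
#' @param eta threshold fraction in `(0, 1)` (default 0.9).
#' @param min_gap merge distance for candidate runs (default `window`).
#' @param threshold_mode,score_floor see [detect_candidates()].
#' @return An object of class `"plsbd"`: a list with the score series
#'   (`$scores`), the candidate table (`$candidates`), the threshold, and
#'   the full configuration. Methods: [print()], [summary()], [plot()].
#' @examples
#' \donttest{
#' sim <- simulate_gauss_segments(seed = 1)
#' cp <- plsbd(sim$x, alpha = 0.5, seed = 1)
#' cp$candidates
#' }
#' @export
plsbd <- function(x, method = c("plsbd", "rulsif", "ulsif"), alpha = 0.5,
                  window = 5L, step = 50L, eta = 0.9, stride = 1L,
                  symmetric = FALSE, min_gap = window,
                  threshold_mode = c("maxfrac", "quantile"), score_floor = NULL,
                  n_basis = 50L, n_folds = 5L,
                  sigma_grid = NULL, sigma_rel = c(0.6, 0.8, 1, 1.2, 1.4),
                  lambda_grid = 10^(-3:0), clip_ratios = FALSE, seed = 1L) {
  method <- match.arg(method)
  threshold_mode <- match.arg(threshold_mode)
  scores <- score_series(x, method = method, alpha = alpha, window = window,
                         step = step, stride = stride, symmetric = symmetric,
                         n_basis = n_basis, n_folds = n_folds,
                         sigma_grid = sigma_grid, sigma_rel = sigma_rel,
                         lambda_grid = lambda_grid, clip_ratios = clip_ratios,
                         seed = seed)
  cand <- detect_candidates(scores, eta = eta, min_gap = min_gap,
                            threshold_mode = threshold_mode,
                            score_floor = score_floor)
  structure(list(scores = scores, candidates = cand,
                 threshold = attr(cand, "threshold"),
                 method = method, alpha = attr(scores, "alpha"),
                 config = c(attr(scores, "config"),
                            list(eta = eta, min_gap = min_gap,
                                 threshold_mode = threshold_mode,
                                 score_floor = score_floor)),
                 series_dim = dim(as_series(x)),
                 call = match.call()),
            class = "plsbd")
}

#' @export
print.plsbd <- function(x, ...) {
  cat(sprintf("Change-point detection (%s, alpha = %g)\n", x$method, x$alpha))
  cat(sprintf("  series: %d time points x %d covariate(s); window k = %d, step = %d\n",
              x$series_dim[1], x$series_dim[2], x$config$window, x$config$step))
  cat(sprintf("  %d reference points scored; threshold = %.4g (%s, eta = %g)\n",
              nrow(x$scores), x$threshold, x$config$threshold_mode, x$config$eta))
  cat(sprintf("  %d candidate region(s):\n", nrow(x$candidates)))
  if (nrow(x$candidates)) print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' @export
summary.plsbd <- function(object, ...) {
  s <- object$scores$score
  out <- list(method = object$method, alpha = object$alpha,
              n_scored = length(s),
              score_range = range(s), score_mean = mean(s),
              threshold = object$threshold,
              candidates = object$candidates, config = object$config)
  class(out) <- "summary.plsbd"
  out
}

#' @export
print.summary.plsbd <- function(x, ...) {
  cat(sprintf("Method %s (alpha = %g): %d reference points\n",
              x$method, x$alpha, x$n_scored))
  cat(sprintf("  scores in [%.4g, %.4g], mean %.4g; threshold %.4g\n",
              x$score_range[1], x$score_range[2], x$score_mean, x$threshold))
  cat(sprintf("  %d candidate region(s)\n", nrow(x$candidates)))
  if (nrow(x$candidates)) print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' Plot a dissimilarity score series with detected candidates
#'
#' @param x a [plsbd()] object.
#' @param truth optional vector of true change times, drawn as vertical
#'   dashed lines.
#' @param ... passed to the underlying [plot()].
#' @export
plot.plsbd <- function(x, truth = NULL, ...) {
  sc <- x$scores
  plot(sc$t, sc$score, type = "l", xlab = "time", ylab = "dissimilarity score",
       main = sprintf("%s score (alpha = %g)", x$method, x$alpha), ...)
  abline(h = x$threshold, lty = 3, col = "grey40")
  if (nrow(x$candidates)) {
    usr <- par("usr")
    rect(x$candidates$run_start, usr[3], x$candidates$run_end, usr[4],
         col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
    points(x$candidates$peak, x$candidates$score, pch = 19, col = "steelblue")
  }
  if (!is.null(truth)) abline(v = truth, lty = 2, col = "firebrick")
  invisible(x)
}
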