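#' Random covariate-subsampling change-point detection
#'
#' High-dimensional extension of [plsbd()]: in matrices with many covariates
#' of which only a few shift (the typical omics regime), non-changing
#' covariates dilute the divergence signal. This routine repeatedly draws a
#' small random subset of covariates, runs the full detector on the
#' restricted matrix, and aggregates two summaries across iterations: a
#' per-time-point frequency (how often each reference point fell inside a
#' candidate region) and the mean score series. High-frequency time
#' intervals are then extracted with [frequency_intervals()].
#'
#' Iterations are independent given per-iteration seeds derived from the
#' master seed by a counter scheme, so results do not depend on execution
#' order. Per-iteration hyperparameter cross-validation is re-run on every
#' subset by default; `reuse_hyperparams = TRUE` selects `(sigma, lambda)`
#' once per iteration (at the first reference point) and reuses them along
#' the series.
#'
#' @inheritParams plsbd
#' @param n_samples number of random subsets (default 300).
#' @param subset_size covariates per iteration: a single integer, or an
#'   inclusive range `c(lo, hi)` from which the size is drawn uniformly
#'   (default `c(3, 5)`).
#' @param gamma frequency-interval fraction for [frequency_intervals()]
#'   (default 0.5).
#' @param peak_only count only the candidate peak (not the whole run) into
#'   the frequency histogram (default `FALSE`).
#' @param reuse_hyperparams fast mode: select `(sigma, lambda)` once per
#'   iteration instead of at every reference point.
#' @return An object of class `"plsbd_sampling"`: a list with `frequency`
#'   (data frame `t`, `frequency`, `mean_score`), `intervals` (from
#'   [frequency_intervals()]), `per_iteration` (candidate tables and the
#'   covariate subsets), and the configuration.
#' @export
plsbd_sample <- function(x, n_samples = 300L, subset_size = c(3L, 5L),
                         method = c("plsbd", "rulsif", "ulsif"), alpha = 0.5,
                         window = 8L, step = 5L, eta = 0.9, stride = 1L,
                         min_gap = window, gamma = 0.5, peak_only = FALSE,
                         n_basis = 50L, n_folds = 5L,
                         sigma_rel = c(0.6, 0.8, 1, 1.2, 1.4),
                         lambda_grid = 10^(-3:0), clip_ratios = FALSE,
                         reuse_hyperparams = FALSE, seed = 1L) {
  method <- match.arg(method)
  x <- as_series(x)
  d <- ncol(x)
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("'n_samples' must be >= 1")
  subset_size <- as.integer(subset_size)
  if (any(subset_size < 1L) || any(subset_size > d)) {
    stop(sprintf("'subset_size' must be within [1, d = %d]", d))
  }
  size_range <- range(subset_size)

  freq <- NULL; mean_score <- NULL; t_seq <- NULL
  per_iteration <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    seed_i <- derive_seed(seed, i)
    pick <- with_seed(seed_i, {
      sz <- if (size_range[1] == size_range[2]) size_range[1] else
        sample(size_range[1]:size_range[2], 1L)
      sort(sample.int(d, sz))
    })
    res <- iteration_detect(x[, pick, drop = FALSE], method, alpha, window,
                            step, eta, stride, min_gap, n_basis, n_folds,
                            sigma_rel, lambda_grid, clip_ratios,
                            reuse_hyperparams, seed_i)
    if (is.null(freq)) {
      t_seq <- res$scores$t
      freq <- integer(length(t_seq))
      mean_score <- numeric(length(t_seq))
    }
    mean_score <- mean_score + res$scores$score
    hit <- logical(length(t_seq))
    if (nrow(res$candidates)) {
      for (j in seq_len(nrow(res$candidates))) {
        if (peak_only) {
          hit[t_seq == res$candidates$peak[j]] <- TRUE
        } else {
          hit[t_seq >= res$candidates$run_start[j] &
                t_seq <= res$candidates$run_end[j]] <- TRUE
        }
      }
    }
    freq <- freq + hit
    per_iteration[[i]] <- list(subset = pick, candidates = res$candidates)
  }
  mean_score <- mean_score / n_samples
  frequency <- data.frame(t = t_seq, frequency = freq, mean_score = mean_score)
  structure(list(frequency = frequency,
                 intervals = frequency_intervals(frequency, gamma = gamma),
                 per_iteration = per_iteration,
                 config = list(n_samples = n_samples, subset_size = subset_size,
                               method = method, alpha = alpha, window = window,
                               step = step, eta = eta, stride = stride,
                               min_gap = min_gap, gamma = gamma,
                               peak_only = peak_only,
                               reuse_hyperparams = reuse_hyperparams,
                               seed = seed),
                 series_dim = dim(x), call = match.call()),
            class = "plsbd_sampling")
}

# one subsampling iteration: score + candidates, with the relative-threshold
# warning muffled (it would otherwise fire once per iteration)
iteration_detect <- function(xi, method, alpha, window, step, eta, stride,
                             min_gap, n_basis, n_folds, sigma_rel, lambda_grid,
                             clip_ratios, reuse_hyperparams, seed_i) {
  sigma_grid <- NULL
  if (reuse_hyperparams) {
    E <- embed_subsequences(xi, window)
    seg <- segment_pair_at(E, step + 1L, step)
    fit0 <- density_ratio(seg$yp, seg$yq, alpha = if (method == "ulsif") 0 else alpha,
                          n_basis = n_basis, n_folds = n_folds,
                          sigma_rel = sigma_rel, lambda_grid = lambda_grid,
                          seed = seed_i)
    sigma_grid <- fit0$sigma
    lambda_grid <- fit0$lambda
  }
  scores <- score_series(xi, method = method, alpha = alpha, window = window,
                         step = step, stride = stride, n_basis = n_basis,
                         n_folds = n_folds, sigma_grid = sigma_grid,
                         sigma_rel = sigma_rel, lambda_grid = lambda_grid,
                         clip_ratios = clip_ratios, seed = seed_i)
  cand <- withCallingHandlers(
    detect_candidates(scores, eta = eta, min_gap = min_gap),
    warning = function(w) {
      if (grepl("fraction-of-max|whole series", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(scores = scores, candidates = cand)
}

#' High-frequency intervals from a candidate-frequency histogram
#'
#' Maximal runs of consecutive reference points whose frequency reaches
#' `gamma * max(frequency)`, sorted by peak frequency (descending; earlier
#' start breaks ties). These intervals are the change-point output of the
#' covariate-subsampling ensemble.
#'
#' @param frequency a data frame with columns `t` and `frequency` (as in a
#'   `"plsbd_sampling"` object), or a bare numeric frequency vector.
#' @param gamma threshold fraction in `(0, 1]`.
#' @param t reference times when `frequency` is a bare vector.
#' @return A data frame with columns `start`, `end` and `peak_frequency`;
#'   zero rows when all frequencies are zero.
#' @export
frequency_intervals <- function(frequency, gamma = 0.5, t = NULL) {
  if (is.data.frame(frequency)) {
    t <- frequency$t
    f <- frequency$frequency
  } else {
    f <- as.numeric(frequency)
    if (is.null(t)) t <- seq_along(f)
  }
  if (length(f) == 0L) stop("empty frequency vector")
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1) stop("'gamma' must be in (0, 1]")
  if (max(f) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      peak_frequency = numeric(0)))
  }
  runs <- score_runs(f >= gamma * max(f) & f > 0)
  out <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:runs$end[i]
    data.frame(start = t[runs$start[i]], end = t[runs$end[i]],
               peak_frequency = max(f[idx]))
  }))
  out[order(-out$peak_frequency, out$start), , drop = FALSE]
}

#' @export
print.plsbd_sampling <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Covariate-subsampling change-point detection (%s, alpha = %g)\n",
              cfg$method, cfg$alpha))
  cat(sprintf("  series: %d x %d; %d iterations, subset size %s\n",
              x$series_dim[1], x$series_dim[2], cfg$n_samples,
              paste(range(cfg$subset_size), collapse = "-")))
  cat(sprintf("  %d high-frequency interval(s) (gamma = %g):\n",
              nrow(x$intervals), cfg$gamma))
  if (nrow(x$intervals)) print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Plot the candidate-frequency histogram of a subsampling run
#'
#' @param x a `"plsbd_sampling"` object.
#' @param truth optional true change times (vertical dashed lines).
#' @param ... passed to [plot()].
#' @export
plot.plsbd_sampling <- function(x, truth = NULL, ...) {
  fr <- x$frequency
  plot(fr$t, fr$frequency, type = "h", xlab = "time",
       ylab = sprintf("candidate frequency (of %d)", x$config$n_samples),
       main = "change-point candidate frequency", ...)
  if (nrow(x$intervals)) {
    usr <- par("usr")
    rect(x$intervals$start, usr[3], x$intervals$end, usr[4],
         col = grDevices::adjustcolor("steelblue", 0.15), border = NA)
  }
  if (!is.null(truth)) abline(v = truth, lty = 2, col = "firebrick")
  invisible(x)
}
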