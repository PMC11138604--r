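#' Match detected change points against ground truth
#'
#' Greedy one-to-one matching by ascending absolute distance: candidate /
#' truth pairs are considered closest-first, each side used at most once,
#' and a pair counts as a match iff its distance is at most `tol`. Exact
#' distance ties are resolved toward the earlier truth time (then the
#' earlier candidate).
#'
#' @param detected numeric vector of detected change times (e.g. candidate
#'   peaks from [plsbd()]).
#' @param truth numeric vector of true change times.
#' @param tol non-negative matching tolerance (in time points). Detection
#'   localization is smeared by the window length, so benchmark tests use
#'   an explicit tolerance of the order of the window.
#' @return An object of class `"cpd_match"`: a list with `n_true`,
#'   `n_detected`, `n_matched`, a `matches` data frame (`truth`,
#'   `detected`, `distance`), and `unmatched_truth` / `unmatched_detected`.
#' @examples
#' match_changepoints(c(105, 198), c(101, 201), tol = 10)$n_matched  # 2
#' @export
match_changepoints <- function(detected, truth, tol) {
  if (!is.numeric(tol) || length(tol) != 1L || tol < 0) stop("'tol' must be >= 0")
  detected <- as.numeric(detected); truth <- as.numeric(truth)
  nd <- length(detected); nt <- length(truth)
  matches <- data.frame(truth = numeric(0), detected = numeric(0),
                        distance = numeric(0))
  if (nd > 0L && nt > 0L) {
    pairs <- expand.grid(ti = seq_len(nt), di = seq_len(nd))
    pairs$dist <- abs(truth[pairs$ti] - detected[pairs$di])
    pairs <- pairs[pairs$dist <= tol, , drop = FALSE]
    pairs <- pairs[order(pairs$dist, truth[pairs$ti], detected[pairs$di]), , drop = FALSE]
    used_t <- logical(nt); used_d <- logical(nd)
    for (i in seq_len(nrow(pairs))) {
      ti <- pairs$ti[i]; di <- pairs$di[i]
      if (used_t[ti] || used_d[di]) next
      used_t[ti] <- TRUE; used_d[di] <- TRUE
      matches <- rbind(matches, data.frame(truth = truth[ti],
                                           detected = detected[di],
                                           distance = pairs$dist[i]))
    }
  } else {
    used_t <- logical(nt); used_d <- logical(nd)
  }
  structure(list(n_true = nt, n_detected = nd, n_matched = nrow(matches),
                 matches = matches,
                 unmatched_truth = truth[!used_t],
                 unmatched_detected = detected[!used_d],
                 tol = tol),
            class = "cpd_match")
}

#' @export
print.cpd_match <- function(x, ...) {
  cat(sprintf("Matched %d of %d true change points (%d detected, tol = %g)\n",
              x$n_matched, x$n_true, x$n_detected, x$tol))
  if (nrow(x$matches)) print(x$matches, row.names = FALSE)
  if (length(x$unmatched_truth)) {
    cat("  missed:", paste(x$unmatched_truth, collapse = ", "), "\n")
  }
  if (length(x$unmatched_detected)) {
    cat("  spurious:", paste(x$unmatched_detected, collapse = ", "), "\n")
  }
  invisible(x)
}
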