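# internal helpers: seeded evaluation, seed derivation, input coercion

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
# RNG kinds are pinned so generated fixtures do not depend on the session's
# RNGkind() settings.
with_seed <- function(seed, expr) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(expr)
}

# Counter scheme for sub-seeds: deterministic, order-independent, < 2^31.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) %% 2147483629 + 7919 * as.double(counter)) %% 2147483629) + 1L
}

# Coerce a vector / matrix / data frame to the internal T x d numeric matrix
# (rows = time points, columns = covariates).
as_series <- function(x) {
  if (is.data.frame(x)) {
    if ("time" %in% names(x)) {
      tm <- x[["time"]]
      if (any(diff(tm) <= 0)) stop("'time' column must be strictly increasing")
      x <- x[setdiff(names(x), "time")]
    }
    x <- as.matrix(x)
  }
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("series must be a numeric vector, matrix or data frame")
  }
  if (nrow(x) < 2L) stop("series must have at least 2 time points")
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at time %d, covariate %d: missing data are not supported",
                 bad[1L], bad[2L]))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop("covariate names must be unique")
  x
}
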