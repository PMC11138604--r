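#' Read a time-series matrix from CSV or TSV
#'
#' Expects rows = time points in order, a header row of covariate names,
#' and optionally a leading `time` column of strictly increasing 1-based
#' integers. Missing or non-numeric cells are a hard error (the detector
#' does not support missing data), reported with their row and column.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated.
#' @param transpose the file is covariate x time (e.g. a gene x time
#'   expression matrix with gene identifiers in the first column); read and
#'   transpose to the internal time x covariate orientation.
#' @param sep optional field separator overriding the extension rule.
#' @return A numeric T x d matrix with covariate column names.
#' @export
read_series <- function(path, transpose = FALSE, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("no columns in ", path)
  if (transpose) {
    rn <- as.character(df[[1L]])
    m <- as.matrix(df[-1L])
    check_numeric_cells(m, rows = rn, cols = colnames(m), path = path)
    storage.mode(m) <- "double"
    m <- t(m)
    colnames(m) <- rn
    rownames(m) <- NULL
  } else {
    if (identical(tolower(names(df)[1L]), "time")) {
      tm <- df[[1L]]
      if (anyNA(tm) || any(tm != as.integer(tm)) || any(diff(tm) <= 0)) {
        stop("'time' column must be strictly increasing integers")
      }
      df <- df[-1L]
    }
    m <- as.matrix(df)
    check_numeric_cells(m, rows = seq_len(nrow(m)), cols = colnames(m), path = path)
    storage.mode(m) <- "double"
  }
  if (anyDuplicated(colnames(m))) stop("duplicate covariate names in ", path)
  as_series(m)
}

check_numeric_cells <- function(m, rows, cols, path) {
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("missing or non-numeric cell in %s at row %s, column '%s': missing data are not supported",
                 path, rows[bad[1L, 1L]], cols[bad[1L, 2L]]))
  }
  invisible(TRUE)
}

#' Write detection results to a directory
#'
#' For a [plsbd()] object writes `scores.csv` (`t, score`),
#' `changepoints.csv` and `changepoints.json` (peak, run_start, run_end,
#' score), and `manifest.json`. For a [plsbd_sample()] object writes
#' `frequency.csv` (`t, frequency, mean_score`), `intervals.csv` and
#' `intervals.json`, and `manifest.json`. The manifest records the package
#' version, configuration, seed and input dimensions, enough to reproduce
#' the run from the same input.
#'
#' @param result a `"plsbd"` or `"plsbd_sampling"` object.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    p
  }
  wj <- function(obj, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    p
  }
  if (inherits(result, "plsbd")) {
    paths <- c(paths, wr(result$scores, "scores.csv"),
               wr(result$candidates, "changepoints.csv"),
               wj(result$candidates, "changepoints.json"))
    manifest <- list(package = "plsbd",
                     version = as.character(packageVersion("plsbd")),
                     kind = "detect", method = result$method,
                     alpha = result$alpha, threshold = result$threshold,
                     config = result$config,
                     series_dim = result$series_dim,
                     seed = result$config$seed,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  } else if (inherits(result, "plsbd_sampling")) {
    paths <- c(paths, wr(result$frequency, "frequency.csv"),
               wr(result$intervals, "intervals.csv"),
               wj(result$intervals, "intervals.json"))
    manifest <- list(package = "plsbd",
                     version = as.character(packageVersion("plsbd")),
                     kind = "sample-detect", config = result$config,
                     series_dim = result$series_dim,
                     seed = result$config$seed,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  } else {
    stop("'result' must be a 'plsbd' or 'plsbd_sampling' object")
  }
  paths <- c(paths, wj(manifest, "manifest.json"))
  invisible(paths)
}
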