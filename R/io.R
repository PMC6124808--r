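#' Read a multichannel fluorescence time series
#'
#' Delimited tabular text with a header row: a `time_s` column followed by
#' one column per region.  Sampling must be uniform (relative jitter below
#' `1e-6`) and strictly increasing.
#'
#' @param path File path (tab- or comma-delimited; sniffed from the header).
#' @return Channels x samples matrix with attributes `fs`, `time_s` and
#'   rownames from the header.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#")
  if (ncol(df) < 2 || names(df)[1] != "time_s")
    stop("format error: first header column must be 'time_s'")
  t <- df[[1]]
  dt <- diff(t)
  if (any(dt <= 0))
    stop("non-monotone timestamps: first offending index ",
         which(dt <= 0)[1] + 1)
  rel <- abs(dt - stats::median(dt)) / stats::median(dt)
  if (any(rel > 1e-6))
    stop("non-uniform sampling: first offending index ",
         which(rel > 1e-6)[1] + 1)
  x <- t(as.matrix(df[, -1, drop = FALSE]))
  attr(x, "fs") <- 1 / stats::median(dt)
  attr(x, "time_s") <- t
  x
}

#' Write a multichannel time series
#'
#' @param x Channels x samples matrix (rownames become region columns).
#' @param fs Sampling rate in Hz (ignored if `time_s` given).
#' @param path Output path.
#' @param time_s Optional explicit time column.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, fs, path, time_s = NULL, sep = "\t") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(time_s)) time_s <- (seq_len(ncol(x)) - 1) / fs
  if (is.null(rownames(x))) rownames(x) <- paste0("R", seq_len(nrow(x)))
  df <- data.frame(time_s = time_s, t(x), check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a table with '#'-prefixed metadata header lines
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Named character/numeric vector written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_table_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", unlist(meta)), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save inversion results to an HDF5 archive
#'
#' Posterior means/covariances, free energies, predicted spectra and
#' per-window metadata in one structured file.
#'
#' @param wi [invert_windows()] output (or a single [invert()] result).
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
save_inversions <- function(wi, path) {
  if (inherits(wi, "inversion_result"))
    wi <- structure(list(results = list(wi), window_times = 1,
                         variance_explained = wi$variance_explained),
                    class = "window_inversions")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(wi$window_times, path, "window_times")
  rhdf5::h5write(wi$variance_explained, path, "variance_explained")
  for (k in seq_along(wi$results)) {
    r <- wi$results[[k]]
    g <- sprintf("window_%03d", k)
    rhdf5::h5createGroup(path, g)
    if (!is.null(r$failed)) {
      rhdf5::h5write(1L, path, paste0(g, "/failed"))
      next
    }
    rhdf5::h5write(r$posterior$mean, path, paste0(g, "/posterior_mean"))
    rhdf5::h5write(r$posterior$cov, path, paste0(g, "/posterior_cov"))
    rhdf5::h5write(names(r$posterior$mean), path, paste0(g, "/parameters"))
    rhdf5::h5write(r$free_energy, path, paste0(g, "/free_energy"))
    rhdf5::h5write(r$variance_explained, path, paste0(g, "/variance_explained"))
    rhdf5::h5write(as.integer(r$iterations), path, paste0(g, "/iterations"))
    rhdf5::h5write(as.integer(r$converged), path, paste0(g, "/converged"))
    rhdf5::h5write(Re(r$predicted$csd), path, paste0(g, "/predicted_csd_re"))
    rhdf5::h5write(Im(r$predicted$csd), path, paste0(g, "/predicted_csd_im"))
    rhdf5::h5write(r$predicted$grid$frequencies, path,
                   paste0(g, "/frequencies"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load inversion results from an HDF5 archive
#'
#' @param path Archive written by [save_inversions()].
#' @return A `window_inversions`-like list (posterior summaries only).
#' @export
load_inversions <- function(path) {
  if (!file.exists(path)) stop("archive not found: ", path)
  wt <- rhdf5::h5read(path, "window_times")
  ve <- rhdf5::h5read(path, "variance_explained")
  groups <- grep("^window_", rhdf5::h5ls(path, recursive = FALSE)$name,
                 value = TRUE)
  results <- lapply(sort(groups), function(g) {
    mean <- tryCatch(drop(rhdf5::h5read(path, paste0(g, "/posterior_mean"))),
                     error = function(e) NULL)
    if (is.null(mean))
      return(structure(list(failed = TRUE, converged = FALSE),
                       class = "inversion_result"))
    pars <- as.character(rhdf5::h5read(path, paste0(g, "/parameters")))
    mean <- stats::setNames(as.numeric(mean), pars)
    cov <- as.matrix(rhdf5::h5read(path, paste0(g, "/posterior_cov")))
    dimnames(cov) <- list(pars, pars)
    structure(list(
      posterior = list(mean = mean, cov = cov),
      free_energy = as.numeric(rhdf5::h5read(path, paste0(g, "/free_energy"))),
      variance_explained = as.numeric(
        rhdf5::h5read(path, paste0(g, "/variance_explained"))),
      iterations = as.integer(rhdf5::h5read(path, paste0(g, "/iterations"))),
      converged = as.logical(as.integer(
        rhdf5::h5read(path, paste0(g, "/converged"))))),
      class = "inversion_result")
  })
  rhdf5::h5closeAll()
  structure(list(results = results, window_times = as.numeric(wt),
                 variance_explained = as.numeric(ve)),
            class = "window_inversions")
}
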