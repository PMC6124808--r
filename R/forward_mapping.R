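#' Frequency band definition
#' @param name Band name.
#' @param lo_hz,hi_hz Band edges in Hz (`0 < lo < hi`).
#' @return Object of class `band_definition`.
#' @export
band_definition <- function(name, lo_hz, hi_hz) {
  if (!(lo_hz > 0 && hi_hz > lo_hz)) stop("band edges must satisfy 0 < lo < hi")
  structure(list(name = name, lo_hz = lo_hz, hi_hz = hi_hz),
            class = "band_definition")
}

#' Parameter trajectory of one region
#'
#' @param window_times Window-centre times (s).
#' @param means Windows x parameters matrix of posterior means with columns
#'   named `h1..h5`, `t_e`, `t_i` (or a subset).
#' @return Object of class `parameter_trajectory`.
#' @export
parameter_trajectory <- function(window_times, means) {
  means <- as.matrix(means)
  if (length(window_times) != nrow(means))
    stop("window_times must align with trajectory rows")
  if (!all(is.finite(means))) stop("trajectory contains non-finite values")
  structure(list(window_times = as.numeric(window_times), means = means),
            class = "parameter_trajectory")
}

# trajectory for one region extracted from windowed inversions
region_trajectory <- function(wi, region) {
  stopifnot(inherits(wi, "window_inversions"))
  ok <- vapply(wi$results, function(r) is.null(r$failed), logical(1))
  pn <- paste0(region, ".", c(paste0("h", 1:5), "t_e", "t_i"))
  means <- t(vapply(wi$results[ok], function(r) r$posterior$mean[pn],
                    numeric(length(pn))))
  colnames(means) <- c(paste0("h", 1:5), "t_e", "t_i")
  parameter_trajectory(wi$window_times[ok], means)
}

#' Principal components of intrinsic-parameter trajectories
#'
#' PCA is run separately on the intrinsic connectivity gains (`h1..h5`)
#' and the time constants (`t_e`, `t_i`), on the sample covariance of the
#' centred trajectories.  Components are orthonormal with the
#' largest-magnitude loading made positive; variance fractions are
#' non-increasing and sum to 1 over all components.
#'
#' @param traj A [parameter_trajectory()].
#' @param groups Named list of column groups (default gains and time
#'   constants).
#' @param n_components Components retained per group (default all).
#' @return Named list per group: `loadings` (columns = components),
#'   `scores` (windows x components), `variance_fraction`, `center`.
#' @export
pca_project <- function(traj,
                        groups = list(gains = paste0("h", 1:5),
                                      time_constants = c("t_e", "t_i")),
                        n_components = NULL) {
  stopifnot(inherits(traj, "parameter_trajectory"))
  if (nrow(traj$means) < 3) stop("pca_project: need >= 3 windows")
  out <- lapply(groups, function(cols) {
    M <- traj$means[, cols, drop = FALSE]
    ctr <- colMeans(M)
    Mc <- sweep(M, 2, ctr)
    CV <- stats::cov(Mc)
    if (sum(diag(CV)) < 1e-14)
      stop("pca_project: trajectory has (near-)zero variance in group")
    eg <- eigen(CV, symmetric = TRUE)
    load <- eg$vectors
    for (k in seq_len(ncol(load))) {
      imax <- which.max(abs(load[, k]))
      if (load[imax, k] < 0) load[, k] <- -load[, k]
    }
    rownames(load) <- cols
    vf <- pmax(eg$values, 0) / sum(pmax(eg$values, 0))
    nc <- if (is.null(n_components)) ncol(load)
          else min(n_components, ncol(load))
    list(loadings = load[, seq_len(nc), drop = FALSE],
         scores = Mc %*% load[, seq_len(nc), drop = FALSE],
         variance_fraction = vf[seq_len(nc)],
         all_variance_fractions = vf,
         center = ctr)
  })
  out
}

#' Predicted band power over a reduced parameter plane
#'
#' Maps each point `(s1, s2)` of the score plane to a parameter vector
#' `base + s1 * pc_conn (on h1..h5) + s2 * pc_tau (on t_e, t_i)`, runs the
#' generative model ([transfer_csd()]) on an extended prediction grid, and
#' records the mean log auto-spectral power in each requested band.
#' Grid points whose model is linearly unstable are flagged (NA surface
#' value, TRUE in `unstable`), never silently filled.
#'
#' @param base [source_params()] at the plane origin.
#' @param pc_conn Length-5 loading vector for the gain component.
#' @param pc_tau Length-2 loading vector for the time-constant component.
#' @param grid_1,grid_2 Numeric score grids.
#' @param bands List of [band_definition()]s (default delta and gamma from
#'   config).
#' @param config Package configuration (prediction grid under
#'   `mapping$pred_grid`).
#' @return List with per-band surfaces (`length(grid_1) x length(grid_2)`
#'   matrices of mean log power), `unstable` flag matrix, and the grids.
#' @export
band_power_map <- function(base, pc_conn, pc_tau, grid_1, grid_2,
                           bands = NULL, config = default_config()) {
  if (is.null(bands)) {
    bands <- lapply(names(config$mapping$bands), function(nm)
      band_definition(nm, config$mapping$bands[[nm]][1],
                      config$mapping$bands[[nm]][2]))
    names(bands) <- vapply(bands, `[[`, character(1), "name")
  }
  pg <- config$mapping$pred_grid
  fgrid <- frequency_grid(pg$lo_hz, pg$hi_hz, pg$by_hz)
  if (!is_stable(single_source_model(base), config))
    stop("band_power_map: base model unstable at the origin")
  stopifnot(length(pc_conn) == 5, length(pc_tau) == 2)
  sel <- lapply(bands, function(b)
    which(fgrid$frequencies >= b$lo_hz & fgrid$frequencies <= b$hi_hz))
  surf <- lapply(bands, function(b)
    matrix(NA_real_, length(grid_1), length(grid_2)))
  unstable <- matrix(FALSE, length(grid_1), length(grid_2))
  for (i in seq_along(grid_1)) for (j in seq_along(grid_2)) {
    p <- base
    p$h <- base$h + grid_1[i] * pc_conn
    p$t_e <- base$t_e + grid_2[j] * pc_tau[1]
    p$t_i <- base$t_i + grid_2[j] * pc_tau[2]
    m <- single_source_model(do.call(source_params, p))
    cs <- tryCatch(transfer_csd(m, fgrid, config = config),
                   error = function(e) NULL)
    if (is.null(cs)) { unstable[i, j] <- TRUE; next }
    a <- auto_spectra(cs)[, 1]
    for (b in names(bands)) surf[[b]][i, j] <- mean(log(a[sel[[b]]]))
  }
  list(surfaces = surf, unstable = unstable, grid_1 = grid_1,
       grid_2 = grid_2, bands = bands, frequencies = fgrid$frequencies)
}

#' Time-ordered trajectory through the score plane
#'
#' Purely a reporting transform: pairs each window's scores with its time
#' for overlay on band-power surfaces.
#'
#' @param scores Windows x 2 matrix (or two-column data frame) of scores.
#' @param window_times Window-centre times (s).
#' @param map Optional [band_power_map()] result for range annotation.
#' @return `data.frame` with `time_s`, `s1`, `s2`, ordered by time, with
#'   attribute `in_grid` when `map` is given.
#' @export
trajectory_overlay <- function(scores, window_times, map = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have 2 columns")
  ord <- order(window_times)
  df <- data.frame(time_s = window_times[ord],
                   s1 = scores[ord, 1], s2 = scores[ord, 2])
  if (!is.null(map)) {
    attr(df, "in_grid") <- df$s1 >= min(map$grid_1) & df$s1 <= max(map$grid_1) &
      df$s2 >= min(map$grid_2) & df$s2 <= max(map$grid_2)
  }
  df
}

#' Plot a band-power map with trajectory overlay
#'
#' Heat map of the first band's surface, isoclines of the second, and the
#' time-coloured trajectory path.
#'
#' @param map A [band_power_map()] result.
#' @param path Optional [trajectory_overlay()] result.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `NULL`.
#' @export
plot_band_map <- function(map, path = NULL, ...) {
  b1 <- names(map$surfaces)[1]
  graphics::image(map$grid_1, map$grid_2, map$surfaces[[b1]],
                  col = grDevices::gray.colors(64),
                  xlab = "connectivity score", ylab = "time-constant score",
                  main = paste("mean log power:", b1), ...)
  if (length(map$surfaces) > 1) {
    b2 <- names(map$surfaces)[2]
    graphics::contour(map$grid_1, map$grid_2, map$surfaces[[b2]],
                      add = TRUE, col = "purple")
  }
  if (!is.null(path)) {
    cols <- grDevices::hcl.colors(nrow(path), "viridis")
    graphics::lines(path$s1, path$s2, col = "grey40")
    graphics::points(path$s1, path$s2, col = cols, pch = 16, cex = 0.7)
  }
  invisible(NULL)
}
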