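#' Sliding-window scheme
#'
#' @param length_s Window length in seconds.
#' @param step_s Step between window starts in seconds (must not exceed
#'   `length_s`).
#' @return Object of class `windowing_scheme`.
#' @export
windowing_scheme <- function(length_s = 60, step_s = 10) {
  if (length_s <= 0 || step_s <= 0) stop("window length and step must be > 0")
  if (step_s > length_s) stop("step_s must not exceed length_s")
  structure(list(length_s = length_s, step_s = step_s),
            class = "windowing_scheme")
}

#' Number of sliding windows in a recording
#'
#' `k = floor((T - length) / step) + 1` for a recording of duration `T`.
#'
#' @param duration_s Recording duration in seconds.
#' @param w A [windowing_scheme()].
#' @return Integer window count (0 if the recording is too short).
#' @export
window_count <- function(duration_s, w) {
  if (duration_s < w$length_s) return(0L)
  as.integer(floor((duration_s - w$length_s) / w$step_s) + 1)
}

# start indices (1-based) of each window in samples
window_starts <- function(n_samples, fs, w) {
  len <- round(w$length_s * fs)
  k <- window_count(n_samples / fs, w)
  if (k < 1) stop("recording shorter than one window")
  round((seq_len(k) - 1) * w$step_s * fs) + 1
}

#' Sliding-window Fourier amplitude spectra
#'
#' For each window and channel, the Fourier amplitude spectrum over
#' 0 to `fs/2`.  Deterministic; no tapering or overlap-averaging within a
#' window (one DFT per window, matching the simple windowed estimator used
#' for visualising seizure phase structure).
#'
#' @param x Channels x samples matrix (or vector).
#' @param fs Sampling rate in Hz.
#' @param w A [windowing_scheme()].
#' @return Object of class `spectral_series`: list with `window_times`
#'   (window centres, s), `frequencies`, and `amplitude`
#'   (windows x channels x frequencies array).
#' @export
sliding_spectra <- function(x, fs, w = windowing_scheme()) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  nchan <- nrow(x)
  n <- ncol(x)
  starts <- window_starts(n, fs, w)
  len <- round(w$length_s * fs)
  nf <- len %/% 2 + 1
  freqs <- (0:(nf - 1)) * fs / len
  amp <- array(NA_real_, c(length(starts), nchan, nf))
  for (k in seq_along(starts)) {
    seg <- x[, starts[k]:(starts[k] + len - 1), drop = FALSE]
    for (ch in seq_len(nchan)) {
      sp <- stats::fft(seg[ch, ] - mean(seg[ch, ]))
      amp[k, ch, ] <- Mod(sp[seq_len(nf)]) / len
    }
  }
  structure(list(window_times = (starts - 1) / fs + w$length_s / 2,
                 frequencies = freqs, amplitude = amp,
                 channels = rownames(x), fs = fs, scheme = w),
            class = "spectral_series")
}

#' Window-by-window power-correlation ("delay-delay") matrix
#'
#' For each window, a vector of per-channel mean power over `band_hz`;
#' the k x k Pearson correlation matrix of these power-distribution
#' vectors across windows reveals slow state changes (e.g. seizure
#' phases).  Windows whose power vector has zero variance are returned as
#' missing (NA) rows/columns rather than propagating NaN.
#'
#' @param s A [sliding_spectra()] result.
#' @param band_hz Length-2 frequency interval in Hz (default 0-10).
#' @return k x k correlation matrix with attribute `window_times`.
#' @export
power_corr_matrix <- function(s, band_hz = c(0, 10)) {
  stopifnot(inherits(s, "spectral_series"))
  k <- dim(s$amplitude)[1]
  if (k < 2) stop("power_corr_matrix: need at least 2 windows")
  sel <- s$frequencies >= band_hz[1] & s$frequencies <= band_hz[2]
  pow <- s$amplitude[, , sel, drop = FALSE]^2
  V <- apply(pow, c(1, 2), mean)             # windows x channels
  sds <- apply(V, 1, stats::sd)
  ok <- sds > 0
  R <- matrix(NA_real_, k, k)
  if (any(ok)) R[ok, ok] <- stats::cor(t(V[ok, , drop = FALSE]))
  diag(R)[ok] <- 1
  attr(R, "window_times") <- s$window_times
  R
}

#' Cross-spectral density from a multivariate autoregressive model
#'
#' Fits a VAR(`order`) by least squares after per-window mean removal and
#' linear detrending, then evaluates the parametric cross-spectrum
#' `S(f) = A(f)^(-1) Sigma A(f)^(-H)` with
#' `A(f) = I - sum_l A_l exp(-i 2 pi f l / fs)` on the requested grid
#' (per-sample normalisation: a white univariate series has `S = sigma^2`).
#'
#' @param x_window Channels x samples segment (or vector).
#' @param fs Sampling rate in Hz.
#' @param order Lag count (default 8).
#' @param grid A [frequency_grid()] (frequencies must be below `fs/2`).
#' @return A [cross_spectrum()].
#' @export
mar_csd <- function(x_window, fs, order = 8, grid = frequency_grid()) {
  if (is.null(dim(x_window))) x_window <- matrix(x_window, nrow = 1)
  d <- nrow(x_window)
  n <- ncol(x_window)
  if (n < 10 * order * d)
    stop("mar_csd: segment too short for order ", order, " with ", d,
         " channels (need >= ", 10 * order * d, " samples)")
  if (max(grid$frequencies) > fs / 2)
    stop("mar_csd: grid extends beyond the Nyquist frequency")
  tt <- seq_len(n)
  X <- t(apply(x_window, 1, function(ch) stats::lsfit(tt, ch)$residuals))
  if (d == 1) X <- matrix(X, nrow = 1)
  sds <- apply(X, 1, stats::sd)
  if (any(sds < 1e-12))
    stop("mar_csd: constant channel(s) ",
         paste(which(sds < 1e-12), collapse = ", "),
         " make the regression rank-deficient")
  Y <- t(X[, (order + 1):n, drop = FALSE])          # (n-order) x d
  Z <- do.call(cbind, lapply(seq_len(order), function(l)
    t(X[, (order + 1 - l):(n - l), drop = FALSE])))  # lagged predictors
  fit <- stats::lm.fit(Z, Y)
  if (fit$rank < ncol(Z))
    stop("mar_csd: rank-deficient autoregression (rank ", fit$rank,
         " < ", ncol(Z), ")")
  A <- matrix(fit$coefficients, ncol = d)            # (d*order) x d
  E <- Y - Z %*% A
  Sigma <- crossprod(E) / nrow(E)
  f <- grid$frequencies
  nf <- length(f)
  csd <- array(0i, c(d, d, nf))
  Id <- diag(d)
  for (k in seq_len(nf)) {
    Af <- Id + 0i
    for (l in seq_len(order)) {
      Al <- t(A[((l - 1) * d + 1):(l * d), , drop = FALSE])
      Af <- Af - Al * exp(-2i * pi * f[k] * l / fs)
    }
    Ainv <- solve(Af)
    S <- Ainv %*% Sigma %*% Conj(t(Ainv))
    csd[, , k] <- (S + Conj(t(S))) / 2
  }
  cross_spectrum(grid, csd, region_names = rownames(x_window),
                 validate = FALSE)
}

#' Dominant spectral eigenmode across a series of cross-spectra
#'
#' For each window, the frequency-averaged channel-space CSD is
#' eigendecomposed; the leading eigenvector's projected spectrum
#' `m(f) = u^H S(f) u` is the eigenmode summary.  Weights are
#' unit-normalised with the largest-magnitude entry rotated to be positive
#' real, so repeated runs give identical (not sign/phase-flipped) output.
#'
#' @param csd_series List of [cross_spectrum()] objects on a shared grid.
#' @return List with `modes` (windows x frequencies matrix), `weights`
#'   (list of complex unit vectors) and `frequencies`.
#' @export
eigenmode_summary <- function(csd_series) {
  if (inherits(csd_series, "cross_spectrum")) csd_series <- list(csd_series)
  if (length(csd_series) < 1) stop("eigenmode_summary: need >= 1 window")
  f <- csd_series[[1]]$grid$frequencies
  modes <- matrix(NA_real_, length(csd_series), length(f))
  weights <- vector("list", length(csd_series))
  for (w in seq_along(csd_series)) {
    cs <- csd_series[[w]]
    n <- dim(cs$csd)[1]
    Sbar <- apply(cs$csd, c(1, 2), mean)
    Sbar <- (Sbar + Conj(t(Sbar))) / 2
    if (n == 1) {
      u <- matrix(1 + 0i, 1, 1)
    } else {
      u <- eigen(Sbar, symmetric = TRUE)$vectors[, 1, drop = FALSE]
    }
    imax <- which.max(Mod(u))
    u <- u * Conj(u[imax]) / Mod(u[imax])
    u <- u / sqrt(sum(Mod(u)^2))
    weights[[w]] <- drop(u)
    modes[w, ] <- vapply(seq_along(f), function(k)
      Re(Conj(t(u)) %*% cs$csd[, , k] %*% u), numeric(1))
  }
  list(modes = modes, weights = weights, frequencies = f)
}

#' Welch power spectral density estimate
#'
#' Two-sided PSD convention (a unit-variance white series sampled at `fs`
#' has PSD `1/fs`), Hann taper, 50% overlap.  This matches the density
#' convention of [transfer_csd()], allowing direct comparison between
#' simulated output and the linearised spectral prediction.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length in samples.
#' @return List with `frequencies` and `psd` (positive frequencies only).
#' @export
welch_psd <- function(x, fs, nperseg = 4096) {
  n <- length(x)
  if (n < nperseg) stop("welch_psd: series shorter than one segment")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1))
  starts <- seq(1, n - nperseg + 1, by = nperseg %/% 2)
  acc <- numeric(nperseg)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    acc <- acc + Mod(stats::fft((seg - mean(seg)) * w))^2
  }
  psd <- acc / length(starts) * (1 / fs) / (nperseg * mean(w^2))
  f <- (0:(nperseg - 1)) * fs / nperseg
  keep <- 2:(nperseg %/% 2)
  list(frequencies = f[keep], psd = psd[keep])
}
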