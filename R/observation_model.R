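#' Calcium-indicator kernel specification
#'
#' The composite kernel has an inverted-quadratic rise lasting `t_up_ms`
#' followed by an exponential decay with time constant `tau_decay_ms`;
#' both branches are normalised so the kernel equals 1 at the end of the
#' rise.  Defaults approximate GCaMP6F dynamics (250 ms rise, 1 s decay).
#'
#' @param t_up_ms Rise duration in ms (> 0).
#' @param tau_decay_ms Decay time constant in ms (> 0).
#' @param dt_ms Kernel sampling step in ms.
#' @param length_ms Total kernel support in ms
#'   (must be at least `t_up_ms + 5 * tau_decay_ms`).
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(t_up_ms = 250, tau_decay_ms = 1000, dt_ms = 1,
                        length_ms = t_up_ms + 5 * tau_decay_ms) {
  if (t_up_ms <= 0 || tau_decay_ms <= 0 || dt_ms <= 0)
    stop("kernel_spec: all times must be positive")
  if (length_ms < t_up_ms + 5 * tau_decay_ms)
    stop("kernel_spec: length_ms must be >= t_up_ms + 5 * tau_decay_ms")
  structure(list(t_up_ms = t_up_ms, tau_decay_ms = tau_decay_ms,
                 dt_ms = dt_ms, length_ms = length_ms),
            class = "kernel_spec")
}

#' Build the sampled calcium kernel
#'
#' Rise: `y(t) = (2 t t_up - t^2) / t_up^2` on `[0, t_up]` (the printed
#' quadratic normalised to `y(t_up) = 1`); decay: `y(t) =
#' exp(-(t - t_up) / tau)` thereafter.  `y(0) = 0` and `y(t_up) = 1`
#' exactly.
#'
#' @param spec A [kernel_spec()].
#' @return Numeric vector sampled at `dt_ms` with attribute `t_ms`.
#' @export
build_kernel <- function(spec = kernel_spec()) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$dt_ms > spec$t_up_ms)
    stop("build_kernel: dt_ms > t_up_ms, kernel rise unresolvable")
  t <- seq(0, spec$length_ms, by = spec$dt_ms)
  y <- ifelse(t <= spec$t_up_ms,
              (2 * t * spec$t_up_ms - t^2) / spec$t_up_ms^2,
              exp(-(t - spec$t_up_ms) / spec$tau_decay_ms))
  attr(y, "t_ms") <- t
  attr(y, "dt_ms") <- spec$dt_ms
  y
}

#' Convolve signals with the calcium kernel and downsample
#'
#' Applies the fluorescence observation model to LFP-like multichannel
#' signals: discrete convolution with the kernel sampled at the input rate
#' ('full' convolution truncated to the input length), an anti-aliasing
#' low-pass at `0.9 * fs_out / 2` (FFT brick-wall), then decimation to the
#' imaging rate.  Linear and shift-covariant before decimation.  The first
#' kernel-length worth of output samples is transient; its extent is
#' returned in the `burnin_samples` attribute.
#'
#' @param x Channels x samples matrix (or a vector for one channel).
#' @param fs_in Input sampling rate in Hz.
#' @param spec A [kernel_spec()].
#' @param fs_out Output (imaging) rate in Hz; must divide `fs_in`.
#' @return Channels x samples matrix at `fs_out` with attributes `fs` and
#'   `burnin_samples`.
#' @export
apply_kernel <- function(x, fs_in, spec = kernel_spec(), fs_out = fs_in) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (fs_out > fs_in) stop("apply_kernel: fs_out must not exceed fs_in")
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("apply_kernel: fs_in must be an integer multiple of fs_out")
  ratio <- round(ratio)
  kspec <- kernel_spec(spec$t_up_ms, spec$tau_decay_ms,
                       dt_ms = 1000 / fs_in, length_ms = spec$length_ms)
  k <- build_kernel(kspec)
  n <- ncol(x)
  nfft <- stats::nextn(n + length(k) - 1, 2)
  K <- stats::fft(c(k, numeric(nfft - length(k))))
  # anti-aliasing mask (applied pre-decimation only)
  f <- (0:(nfft - 1)) / nfft * fs_in
  f <- pmin(f, fs_in - f)
  aa <- if (ratio > 1) as.numeric(f <= 0.9 * fs_out / 2) else rep(1, nfft)
  conv1 <- function(xi) {
    X <- stats::fft(c(xi, numeric(nfft - n)))
    Re(stats::fft(X * K * aa, inverse = TRUE))[seq_len(n)] / nfft
  }
  y <- t(apply(x, 1, conv1))
  idx <- seq(1, n, by = ratio)
  out <- y[, idx, drop = FALSE]
  rownames(out) <- rownames(x)
  attr(out, "fs") <- fs_out
  attr(out, "burnin_samples") <- ceiling(length(k) / ratio)
  out
}
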