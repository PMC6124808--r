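test_that("window count follows the closed formula (brute force oracle)", {
  set.seed(11)
  for (i in 1:20) {
    len <- runif(1, 5, 120)
    stp <- runif(1, 1, len)
    T <- runif(1, len, 2000)
    w <- windowing_scheme(len, stp)
    # brute force: count window start times fitting in [0, T]
    k_brute <- 0
    s <- 0
    while (s + len <= T + 1e-9) { k_brute <- k_brute + 1; s <- s + stp }
    expect_equal(window_count(T, w), k_brute)
  }
  # the full-length recording the generator emulates
  expect_equal(window_count(9000, windowing_scheme(60, 10)), 895L)
})

test_that("sliding spectra: sinusoid peaks at its frequency, constants vanish", {
  fs <- 20
  t <- seq(0, 300, by = 1 / fs)[-1]
  x <- sin(2 * pi * 2 * t)
  s <- sliding_spectra(x, fs, windowing_scheme(60, 30))
  for (k in seq_along(s$window_times)) {
    pk <- s$frequencies[which.max(s$amplitude[k, 1, ])]
    expect_equal(pk, 2, tolerance = s$frequencies[2])
  }
  s0 <- sliding_spectra(rep(3, 6000), fs, windowing_scheme(60, 30))
  expect_lt(max(s0$amplitude[, , s0$frequencies > 0]), 1e-10)
  expect_error(sliding_spectra(rnorm(100), fs, windowing_scheme(60, 30)),
               "shorter than one window")
})

test_that("power correlation matrix is a correlation matrix", {
  set.seed(2)
  x <- matrix(rnorm(3 * 4800), 3)
  s <- sliding_spectra(x, 20, windowing_scheme(30, 30))
  R <- power_corr_matrix(s)
  expect_equal(R, t(R))
  expect_true(all(diag(R) == 1))
  expect_true(all(abs(R[!is.na(R)]) <= 1 + 1e-12))
})

test_that("two-regime recordings show block structure in the delay-delay matrix", {
  set.seed(3)
  fs <- 20
  n <- 240 * fs
  # regime A: broadband; regime B: strong slow oscillation on channel 1
  t <- seq_len(n) / fs
  xa <- matrix(rnorm(2 * n), 2)
  xb <- xa
  xb[1, ] <- xb[1, ] + 8 * sin(2 * pi * 1 * t)
  x <- cbind(xa, xb)
  s <- sliding_spectra(x, fs, windowing_scheme(30, 30))
  R <- power_corr_matrix(s)
  k <- nrow(R)
  half <- seq_len(k / 2)
  within <- c(R[half, half][upper.tri(diag(k / 2))],
              R[-half, -half][upper.tri(diag(k / 2))])
  between <- as.numeric(R[half, -half])
  expect_gt(mean(within), mean(between))
})

test_that("identical windows correlate perfectly", {
  # channels must differ (a constant cross-channel pattern has no
  # correlation), but the two windows are exact copies
  t <- seq_len(1200) / 20
  x <- rbind(sin(2 * pi * 3 * t), 3 * sin(2 * pi * 1 * t))
  s <- sliding_spectra(cbind(x, x), 20, windowing_scheme(60, 60))
  R <- power_corr_matrix(s)
  expect_equal(R[1, 2], 1)
})

test_that("mar_csd recovers closed-form AR(1) and white-noise spectra", {
  set.seed(4)
  g <- frequency_grid(0.25, 9, 0.25)
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), 10000))
  cs <- mar_csd(x, 20, order = 8, grid = g)
  f <- g$frequencies
  closed <- 1 / Mod(1 - 0.9 * exp(-2i * pi * f / 20))^2
  est <- auto_spectra(cs)[, 1]
  expect_lt(median(abs(est - closed) / closed), 0.15)

  w <- rnorm(10000)
  csw <- mar_csd(w, 20, order = 8, grid = g)
  aw <- auto_spectra(csw)[, 1]
  expect_lt(max(aw) / min(aw), 2)

  # Hermitian by construction on multichannel input
  xm <- matrix(rnorm(2 * 5000), 2)
  csm <- mar_csd(xm, 20, 8, g)
  for (k in c(1, 18, 36)) {
    S <- csm$csd[, , k]
    expect_lt(max(abs(S - Conj(t(S)))), 1e-10)
  }
  expect_error(mar_csd(rbind(rnorm(2000), rep(1, 2000)), 20, 8, g), "constant")
  expect_error(mar_csd(rnorm(50), 20, 8, g), "too short")
})

test_that("mar_csd converges toward the Welch estimate on long stationary data", {
  m <- single_source_model(source_params())
  y <- as.numeric(simulate_lfp(m, 150, 0.001, seed = 21))
  y20 <- y[seq(1, length(y), by = 50)]
  g <- frequency_grid(0.5, 8, 0.5)
  a_mar <- auto_spectra(mar_csd(y20, 20, order = 12, grid = g))[, 1]
  w <- welch_psd(y20, 20, nperseg = 512)
  a_welch <- vapply(g$frequencies, function(f)
    w$psd[which.min(abs(w$frequencies - f))], numeric(1))
  # per-sample vs per-Hz conventions differ by fs
  expect_lt(median(abs(a_mar / 20 - a_welch) / a_welch), 0.2)
})

test_that("eigenmode summary: degenerate case, correlated channels, determinism", {
  g <- frequency_grid(0.5, 8, 0.5)
  m <- single_source_model(source_params())
  cs1 <- transfer_csd(m, g)
  es1 <- eigenmode_summary(list(cs1))
  expect_equal(as.numeric(es1$modes[1, ]), auto_spectra(cs1)[, 1])

  # duplicated channel: leading mode captures > 99% of power
  set.seed(6)
  x <- rbind(a = rnorm(5000))
  xd <- rbind(x, x + rnorm(5000, 0, 0.01))
  cs2 <- mar_csd(xd, 20, 6, g)
  Sbar <- apply(cs2$csd, c(1, 2), mean)
  ev <- eigen((Sbar + Conj(t(Sbar))) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[1] / sum(ev), 0.99)

  es2a <- eigenmode_summary(list(cs2))
  es2b <- eigenmode_summary(list(cs2))
  expect_identical(es2a$weights, es2b$weights)
  imax <- which.max(Mod(es2a$weights[[1]]))
  expect_gt(Re(es2a$weights[[1]][imax]), 0)
  expect_lt(abs(Im(es2a$weights[[1]][imax])), 1e-12)
})
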