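test_that("effective_params maps log-scalings onto prior means", {
  pm <- default_config()$neural_mass$prior_means
  e0 <- effective_params(source_params())
  expect_identical(e0$H, pm$H)
  expect_identical(e0$T_e_ms, pm$T_e_ms)
  expect_identical(e0$T_i_ms, pm$T_i_ms)

  e1 <- effective_params(source_params(h = c(1, 0, 0, 0, 0)))
  expect_equal(e1$H[1], pm$H[1] * exp(1))
  expect_equal(e1$H[2:5], pm$H[2:5])

  e2 <- effective_params(source_params(t_e = log(2)))
  expect_equal(e2$T_e_ms, 2 * pm$T_e_ms)

  expect_error(source_params(h = c(Inf, 0, 0, 0, 0)), "finite")
})

test_that("network_model validates masks and rejects self-connections", {
  p2 <- list(source_params(), source_params())
  expect_error(network_model(p2, mask_fwd = diag(2)), "zero diagonal")
  expect_error(network_model(p2, mask_fwd = matrix(2, 2, 2) - 2 * diag(2)),
               "binary")
  m <- network_model(p2, region_names = c("A", "B"))
  expect_equal(m$n_sources, 2)
  expect_error(network_model(p2, region_names = c("A.x", "B")), "must not contain")
})

test_that("fixed point has vanishing dynamics and is initialisation-robust", {
  m <- single_source_model(source_params())
  eff <- zebradcm:::network_effective(m)
  x1 <- fixed_point(m)
  expect_lt(sqrt(sum(zebradcm:::nm_dynamics(as.numeric(x1), eff)^2)), 1e-8)
  x2 <- fixed_point(m, init = rep(0.1, 6))
  expect_lt(max(abs(as.numeric(x1) - as.numeric(x2))), 1e-6)

  # uncoupled identical sources replicate the same fixed point
  m3 <- network_model(replicate(3, source_params(), simplify = FALSE))
  x3 <- matrix(fixed_point(m3), nrow = 6)
  expect_lt(max(abs(x3 - x3[, 1])), 1e-10)
})

test_that("analytic Jacobian matches a numerical one at a generic state", {
  m <- network_model(list(source_params(h = rep(0.1, 5)), source_params()),
                     a_fwd = matrix(c(0, 0.4, 0.3, 0), 2, 2),
                     mask_fwd = matrix(c(0, 1, 1, 0), 2, 2))
  eff <- zebradcm:::network_effective(m)
  x <- seq(-0.05, 0.06, length.out = 12)
  J <- zebradcm:::nm_jacobian(x, eff)
  h <- 1e-6
  Jnum <- sapply(seq_along(x), function(k) {
    up <- x; up[k] <- up[k] + h
    dn <- x; dn[k] <- dn[k] - h
    (zebradcm:::nm_dynamics(up, eff) - zebradcm:::nm_dynamics(dn, eff)) / (2 * h)
  })
  expect_lt(max(abs(J - Jnum)) / max(abs(J)), 1e-6)
})

test_that("simulate_lfp is reproducible, finite, and decays without noise", {
  m <- single_source_model(source_params())
  y1 <- simulate_lfp(m, 2, 0.001, seed = 42)
  y2 <- simulate_lfp(m, 2, 0.001, seed = 42)
  expect_identical(y1, y2)
  expect_true(all(is.finite(y1)))
  y3 <- simulate_lfp(m, 2, 0.001, seed = 43)
  expect_false(identical(y1, y3))

  # noise amplitude -> 0 limit: output decays to the (zero) fixed point
  m0 <- single_source_model(source_params(noise_amp = -30))
  y0 <- simulate_lfp(m0, 2, 0.001, seed = 1)
  expect_lt(max(abs(y0[, ncol(y0)])), 1e-8)

  expect_error(simulate_lfp(m, 0.05, 0.001), "at least 100 samples")
  expect_error(simulate_lfp(m, 2, 0.002), "dt too coarse")
})

test_that("transfer_csd is Hermitian, PSD, and off-diagonal-free when uncoupled", {
  g <- default_grid()
  m2 <- network_model(list(source_params(), source_params(h = rep(0.2, 5))))
  cs <- transfer_csd(m2, g)
  for (k in c(1, 20, 40)) {
    S <- cs$csd[, , k]
    expect_lt(max(abs(S - Conj(t(S)))), 1e-10)
    expect_true(all(Re(diag(S)) >= 0))
    expect_lt(max(Mod(S[upper.tri(S)])), 1e-14)  # independent inputs
  }
  ev <- eigen(cs$csd[, , 10], symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
})

test_that("h1 orders total low-frequency power monotonically", {
  g <- default_grid()
  pow <- vapply(c(-1, 0, 1), function(h1) {
    cs <- transfer_csd(single_source_model(source_params(h = c(h1, 0, 0, 0, 0))), g)
    sum(auto_spectra(cs)[g$frequencies <= 4, 1])
  }, numeric(1))
  expect_true(all(diff(pow) > 0))
  expect_equal(length(unique(pow)), 3)
})

test_that("noise amplitude scaling quadruples the CSD and masked entries are inert", {
  g <- default_grid()
  m1 <- single_source_model(source_params())
  m2 <- single_source_model(source_params(noise_amp = log(2)))
  r <- Mod(transfer_csd(m2, g)$csd) / Mod(transfer_csd(m1, g)$csd)
  expect_lt(max(abs(r - 4)), 4e-6)

  p2 <- list(source_params(), source_params())
  mask <- matrix(c(0, 1, 0, 0), 2, 2)   # only 2<-1 exists
  a <- matrix(c(0, 0.5, 0, 0), 2, 2)
  ma <- network_model(p2, a_fwd = a, mask_fwd = mask)
  mb <- ma
  mb$a_fwd[1, 2] <- 7   # masked entry perturbed
  d <- Mod(transfer_csd(ma, g)$csd - transfer_csd(mb, g)$csd)
  expect_lt(max(d), 1e-12)
})

test_that("instability is reported distinctly from non-convergence", {
  m_bad <- single_source_model(source_params(h = c(3, 3, 0, 0, 0)))
  expect_error(transfer_csd(m_bad, default_grid()), "unstable")
})

test_that("time-domain spectrum matches the linearised prediction", {
  # single oracle-equivalence example; the 10-model battery runs in the
  # acceptance suite
  m <- single_source_model(source_params())
  y <- simulate_lfp(m, 200, 0.001, seed = 7)
  w <- welch_psd(as.numeric(y), 1000, nperseg = 4096)
  sel <- w$frequencies >= 1 & w$frequencies <= 10
  g <- frequency_grid(frequencies = w$frequencies[sel])
  pred <- auto_spectra(transfer_csd(m, g))[, 1]
  relerr <- abs(w$psd[sel] - pred) / pred
  expect_lt(median(relerr), 0.2)
})
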