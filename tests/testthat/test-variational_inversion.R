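test_that("prior_density validates its covariance", {
  expect_error(prior_density(c(a = 0, b = 0),
                             matrix(c(1, 2, 0, 1), 2)), "symmetric")
  expect_error(prior_density(c(a = 0, b = 0),
                             matrix(c(1, 2, 2, 1), 2)), "semi-definite")
  p <- prior_density(c(a = 0, b = 1), c(1, 0))
  expect_equal(diag(p$cov), c(a = 1, b = 0))
})

test_that("self-inversion at the generative truth recovers the prior mean", {
  g <- default_grid()
  m <- single_source_model(source_params())
  dat <- transfer_csd(m, g)
  r <- invert(m, dat, rescale_data = FALSE)
  expect_true(r$converged)
  expect_lt(max(abs(r$posterior$mean)), 0.1)
  expect_gt(r$variance_explained, 0.9)
  # determinism: bitwise-identical free energy on repeat
  r2 <- invert(m, dat, rescale_data = FALSE)
  expect_identical(r$free_energy, r2$free_energy)
})

test_that("two-point ordinal recovery of h1 and monotone free energy", {
  g <- default_grid()
  m <- single_source_model(source_params())
  est <- vapply(c(-0.5, 0.5), function(v) {
    dat <- transfer_csd(single_source_model(source_params(h = c(v, 0, 0, 0, 0))), g)
    r <- invert(m, dat, rescale_data = FALSE)
    expect_true(all(diff(r$f_trace) > -1e-6))
    r$posterior$mean[["R1.h1"]]
  }, numeric(1))
  expect_gt(est[2], 0)
  expect_lt(est[1], 0)
  expect_gt(est[2], est[1])
})

test_that("variance_explained handles exact fit, null fit and zero data", {
  g <- frequency_grid(1, 5, 1)
  m <- single_source_model(source_params())
  cs <- transfer_csd(m, g)
  r <- list(predicted = cs, data_scale = 1)
  expect_equal(variance_explained(r, cs), 1)

  zero <- cross_spectrum(g, array(0i, c(1, 1, 5)), validate = FALSE)
  r0 <- list(predicted = zero, data_scale = 1)
  expect_warning(ve <- variance_explained(r0, cs), "clipped")
  expect_equal(ve, 0)
  expect_error(variance_explained(r, zero), "no power")
})

test_that("single-parameter sign recovery across the intrinsic set", {
  # 20 perturbed datasets (noiseless self-data): the sign of the perturbed
  # parameter's posterior deviation must be recovered in >= 18/20
  g <- default_grid()
  m <- single_source_model(source_params())
  prior <- network_priors(m)
  params <- c(paste0("h", c(1, 2, 5)), "t_e", "t_i")
  hits <- 0
  total <- 0
  for (p in params) {
    for (v in c(-0.5, 0.5)) {
      for (extra in c(0, 0.1)) {
        th <- prior$mean
        th[paste0("R1.", p)] <- v + extra * sign(v)
        dat <- transfer_csd(zebradcm:::apply_params(m, th), g)
        r <- invert(m, dat, rescale_data = FALSE)
        est <- r$posterior$mean[[paste0("R1.", p)]]
        hits <- hits + (sign(est) == sign(v))
        total <- total + 1
      }
    }
  }
  expect_equal(total, 20)
  expect_gte(hits, 18)
})

test_that("invert_windows reduces to invert and is order-equivariant", {
  g <- default_grid()
  m <- single_source_model(source_params())
  w1 <- transfer_csd(single_source_model(source_params(h = c(0.3, 0, 0, 0, 0))), g)
  w2 <- transfer_csd(single_source_model(source_params(t_i = 0.2)), g)
  w3 <- transfer_csd(m, g)
  windows <- list(w1, w2, w3)
  attr(windows, "window_times") <- c(10, 20, 30)
  wi <- invert_windows(m, windows)
  scl <- common_scale(m, windows)
  single <- invert(m, w1, network_priors(m), scale = scl)
  expect_identical(wi$results[[1]]$free_energy, single$free_energy)

  perm <- windows[c(2, 3, 1)]
  attr(perm, "window_times") <- c(20, 30, 10)
  wip <- invert_windows(m, perm)
  expect_identical(wip$results[[1]]$free_energy, wi$results[[2]]$free_energy)
  expect_identical(wip$results[[3]]$free_energy, wi$results[[1]]$free_energy)
})

test_that("model with a true connection beats the one without (F comparison)", {
  g <- default_grid()
  p2 <- function() list(source_params(), source_params())
  mask <- matrix(c(0, 1, 0, 0), 2, 2)       # 2 <- 1 forward connection
  m_con <- network_model(p2(), a_fwd = mask * 0.8, mask_fwd = mask,
                         region_names = c("A", "B"))
  m_null <- network_model(p2(), region_names = c("A", "B"))
  wins <- 0
  for (seed in 1:5) {
    y <- simulate_lfp(m_con, 120, 0.001, seed = 400 + seed)
    y20 <- y[, seq(1, ncol(y), by = 50)]
    dat <- mar_csd(y20, 20, 8, g)
    prior_con <- network_priors(m_con)
    f_con <- invert(m_con, dat, prior_con)$free_energy
    f_null <- invert(m_null, dat)$free_energy
    wins <- wins + (f_con > f_null)
  }
  expect_gte(wins, 4)
})
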