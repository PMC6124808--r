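test_that("factorial space enumerates 24 distinct architectures", {
  sp <- build_factorial_space()
  expect_length(sp, 24)
  keys <- vapply(sp, function(m)
    paste(c(m$mask_fwd, m$mask_bwd), collapse = ""), character(1))
  expect_equal(length(unique(keys)), 24)

  null <- Filter(function(m) m$hub == "none" && !m$neighbouring &&
                   !m$homotopic, sp)[[1]]
  expect_equal(sum(null$mask_fwd) + sum(null$mask_bwd), 0)

  # hub rule, checked entry by entry against its definition
  tect <- Filter(function(m) m$hub == "Tect" && !m$neighbouring &&
                   !m$homotopic, sp)[[1]]
  rs <- region_set()
  hub_idx <- which(rs$pair_index == 1)
  for (i in seq_along(rs$names)) for (j in seq_along(rs$names)) {
    expect_fwd <- (i %in% hub_idx) && !(j %in% hub_idx)
    expect_bwd <- (j %in% hub_idx) && !(i %in% hub_idx)
    expect_equal(tect$mask_fwd[i, j], as.numeric(expect_fwd))
    expect_equal(tect$mask_bwd[i, j], as.numeric(expect_bwd))
  }

  expect_error(build_factorial_space(region_set(c("A", "B"))), "5 bilateral")
  expect_error(region_set(c("A", "A")), "duplicate")
})

test_that("BMR matches analytic conjugate evidence to 1e-6", {
  set.seed(3)
  n <- 25
  X <- cbind(1, rnorm(n), rnorm(n))
  s2 <- 0.4
  y <- X %*% c(1, 0.7, -0.2) + rnorm(n, 0, sqrt(s2))
  analytic <- function(m0, C0) {
    S <- s2 * diag(n) + X %*% C0 %*% t(X)
    as.numeric(-0.5 * (n * log(2 * pi) + determinant(S)$modulus +
                         t(y - X %*% m0) %*% solve(S) %*% (y - X %*% m0)))
  }
  C0 <- diag(c(1, 1, 0.5)); m0 <- c(0, 0, 0)
  P <- t(X) %*% X / s2 + solve(C0)
  Cpost <- solve(P)
  mpost <- drop(Cpost %*% (t(X) %*% y / s2))
  full <- list(posterior = list(mean = mpost, cov = Cpost),
               prior = prior_density(m0, C0))
  cases <- list(
    list(mr = c(0, 0, 0), Cr = diag(c(1, 1e-8, 0.5))),
    list(mr = c(0, 0, 0), Cr = diag(c(1e-8, 1e-8, 0.5))),
    list(mr = c(0.5, 0, 0), Cr = diag(c(0.25, 1, 0.5)))
  )
  for (cs in cases) {
    red <- reduce_model(full, reduced_prior = prior_density(cs$mr, cs$Cr))
    expect_equal(red$dF, analytic(cs$mr, cs$Cr) - analytic(m0, C0),
                 tolerance = 1e-6)
  }
  ident <- reduce_model(full, reduced_prior = full$prior)
  expect_lt(abs(ident$dF), 1e-8)
  expect_lt(max(abs(ident$mean - mpost)), 1e-8)
})

test_that("family comparison obeys softmax arithmetic and invariances", {
  part <- list(a = 1:4, b = 5:8, c = 9:12, d = 13:16)
  pr <- compare_families(rep(0, 16), part)
  expect_equal(unname(pr), rep(0.25, 4))
  expect_equal(sum(pr), 1, tolerance = 1e-12)

  F2 <- rep(0, 16); F2[3] <- 10
  pr2 <- compare_families(F2, part)
  expect_gt(pr2[["a"]], 0.99)

  pr3 <- compare_families(F2 + 123.4, part)
  expect_equal(pr2, pr3, tolerance = 1e-12)

  expect_error(compare_families(c(0, NA), list(a = 1, b = 2)), "finite")
  expect_error(compare_families(rep(0, 3), list(a = 1:3, b = integer(0))),
               "empty")
  expect_error(compare_families(rep(0, 3), list(a = 1:2)), "every model")
})

test_that("hub recovery by BMR on a scaled-down bilateral space", {
  # data generated WITH a pair-1 hub: hub-present reductions should
  # collectively outscore hub-absent ones (2 pairs instead of 5 to keep
  # runtime in budget; the rule under test is identical)
  rs <- region_set(c("Tect", "Crbl"))
  g <- default_grid()
  hubarch <- arch_masks(rs, hub = "Tect", homotopic = TRUE)
  m_true <- network_model(replicate(4, source_params(), simplify = FALSE),
                          a_fwd = hubarch$mask_fwd * 0.7,
                          a_bwd = hubarch$mask_bwd * 0.7,
                          mask_fwd = hubarch$mask_fwd,
                          mask_bwd = hubarch$mask_bwd,
                          region_names = rs$names)
  # full (union) model: every architecture's connections present
  archs <- list()
  for (hub in c("none", rs$pairs)) for (homo in c(FALSE, TRUE))
    archs[[length(archs) + 1]] <- c(list(hub = hub, homotopic = homo),
                                    arch_masks(rs, hub, FALSE, homo))
  umf <- Reduce(`+`, lapply(archs, `[[`, "mask_fwd")) > 0
  umb <- Reduce(`+`, lapply(archs, `[[`, "mask_bwd")) > 0
  m_full <- network_model(replicate(4, source_params(), simplify = FALSE),
                          a_fwd = umf * 0, a_bwd = umb * 0,
                          mask_fwd = umf * 1, mask_bwd = umb * 1,
                          region_names = rs$names)
  prior <- network_priors(m_full)
  wins <- 0
  for (seed in 1:5) {
    y <- simulate_lfp(m_true, 120, 0.001, seed = 700 + seed)
    dat <- mar_csd(y[, seq(1, ncol(y), by = 50)], 20, 8, g)
    inv <- invert(m_full, dat, prior)
    F <- vapply(archs, function(a)
      reduce_model(inv, prior, architecture_prior(prior, a, rs))$dF,
      numeric(1))
    hub_present <- vapply(archs, function(a) a$hub == "Tect", logical(1))
    wins <- wins +
      (zebradcm:::log_sum_exp(F[hub_present]) >
         zebradcm:::log_sum_exp(F[!hub_present]))
  }
  expect_gte(wins, 4)
})
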