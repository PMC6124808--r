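test_that("pca_project matches an independent eigendecomposition", {
  set.seed(13)
  n <- 40
  M <- cbind(matrix(rnorm(n * 5, sd = c(0.3, 0.2, 0.1, 0.1, 0.05)), n, 5,
                    byrow = TRUE),
             matrix(rnorm(n * 2, sd = c(0.2, 0.1)), n, 2, byrow = TRUE))
  colnames(M) <- c(paste0("h", 1:5), "t_e", "t_i")
  traj <- parameter_trajectory(seq_len(n), M)
  pc <- pca_project(traj)

  for (grp in c("gains", "time_constants")) {
    cols <- if (grp == "gains") paste0("h", 1:5) else c("t_e", "t_i")
    CV <- stats::cov(scale(M[, cols], scale = FALSE))
    eg <- eigen(CV, symmetric = TRUE)
    expect_equal(pc[[grp]]$all_variance_fractions,
                 eg$values / sum(eg$values), tolerance = 1e-8)
    for (k in seq_along(cols))
      expect_equal(abs(sum(pc[[grp]]$loadings[, k] * eg$vectors[, k])), 1,
                   tolerance = 1e-8)
    expect_equal(sum(pc[[grp]]$all_variance_fractions), 1, tolerance = 1e-10)
    # orthonormal loadings; reconstruction from all components is exact
    L <- pc[[grp]]$loadings
    expect_equal(crossprod(L), diag(length(cols)), tolerance = 1e-10,
                 ignore_attr = TRUE)
    rec <- pc[[grp]]$scores %*% t(L)
    ctr <- sweep(M[, cols], 2, pc[[grp]]$center)
    expect_lt(max(abs(rec - ctr)), 1e-8)
  }
})

test_that("rank-1 trajectories give a single component; constants error", {
  n <- 30
  u <- c(1, -0.5, 0.25, 0, 2) / sqrt(5.3125)
  M <- outer(seq(-1, 1, length.out = n), u)
  M <- cbind(M, t_e = seq(0, 0.3, length.out = n), t_i = 0.1)
  colnames(M) <- c(paste0("h", 1:5), "t_e", "t_i")
  traj <- parameter_trajectory(seq_len(n), M)
  pc <- pca_project(traj)
  expect_equal(pc$gains$all_variance_fractions[1], 1, tolerance = 1e-10)

  flat <- parameter_trajectory(1:5, matrix(0.3, 5, 2,
                                           dimnames = list(NULL, c("t_e", "t_i"))))
  expect_error(pca_project(flat, groups = list(tc = c("t_e", "t_i"))),
               "zero variance")
})

test_that("band power map: origin identity, totality, excitation direction", {
  cfg <- default_config()
  cfg$mapping$pred_grid <- list(lo_hz = 1, hi_hz = 60, by_hz = 1)
  base <- source_params()
  pc_conn <- c(1, 1, 0, -1, -1) / sqrt(4)
  pc_tau <- c(1, -1) / sqrt(2)
  g1 <- seq(-0.4, 0.4, length.out = 5)
  map <- band_power_map(base, pc_conn, pc_tau, g1, c(-0.2, 0, 0.2),
                        config = cfg)
  # zero-score point equals the base model's band power exactly
  fg <- frequency_grid(1, 60, 1)
  a <- auto_spectra(transfer_csd(single_source_model(base), fg,
                                 config = cfg))[, 1]
  sel <- fg$frequencies >= 1 & fg$frequencies <= 4
  expect_identical(map$surfaces$delta[3, 2], mean(log(a[sel])))

  # every grid point is finite or explicitly flagged
  for (b in names(map$surfaces))
    expect_true(all(is.finite(map$surfaces[[b]]) | map$unstable))

  # increasing excitation / decreasing inhibition raises broadband power
  tot <- vapply(seq_along(g1), function(i) {
    p <- base; p$h <- base$h + g1[i] * pc_conn
    m <- single_source_model(do.call(source_params, p))
    sum(auto_spectra(transfer_csd(m, fg, config = cfg))[, 1])
  }, numeric(1))
  expect_true(all(diff(tot) > 0))

  expect_error(band_power_map(source_params(h = c(3, 3, 0, 0, 0)),
                              pc_conn, pc_tau, 0, 0, config = cfg),
               "unstable")
})

test_that("trajectory overlay is a time-ordered reporting transform", {
  one <- trajectory_overlay(matrix(c(0.1, 0.2), 1), 5)
  expect_equal(nrow(one), 1)

  set.seed(14)
  t <- seq_len(50)
  r <- c(rep(0.1, 20), seq(0.1, 1, length.out = 30))  # excursion after "onset"
  scores <- cbind(r * cos(t / 5), r * sin(t / 5))
  path <- trajectory_overlay(scores[sample(50), ][order(sample(50)), ], t)
  path <- trajectory_overlay(scores, t)
  expect_equal(nrow(path), 50)
  expect_true(!is.unsorted(path$time_s))
  rad <- sqrt(path$s1^2 + path$s2^2)
  expect_lt(mean(rad[1:20]), mean(rad[31:50]))
})
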