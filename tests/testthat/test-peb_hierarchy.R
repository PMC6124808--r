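test_that("temporal basis honours its invariants", {
  t <- seq(30, 2970, by = 120)
  onset <- 900
  b <- build_basis(t, onset, fish_ids = rep(1:2, length.out = length(t)))
  X <- b$regressors

  pre <- t < onset
  expect_true(all(X[pre, c("tonic_step", "pk_monophasic", "ramp")] == 0))
  expect_true(all(X[!pre, "tonic_step"] == 1))
  expect_true(all(X[, "tonic_step"] %in% c(0, 1)))

  # monophasic effect: peak 1 at ~onset + 1800 s, unique maximum
  expect_equal(b$pk_peak_s - onset, 1801.6, tolerance = 0.1)
  peak_w <- which.max(X[, "pk_monophasic"])
  expect_equal(t[peak_w], t[which.min(abs(t - b$pk_peak_s))])
  expect_lte(max(X[, "pk_monophasic"]), 1)
  expect_equal(sum(X[, "pk_monophasic"] == max(X[, "pk_monophasic"])), 1)

  expect_equal(max(X[, "ramp"]), 1)
  expect_true(all(diff(X[!pre, "ramp"]) > 0))

  for (pair in list(c("dct1", "dct2"), c("dct1", "dct3"), c("dct2", "dct3")))
    expect_lt(abs(sum(X[, pair[1]] * X[, pair[2]])), 1e-10)

  fish_cols <- X[, grep("^fish_", colnames(X)), drop = FALSE]
  expect_true(all(rowSums(fish_cols) == 1))

  expect_error(build_basis(t, 5000), "outside the recording span")
})

test_that("peb_fit matches the conjugate linear-Gaussian oracle", {
  mus <- replicate(6, c(a = 0.3, b = -0.1), simplify = FALSE)
  fl <- fake_first_level(mus, sd = 0.1)
  X <- cbind(intercept = rep(1, 6))
  gp <- peb_fit(fl, X, c("a", "b"))
  # independent conjugate computation at the fitted gamma
  s2 <- exp(-gp$gamma)
  v <- 0.1^2 + s2
  prec <- 6 / v + 16                 # prior variance 1/16
  expected <- (6 / v) * c(0.3, -0.1) / prec
  expect_equal(as.numeric(gp$beta), expected, tolerance = 1e-8)
  # shrinkage is mild: group mean close to the shared window mean
  expect_lt(max(abs(as.numeric(gp$beta) - c(0.3, -0.1))), 0.02)
})

test_that("generative recovery: the driving regressor carries the effect", {
  t <- seq(30, 1170, by = 60)
  onset <- 420
  wins <- 0
  for (seed in 1:5) {
    set.seed(seed)
    basis <- build_basis(t, onset)
    X <- basis$regressors
    mus <- lapply(seq_along(t), function(w)
      c(p1 = 0.4 * unname(X[w, "tonic_step"]) + rnorm(1, 0, 0.03),
        p2 = rnorm(1, 0, 0.03)))
    gp <- peb_fit(fake_first_level(mus, 0.03), basis, c("p1", "p2"))
    b1 <- gp$beta["tonic_step", "p1"]
    others <- abs(gp$beta[setdiff(rownames(gp$beta), "fish_1"), ])
    others["tonic_step", "p1"] <- NA
    wins <- wins + (b1 > 0 && abs(b1) > max(others, na.rm = TRUE))
  }
  expect_gte(wins, 4)
})

test_that("paired permutation of windows and basis rows is invariant", {
  t <- seq(30, 1170, by = 120)
  basis <- build_basis(t, 420)
  set.seed(8)
  mus <- lapply(seq_along(t), function(w)
    c(p1 = rnorm(1, 0.2, 0.1), p2 = rnorm(1)))
  fl <- fake_first_level(mus)
  gp1 <- peb_fit(fl, basis, c("p1", "p2"))
  perm <- sample(length(t))
  gp2 <- peb_fit(fl[perm], basis$regressors[perm, , drop = FALSE],
                 c("p1", "p2"))
  expect_equal(gp1$beta, gp2$beta, tolerance = 1e-8)
  expect_equal(gp1$F_group, gp2$F_group, tolerance = 1e-6)
})

test_that("empirical priors only shrink window posteriors", {
  t <- seq(30, 1170, by = 120)
  basis <- build_basis(t, 420)
  set.seed(9)
  mus <- lapply(seq_along(t), function(w) c(p1 = rnorm(1), p2 = rnorm(1)))
  fl <- fake_first_level(mus, sd = 0.2)
  gp <- peb_fit(fl, basis, c("p1", "p2"))
  for (w in seq_along(t)) {
    expect_lte(sum(diag(gp$updated[[w]]$cov)),
               sum(diag(fl[[w]]$posterior$cov)) + 1e-12)
  }
})

test_that("sign recovery of known-sign regressor mixtures (20 seeds)", {
  t <- seq(30, 2370, by = 120)
  onset <- 600
  hits <- 0
  for (seed in 1:20) {
    set.seed(100 + seed)
    basis <- build_basis(t, onset)
    X <- basis$regressors
    mus <- lapply(seq_along(t), function(w)
      c(p1 = 0.3 * unname(X[w, "tonic_step"]) -
          0.3 * unname(X[w, "dct1"]) + rnorm(1, 0, 0.05)))
    gp <- peb_fit(fake_first_level(mus, 0.05), basis, "p1")
    hits <- hits + (gp$beta["tonic_step", "p1"] > 0) +
      (gp$beta["dct1", "p1"] < 0)
  }
  expect_gte(hits / 40, 0.9)
})

test_that("family comparison over fluctuating parameter sets (summary level)", {
  t <- seq(30, 2370, by = 120)
  onset <- 600
  basis <- build_basis(t, onset)
  X <- basis$regressors
  params <- c("Tect_L.h1", "Tect_R.h1", "Crbl_L.h1", "Crbl_R.h1")
  fams <- list(none = character(0), Tect = params[1:2], all = params)
  set.seed(12)
  # all regions fluctuate
  mus_all <- lapply(seq_along(t), function(w)
    stats::setNames(0.4 * unname(X[w, "tonic_step"]) + rnorm(4, 0, 0.03),
                    params))
  cmp_all <- peb_compare_sets(fake_first_level(mus_all, 0.03), basis, fams)
  expect_equal(cmp_all$winner, "all")
  # no fluctuations at all
  mus_null <- lapply(seq_along(t), function(w)
    stats::setNames(rnorm(4, 0, 0.03), params))
  cmp_null <- peb_compare_sets(fake_first_level(mus_null, 0.03), basis, fams)
  expect_equal(cmp_null$winner, "none")
  # evidences are comparative: probabilities invariant to common shifts
  expect_equal(sum(cmp_all$probabilities), 1, tolerance = 1e-12)
})

test_that("collinear designs are rejected with column names", {
  t <- seq(30, 1170, by = 120)
  X <- cbind(a = rep(1, length(t)), b = rep(1, length(t)))
  mus <- lapply(seq_along(t), function(w) c(p1 = 0.1))
  expect_error(peb_fit(fake_first_level(mus), X, "p1"), "collinear.*b")
})
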