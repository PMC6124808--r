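#' Intrinsic parameters of one neural-mass source
#'
#' A source is a three-population microcircuit (pyramidal projection
#' population P, excitatory interneurons E, inhibitory interneurons I).
#' Each population's membrane responds to presynaptic firing through a
#' second-order synaptic kernel with time constant `T` and the five
#' intrinsic connections carry gains `H1..H5` (the ordering of the
#' standard LFP-type source):
#' H1: E->P, H2: P->E, H3: P->I (excitatory); H4: I->P, H5: I->I
#' (inhibitory).  All fields are dimensionless log-scalings of the prior
#' means recorded in [default_config()]; a value of 0 reproduces the prior
#' mean exactly (see [effective_params()]).
#'
#' @param h Numeric length-5 vector of intrinsic gain log-scalings.
#' @param t_e,t_i Log-scalings of the excitatory / inhibitory time constants.
#' @param noise_amp,noise_exp Log-scalings of the endogenous input noise
#'   amplitude and spectral exponent (input PSD `amp / f^exp`).
#' @return Object of class `source_params`.
#' @export
source_params <- function(h = numeric(5), t_e = 0, t_i = 0,
                          noise_amp = 0, noise_exp = 0) {
  h <- as.numeric(h)
  if (length(h) != 5) stop("h must have length 5")
  p <- list(h = h, t_e = as.numeric(t_e), t_i = as.numeric(t_i),
            noise_amp = as.numeric(noise_amp),
            noise_exp = as.numeric(noise_exp))
  if (!all(vapply(p, function(v) all(is.finite(v)), logical(1))))
    stop("source_params: all fields must be finite")
  structure(p, class = "source_params")
}

#' Physical (effective) parameters of a source
#'
#' Maps log-scalings to physical values: `value_i = prior_mean_i * exp(p_i)`
#' for every scaled field.  Gains are in arbitrary units, time constants in
#' milliseconds.
#'
#' @param p A [source_params()] object.
#' @param config Package configuration (for the prior means).
#' @return List with `H` (length 5), `T_e_ms`, `T_i_ms`, `noise_amp`,
#'   `noise_exp`.
#' @export
effective_params <- function(p, config = default_config()) {
  stopifnot(inherits(p, "source_params"))
  if (!all(vapply(p, function(v) all(is.finite(v)), logical(1))))
    stop("effective_params: non-finite parameter value")
  pm <- config$neural_mass$prior_means
  list(H = pm$H * exp(p$h),
       T_e_ms = pm$T_e_ms * exp(p$t_e),
       T_i_ms = pm$T_i_ms * exp(p$t_i),
       noise_amp = pm$noise_amp * exp(p$noise_amp),
       noise_exp = pm$noise_exp * exp(p$noise_exp))
}

#' Coupled network of neural-mass sources
#'
#' The architecture hypothesis: a set of sources plus masked extrinsic
#' coupling matrices.  Entry `[i, j]` couples source `j`'s pyramidal firing
#' into source `i`; forward connections target the excitatory interneurons,
#' backward connections the pyramidal population.  The effective coupling
#' strength is `ext_scale * mask[i,j] * a[i,j]` -- an effect-size
#' parameterisation in which 0 means "connection absent", so that pinning a
#' coupling parameter at 0 removes the connection (used by Bayesian model
#' reduction over architectures).
#'
#' @param sources List of [source_params()] (or a single one), one per region.
#' @param a_fwd,a_bwd Numeric n x n coupling parameter matrices.
#' @param mask_fwd,mask_bwd Binary n x n structural masks (1 = exists).
#' @param lead Observation gain per source (length n or scalar).
#' @param region_names Optional character vector of region names.
#' @return Object of class `network_model`.
#' @export
network_model <- function(sources, a_fwd = NULL, a_bwd = NULL,
                          mask_fwd = NULL, mask_bwd = NULL, lead = 1,
                          region_names = NULL) {
  if (inherits(sources, "source_params")) sources <- list(sources)
  n <- length(sources)
  zero <- matrix(0, n, n)
  if (is.null(a_fwd)) a_fwd <- zero
  if (is.null(a_bwd)) a_bwd <- zero
  if (is.null(mask_fwd)) mask_fwd <- (a_fwd != 0) * 1
  if (is.null(mask_bwd)) mask_bwd <- (a_bwd != 0) * 1
  for (M in list(a_fwd, a_bwd, mask_fwd, mask_bwd))
    if (!is.matrix(M) || any(dim(M) != n)) stop("coupling matrices must be n x n")
  for (M in list(mask_fwd, mask_bwd)) {
    if (!all(M %in% c(0, 1))) stop("masks must be binary")
    if (any(diag(M) != 0)) stop("masks must have zero diagonal (no extrinsic self-connection)")
  }
  lead <- rep_len(as.numeric(lead), n)
  if (is.null(region_names)) region_names <- paste0("R", seq_len(n))
  if (any(grepl(".", region_names, fixed = TRUE)))
    stop("region names must not contain '.' (reserved for parameter names)")
  structure(list(n_sources = n, sources = sources,
                 a_fwd = a_fwd, a_bwd = a_bwd,
                 mask_fwd = mask_fwd, mask_bwd = mask_bwd,
                 lead = lead, region_names = region_names),
            class = "network_model")
}

#' Single-source convenience constructor
#' @param params A [source_params()] object.
#' @param ... Passed to [network_model()].
#' @return A one-source `network_model`.
#' @export
single_source_model <- function(params = source_params(), ...)
  network_model(list(params), ...)

#' Frequency grid
#'
#' @param lo_hz,hi_hz,by_hz Grid limits and resolution in Hz.
#' @param frequencies Alternatively, an explicit strictly increasing vector.
#' @return Object of class `frequency_grid` with fields `frequencies` and
#'   `resolution`.
#' @export
frequency_grid <- function(lo_hz = 0.25, hi_hz = 10, by_hz = 0.25,
                           frequencies = NULL) {
  if (is.null(frequencies)) frequencies <- seq(lo_hz, hi_hz, by = by_hz)
  frequencies <- as.numeric(frequencies)
  if (any(frequencies <= 0)) stop("frequencies must be > 0")
  if (any(diff(frequencies) <= 0)) stop("frequencies must be strictly increasing")
  structure(list(frequencies = frequencies,
                 resolution = if (length(frequencies) > 1)
                   stats::median(diff(frequencies)) else NA_real_),
            class = "frequency_grid")
}

#' Cross-spectral density container
#'
#' @param grid A [frequency_grid()].
#' @param csd Complex array n x n x nfreq (Hermitian at every frequency).
#' @param region_names Optional channel names.
#' @param validate Check Hermitian symmetry and non-negative auto-spectra.
#' @return Object of class `cross_spectrum`.
#' @export
cross_spectrum <- function(grid, csd, region_names = NULL, validate = TRUE) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (length(dim(csd)) == 2) dim(csd) <- c(1, 1, length(csd))
  nf <- length(grid$frequencies)
  if (dim(csd)[3] != nf || dim(csd)[1] != dim(csd)[2])
    stop("csd must be n x n x nfreq")
  if (validate) {
    for (k in seq_len(nf)) {
      S <- csd[, , k, drop = FALSE]; dim(S) <- dim(csd)[1:2]
      if (max(abs(S - Conj(t(S)))) > 1e-10)
        stop("csd not Hermitian at frequency ", grid$frequencies[k])
      if (any(Re(diag(S)) < -1e-12))
        stop("negative auto-spectrum at frequency ", grid$frequencies[k])
    }
  }
  structure(list(grid = grid, csd = csd, region_names = region_names),
            class = "cross_spectrum")
}

#' Auto-spectra of a cross-spectrum
#' @param cs A `cross_spectrum`.
#' @return Real matrix nfreq x n of auto-spectral densities.
#' @export
auto_spectra <- function(cs) {
  stopifnot(inherits(cs, "cross_spectrum"))
  n <- dim(cs$csd)[1]
  out <- sapply(seq_len(n), function(i) Re(cs$csd[i, i, ]))
  matrix(out, ncol = n, dimnames = list(NULL, cs$region_names))
}

# ---- internal machinery ----------------------------------------------------

# Assemble effective physical parameters for the whole network.
# Time constants are converted to seconds for the dynamics.
network_effective <- function(m, config = default_config()) {
  stopifnot(inherits(m, "network_model"))
  eff <- lapply(m$sources, effective_params, config = config)
  n <- m$n_sources
  list(n = n,
       H = t(vapply(eff, `[[`, numeric(5), "H")),
       TE = vapply(eff, `[[`, numeric(1), "T_e_ms") / 1000,
       TI = vapply(eff, `[[`, numeric(1), "T_i_ms") / 1000,
       noise_amp = vapply(eff, `[[`, numeric(1), "noise_amp"),
       noise_exp = vapply(eff, `[[`, numeric(1), "noise_exp"),
       AF = config$neural_mass$ext_scale * m$mask_fwd * m$a_fwd,
       AB = config$neural_mass$ext_scale * m$mask_bwd * m$a_bwd,
       slope = config$neural_mass$sigmoid_slope,
       lead = m$lead)
}

nm_sigmoid <- function(v, r) 1 / (1 + exp(-r * v)) - 0.5
nm_sigmoid_d <- function(v, r) { s <- 1 / (1 + exp(-r * v)); r * s * (1 - s) }

# Derivative field at state x (length 6n), zero input unless given.
nm_dynamics <- function(x, eff, u = numeric(eff$n)) {
  n <- eff$n
  idx <- function(k) seq(k, by = 6, length.out = n)
  vE <- x[idx(1)]; zE <- x[idx(2)]; vP <- x[idx(3)]
  zP <- x[idx(4)]; vI <- x[idx(5)]; zI <- x[idx(6)]
  sP <- nm_sigmoid(vP, eff$slope)
  sE <- nm_sigmoid(vE, eff$slope)
  sI <- nm_sigmoid(vI, eff$slope)
  TE <- eff$TE; TI <- eff$TI; H <- eff$H
  dx <- numeric(6 * n)
  dx[idx(1)] <- zE
  dx[idx(2)] <- (H[, 2] * sP + drop(eff$AF %*% sP) + u) / TE^2 -
    2 * zE / TE - vE / TE^2
  dx[idx(3)] <- zP
  dx[idx(4)] <- (H[, 1] * sE - H[, 4] * sI + drop(eff$AB %*% sP)) / TE^2 -
    2 * zP / TE - vP / TE^2
  dx[idx(5)] <- zI
  dx[idx(6)] <- (H[, 3] * sP - H[, 5] * sI) / TI^2 - 2 * zI / TI - vI / TI^2
  dx
}

# Jacobian of nm_dynamics at state x.
nm_jacobian <- function(x, eff) {
  n <- eff$n
  J <- matrix(0, 6 * n, 6 * n)
  idx <- function(i, k) 6 * (i - 1) + k
  vE <- x[seq(1, by = 6, length.out = n)]
  vP <- x[seq(3, by = 6, length.out = n)]
  vI <- x[seq(5, by = 6, length.out = n)]
  dP <- nm_sigmoid_d(vP, eff$slope)
  dE <- nm_sigmoid_d(vE, eff$slope)
  dI <- nm_sigmoid_d(vI, eff$slope)
  TE <- eff$TE; TI <- eff$TI; H <- eff$H
  for (i in seq_len(n)) {
    te <- TE[i]; ti <- TI[i]
    J[idx(i, 1), idx(i, 2)] <- 1
    J[idx(i, 2), idx(i, 1)] <- -1 / te^2
    J[idx(i, 2), idx(i, 2)] <- -2 / te
    J[idx(i, 2), idx(i, 3)] <- H[i, 2] * dP[i] / te^2
    J[idx(i, 3), idx(i, 4)] <- 1
    J[idx(i, 4), idx(i, 1)] <- H[i, 1] * dE[i] / te^2
    J[idx(i, 4), idx(i, 3)] <- -1 / te^2
    J[idx(i, 4), idx(i, 4)] <- -2 / te
    J[idx(i, 4), idx(i, 5)] <- -H[i, 4] * dI[i] / te^2
    J[idx(i, 5), idx(i, 6)] <- 1
    J[idx(i, 6), idx(i, 3)] <- H[i, 3] * dP[i] / ti^2
    J[idx(i, 6), idx(i, 5)] <- -(1 / ti^2) - H[i, 5] * dI[i] / ti^2
    J[idx(i, 6), idx(i, 6)] <- -2 / ti
    for (j in seq_len(n)) {
      if (eff$AF[i, j] != 0)
        J[idx(i, 2), idx(j, 3)] <- J[idx(i, 2), idx(j, 3)] +
          eff$AF[i, j] * dP[j] / te^2
      if (eff$AB[i, j] != 0)
        J[idx(i, 4), idx(j, 3)] <- J[idx(i, 4), idx(j, 3)] +
          eff$AB[i, j] * dP[j] / te^2
    }
  }
  J
}

#' Steady state of a network model
#'
#' Newton root-finding on the deterministic dynamics (no input).  Because
#' the firing sigmoid is centred, the origin is always a root; coupled
#' networks may have further roots, and the solver converges to the one
#' nearest the initialisation.
#'
#' @param m A [network_model()].
#' @param init Initial state (length `6 * n_sources`), default zeros.
#' @param tol Residual norm required for convergence.
#' @param max_iter Newton iteration budget.
#' @param config Package configuration.
#' @return Numeric state vector with attribute `residual`.
#' @export
fixed_point <- function(m, init = NULL, tol = 1e-8, max_iter = 100,
                        config = default_config()) {
  eff <- network_effective(m, config)
  x <- if (is.null(init)) numeric(6 * eff$n) else as.numeric(init)
  if (length(x) != 6 * eff$n) stop("init must have 6 states per source")
  for (it in seq_len(max_iter)) {
    fx <- nm_dynamics(x, eff)
    if (sqrt(sum(fx^2)) < tol) {
      attr(x, "residual") <- sqrt(sum(fx^2))
      return(x)
    }
    J <- nm_jacobian(x, eff)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step)) step <- fx * 1e-3
    x <- x - step
  }
  fx <- nm_dynamics(x, eff)
  res <- matrix(fx, nrow = 6)
  worst <- which.max(colSums(res^2))
  stop("fixed_point: no convergence within ", max_iter,
       " iterations (worst source: ", m$region_names[worst],
       ", residual ", format(sqrt(sum(fx^2)), digits = 3), ")")
}

#' Predicted steady-state cross-spectral density
#'
#' Linearises the network dynamics about its fixed point and propagates the
#' parameterised input-noise spectra (`amp / f^exp` per source, entering the
#' excitatory interneuron population) through the transfer function
#' `T(f) = C (i 2 pi f I - J)^(-1) L`, giving
#' `S(f) = T(f) diag(g_u(f)) T(f)^H` -- Hermitian and positive
#' semi-definite by construction.
#'
#' @param m A [network_model()].
#' @param grid A [frequency_grid()].
#' @param config Package configuration.
#' @return A [cross_spectrum()].
#' @export
transfer_csd <- function(m, grid, config = default_config()) {
  stopifnot(inherits(grid, "frequency_grid"))
  eff <- network_effective(m, config)
  n <- eff$n
  x0 <- fixed_point(m, config = config)
  J <- nm_jacobian(x0, eff)
  ev <- eigen(J)
  if (max(Re(ev$values)) >= 0)
    stop("transfer_csd: fixed point is linearly unstable (max Re eigenvalue ",
         format(max(Re(ev$values)), digits = 4), ")",
         call. = FALSE)
  L <- matrix(0, 6 * n, n)
  Cm <- matrix(0, n, 6 * n)
  for (i in seq_len(n)) {
    L[6 * (i - 1) + 2, i] <- 1 / eff$TE[i]^2
    Cm[i, 6 * (i - 1) + 3] <- eff$lead[i]
  }
  f <- grid$frequencies
  nf <- length(f)
  csd <- array(0i, c(n, n, nf))
  # transfer via eigendecomposition when well conditioned, else direct solves
  use_eig <- tryCatch(kappa(ev$vectors) < 1e10, error = function(e) FALSE)
  if (use_eig) {
    CV <- Cm %*% ev$vectors
    VL <- solve(ev$vectors, L)
    for (k in seq_len(nf)) {
      g <- 1 / (2i * pi * f[k] - ev$values)
      Tf <- CV %*% (VL * g)
      Su <- eff$noise_amp^2 / f[k]^eff$noise_exp
      S <- Tf %*% (Su * Conj(t(Tf)))
      csd[, , k] <- (S + Conj(t(S))) / 2
    }
  } else {
    I6 <- diag(6 * n)
    for (k in seq_len(nf)) {
      Tf <- Cm %*% solve(2i * pi * f[k] * I6 - J, L)
      Su <- eff$noise_amp^2 / f[k]^eff$noise_exp
      S <- Tf %*% (Su * Conj(t(Tf)))
      csd[, , k] <- (S + Conj(t(S))) / 2
    }
  }
  cross_spectrum(grid, csd, region_names = m$region_names, validate = FALSE)
}

# Sample a real noise series with two-sided PSD amp/|f|^gam by FFT synthesis.
# Returns an n-length series at sampling step dt; DC (and Nyquist) are zeroed.
pink_noise <- function(n, dt, amp = 1, gam = 1) {
  nf <- floor(n / 2)
  X <- complex(n)
  f <- (1:nf) / (n * dt)
  sdk <- sqrt(n / dt * amp / f^gam / 2)
  re <- stats::rnorm(nf) * sdk
  im <- stats::rnorm(nf) * sdk
  if (n %% 2 == 0) im[nf] <- 0         # Nyquist bin must be real
  X[2:(nf + 1)] <- complex(real = re, imaginary = im)
  if (n %% 2 == 0) {
    X[(nf + 2):n] <- Conj(X[nf:2])
  } else {
    X[(nf + 2):n] <- Conj(X[(nf + 1):2])
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Simulate LFP-like output of a network model
#'
#' Integrates the stochastic neural-mass network with per-source pink-noise
#' input (fixed-step RK4, zero-order-hold input) and returns the pyramidal
#' membrane potentials after discarding the first 10% of samples as burn-in.
#' Reproducible: the seed governs a single noise stream per source.
#'
#' @param m A [network_model()].
#' @param duration_s,dt_s Duration and integration step in seconds.
#' @param seed Integer RNG seed.
#' @param burnin_frac Fraction of initial samples discarded (default 0.1).
#' @return Matrix `n_sources x n_kept` with attributes `fs` and `dt_s`.
#' @export
simulate_lfp <- function(m, duration_s, dt_s = 0.001, seed = 1,
                         burnin_frac = NULL, config = default_config()) {
  eff <- network_effective(m, config)
  if (is.null(burnin_frac)) burnin_frac <- config$neural_mass$sim$burnin_frac
  nt <- round(duration_s / dt_s)
  if (nt < 100) stop("simulate_lfp: need at least 100 samples")
  if (dt_s > min(eff$TE) / 4)
    stop("simulate_lfp: dt too coarse for the fastest time constant (need dt <= T_E/4)")
  U <- with_seed(seed, {
    U <- matrix(0, eff$n, nt)
    for (i in seq_len(eff$n))
      U[i, ] <- pink_noise(nt, dt_s, eff$noise_amp[i]^2, eff$noise_exp[i])
    U
  })
  res <- nm_integrate_cpp(eff$H, eff$TE, eff$TI, eff$AF, eff$AB, eff$slope,
                          U, dt_s, numeric(6 * eff$n))
  if (res$diverged_at > 0)
    stop("simulate_lfp: numerical blow-up at t = ",
         format(res$diverged_at * dt_s, digits = 4), " s")
  keep <- seq.int(floor(nt * burnin_frac) + 1, nt)
  out <- res$out[, keep, drop = FALSE] * eff$lead
  rownames(out) <- m$region_names
  attr(out, "fs") <- 1 / dt_s
  attr(out, "dt_s") <- dt_s
  out
}

# Low-level integration with explicit input and initial state; used by the
# synthetic-data generator to stitch quasi-static segments with a continuous
# state.  Returns list(out, xfinal).
nm_integrate <- function(m, U, dt_s, x0 = NULL, config = default_config()) {
  eff <- network_effective(m, config)
  if (is.null(x0)) x0 <- numeric(6 * eff$n)
  res <- nm_integrate_cpp(eff$H, eff$TE, eff$TI, eff$AF, eff$AB, eff$slope,
                          U, dt_s, as.numeric(x0))
  if (res$diverged_at > 0)
    stop("nm_integrate: numerical blow-up at step ", res$diverged_at)
  res
}

# Linear stability of the fixed point; TRUE if all eigenvalues in the left
# half-plane.
is_stable <- function(m, config = default_config()) {
  ok <- tryCatch({
    eff <- network_effective(m, config)
    x0 <- fixed_point(m, config = config)
    max(Re(eigen(nm_jacobian(x0, eff), only.values = TRUE)$values)) < 0
  }, error = function(e) FALSE)
  ok
}
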