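#' Second-level temporal basis
#'
#' Design matrix for slow parameter fluctuations across a seizure
#' experiment: a tonic step at PTZ onset, a monophasic pharmacokinetic
#' effect (double exponential `(1 - exp(-tau/tau1)) * exp(-tau/tau2)`,
#' normalised to peak 1; with the default constants the peak sits at
#' onset + 1800 s), a linear ramp from onset (scaled to max 1), the three
#' lowest non-constant discrete-cosine components over the post-onset
#' windows, and one indicator column per fish (random between-fish
#' effects, which double as per-fish intercepts).
#'
#' @param window_times Window-centre times in seconds.
#' @param ptz_onset_s PTZ onset time (must lie within the recording span).
#' @param fish_ids Fish identity per window (factor-like; default one fish).
#' @param config Package configuration (`peb$pk_tau1_s`, `peb$pk_tau2_s`,
#'   `peb$n_dct`).
#' @return Object of class `temporal_basis` with fields `window_times`,
#'   `regressors` (named columns), `ptz_onset_s`.
#' @export
build_basis <- function(window_times, ptz_onset_s,
                        fish_ids = rep(1, length(window_times)),
                        config = default_config()) {
  t <- as.numeric(window_times)
  if (ptz_onset_s < min(t) || ptz_onset_s > max(t))
    stop("build_basis: PTZ onset outside the recording span")
  tau <- pmax(0, t - ptz_onset_s)
  post <- t >= ptz_onset_s
  t1 <- config$peb$pk_tau1_s
  t2 <- config$peb$pk_tau2_s
  pk_raw <- function(x) (1 - exp(-x / t1)) * exp(-x / t2)
  tau_star <- t1 * log((t1 + t2) / t1)      # analytic peak location
  pk <- ifelse(post, pk_raw(tau) / pk_raw(tau_star), 0)
  ramp <- ifelse(post, tau, 0)
  if (max(ramp) > 0) ramp <- ramp / max(ramp)
  X <- cbind(tonic_step = as.numeric(post), pk_monophasic = pk, ramp = ramp)
  np <- sum(post)
  # only as many DCT components as the post-onset windows can support
  ndct <- min(config$peb$n_dct, max(np - 1, 0))
  if (ndct > 0) {
    dct <- matrix(0, length(t), ndct,
                  dimnames = list(NULL, paste0("dct", seq_len(ndct))))
    pos <- seq_len(np)
    for (k in seq_len(ndct))
      dct[post, k] <- cos(pi * k * (pos - 0.5) / np)
    X <- cbind(X, dct)
  }
  ids <- as.character(fish_ids)
  for (fid in unique(ids))
    X <- cbind(X, as.numeric(ids == fid))
  colnames(X)[(ncol(X) - length(unique(ids)) + 1):ncol(X)] <-
    paste0("fish_", unique(ids))
  structure(list(window_times = t, regressors = X,
                 ptz_onset_s = ptz_onset_s, fish_ids = ids,
                 pk_peak_s = ptz_onset_s + tau_star),
            class = "temporal_basis")
}

# Coerce basis input to a design matrix with named columns.
basis_matrix <- function(basis) {
  if (inherits(basis, "temporal_basis")) return(basis$regressors)
  if (is.matrix(basis)) {
    if (is.null(colnames(basis))) stop("basis matrix must have column names")
    return(basis)
  }
  stop("basis must be a temporal_basis or a named-column matrix")
}

# Extract per-window posterior summaries for a parameter subset.
peb_data <- function(first_level, which_params) {
  if (inherits(first_level, "window_inversions"))
    first_level <- first_level$results
  ok <- vapply(first_level, function(r) is.null(r$failed), logical(1))
  if (!any(ok)) stop("no successful first-level inversions")
  mus <- lapply(first_level[ok], function(r) {
    mu <- r$posterior$mean[which_params]
    if (any(is.na(mu))) stop("parameter(s) missing from first level: ",
                             paste(which_params[is.na(mu)], collapse = ", "))
    mu
  })
  Ss <- lapply(first_level[ok], function(r) {
    S <- r$posterior$cov[which_params, which_params, drop = FALSE]
    d <- diag(S)
    if (any(d < 1e-10)) diag(S)[d < 1e-10] <- 1e-10
    S
  })
  list(mu = mus, S = Ss, ok = ok)
}

# Marginal log evidence of the second-level linear-Gaussian model at a
# given between-window log precision gamma, with prior variances vb on the
# stacked effect vector.  Returns evidence pieces for reuse in BMR.
peb_evidence <- function(mu, S, X, vb, gamma) {
  W <- length(mu)
  P <- length(mu[[1]])
  R <- ncol(X)
  nb <- P * R
  A <- matrix(0, nb, nb)
  r <- numeric(nb)
  quad <- 0
  ldV <- 0
  s2 <- exp(-gamma)
  for (w in seq_len(W)) {
    Vw <- S[[w]] + s2 * diag(P)
    iVw <- robust_inv(Vw)
    ldV <- ldV + logdet(Vw)
    # design block for window w: row p has X[w, ] in the p-th R-block
    xw <- X[w, ]
    # A += kron(outer block); exploit structure: Xw^T iV Xw in blocks
    for (p in seq_len(P)) for (q in seq_len(P)) {
      bi <- (p - 1) * R + seq_len(R)
      bj <- (q - 1) * R + seq_len(R)
      A[bi, bj] <- A[bi, bj] + iVw[p, q] * tcrossprod(xw)
    }
    mv <- drop(iVw %*% mu[[w]])
    for (p in seq_len(P))
      r[(p - 1) * R + seq_len(R)] <- r[(p - 1) * R + seq_len(R)] + mv[p] * xw
    quad <- quad + drop(t(mu[[w]]) %*% mv)
  }
  list(A = A, r = r, quad = quad, ldV = ldV, n = W * P, P = P, R = R,
       vb = vb, gamma = gamma)
}

# Complete the evidence given a prior variance vector over the stacked
# effects (length P*R); returns list(F, beta_mean, beta_prec).
peb_complete <- function(pieces, vb) {
  Pb <- pieces$A + diag(1 / vb, length(vb))
  cPb <- chol((Pb + t(Pb)) / 2)
  mb <- backsolve(cPb, backsolve(cPb, pieces$r, transpose = TRUE))
  ldPb <- 2 * sum(log(diag(cPb)))
  Fv <- -0.5 * (pieces$n * log(2 * pi) + pieces$ldV + sum(log(vb)) + ldPb +
                  pieces$quad - drop(t(mb) %*% Pb %*% mb))
  list(F = Fv, beta_mean = mb, beta_prec = Pb)
}

#' Parametric empirical Bayes over windowed inversions
#'
#' Second-level model: the first-level posterior means of the selected
#' parameters are modelled as `mu_w = t(B) x_w + e_w`, where `x_w` is the
#' window's row of the temporal basis, `B` the effect matrix with Gaussian
#' prior `N(0, beta_prior_var)`, and `e_w ~ N(0, S_w + exp(-gamma) I)`
#' combines first-level posterior uncertainty with a between-window
#' random-effect variance whose log precision `gamma` is optimised against
#' the marginal likelihood (with a broad Gaussian prior).  This
#' summary-statistic formulation gives a closed-form Gaussian evidence,
#' supports exact model reduction over effect subsets, and yields
#' empirically shrunk window posteriors.
#'
#' @param first_level [invert_windows()] output or list of [invert()]
#'   results.
#' @param basis A [build_basis()] result or named-column design matrix
#'   (rows = windows).
#' @param which_params Character vector of first-level parameter names to
#'   model.
#' @param config Package configuration.
#' @return Object of class `group_posterior`: `beta` (regressors x
#'   parameters effect matrix), `beta_cov`, `F_group`, `gamma`, `updated`
#'   (shrunk per-window posteriors), plus evidence pieces for reduction.
#' @export
peb_fit <- function(first_level, basis, which_params,
                    config = default_config()) {
  X <- basis_matrix(basis)
  d <- peb_data(first_level, which_params)
  W <- length(d$mu)
  if (W < 2) stop("peb_fit: need >= 2 windows")
  if (nrow(X) != length(d$ok))
    stop("basis rows must match the number of windows")
  X <- X[d$ok, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    stop("peb_fit: collinear design; offending column(s): ",
         paste(colnames(X)[drop_cols], collapse = ", "))
  }
  P <- length(which_params)
  R <- ncol(X)
  vb <- rep(config$peb$beta_prior_var, P * R)
  vg <- config$peb$gamma_prior_var
  obj <- function(gamma) {
    pieces <- peb_evidence(d$mu, d$S, X, vb, gamma)
    peb_complete(pieces, vb)$F - 0.5 * gamma^2 / vg
  }
  opt <- stats::optimize(obj, c(-6, 14), maximum = TRUE, tol = 1e-4)
  gamma <- opt$maximum
  pieces <- peb_evidence(d$mu, d$S, X, vb, gamma)
  fit <- peb_complete(pieces, vb)
  Bc <- robust_inv(fit$beta_prec)
  beta <- matrix(fit$beta_mean, nrow = R, ncol = P,
                 dimnames = list(colnames(X), which_params))
  # empirical-prior update of each window posterior
  s2 <- exp(-gamma)
  updated <- vector("list", W)
  for (w in seq_len(W)) {
    pred <- drop(t(beta) %*% X[w, ])
    iS <- robust_inv(d$S[[w]])
    prec <- iS + diag(1 / s2, P)
    cov_w <- robust_inv(prec)
    mean_w <- drop(cov_w %*% (iS %*% d$mu[[w]] + pred / s2))
    updated[[w]] <- list(mean = stats::setNames(mean_w, which_params),
                         cov = cov_w)
  }
  structure(list(beta = beta, beta_cov = Bc,
                 F_group = fit$F - 0.5 * gamma^2 / vg,
                 gamma = gamma, params = which_params,
                 regressors = colnames(X), X = X,
                 pieces = pieces, vb = vb, vg = vg, updated = updated,
                 data = d), class = "group_posterior")
}

#' Evidence for a reduced second-level model
#'
#' Re-evaluates the exact marginal evidence with selected effect entries
#' pinned (prior variance 1e-8) at the full model's optimised random-effect
#' precision: Bayesian model reduction on the group model.
#'
#' @param gp A [peb_fit()] result.
#' @param free Logical or index matrix/vector over (regressor, parameter)
#'   effects; pinned entries are fixed at zero effect.  May be a logical
#'   matrix shaped like `gp$beta`.
#' @return Log evidence of the reduced model (comparable to `gp$F_group`).
#' @export
peb_reduce <- function(gp, free) {
  R <- length(gp$regressors)
  P <- length(gp$params)
  # stacked effect vector is parameter-major (R entries per parameter), which
  # is exactly column-major order of the R x P effect matrix
  if (is.matrix(free)) free <- as.vector(free)
  if (is.logical(free)) {
    if (length(free) != R * P) stop("free mask has wrong length")
  } else stop("free must be logical")
  vb <- gp$vb
  vb[!free] <- 1e-8
  peb_complete(gp$pieces, vb)$F - 0.5 * gp$gamma^2 / gp$vg
}

# logical matrix R x P marking effect entries free for a parameter subset:
# nuisance columns (fish_* indicators / intercept) stay free for all
# parameters, effect columns only for `params`.
effect_mask <- function(gp, params,
                        nuisance = grepl("^fish_|^intercept$", gp$regressors)) {
  M <- matrix(FALSE, length(gp$regressors), length(gp$params),
              dimnames = list(gp$regressors, gp$params))
  M[nuisance, ] <- TRUE
  M[!nuisance, gp$params %in% params] <- TRUE
  M
}

#' Compare families of fluctuating parameter sets
#'
#' Fits the full second-level model over the union of all named parameters
#' and scores each family by Bayesian model reduction: a family's model
#' lets its parameters load on the seizure-effect regressors, while all
#' other parameters keep only nuisance (fish / intercept) effects.
#'
#' @param first_level [invert_windows()] output or list of [invert()]
#'   results.
#' @param basis A [build_basis()] result or design matrix.
#' @param families Named list of character vectors of parameter names
#'   (may be empty for the no-fluctuation family).
#' @param config Package configuration.
#' @return List with `F` (named per-family log evidences), `probabilities`
#'   (softmax), `winner`, and the full `fit`.
#' @export
peb_compare_sets <- function(first_level, basis, families,
                             config = default_config()) {
  all_params <- unique(unlist(families))
  if (length(all_params) == 0) stop("families name no parameters")
  gp <- peb_fit(first_level, basis, all_params, config = config)
  F <- vapply(families, function(fam)
    peb_reduce(gp, effect_mask(gp, fam)), numeric(1))
  prob <- exp(F - log_sum_exp(F))
  list(F = F, probabilities = prob,
       winner = names(families)[which.max(F)], fit = gp)
}

#' Construct-validity analysis on kernel-convolved segments
#'
#' Inverts each fluorescence segment with a single-source model, then asks
#' which single intrinsic parameter best explains the between-segment
#' differences: a second-level design with an intercept and a linear
#' regressor across segments is fitted, and single-parameter explanations
#' (linear effect free for exactly one parameter) are compared by model
#' reduction, against a null with no linear effects.
#'
#' @param segments List of single-channel series at a common sampling rate,
#'   or the output of [generate_validation_segments()].
#' @param candidate_params Parameters competing to explain the differences.
#' @param fs Sampling rate in Hz (taken from `segments$fs` if present).
#' @param config Package configuration.
#' @return List with `winner`, `F` (named, including `null`),
#'   `bayes_factor` (winner vs runner-up, log units), `estimates`
#'   (per-segment posterior means of the winning parameter), and the
#'   per-segment inversion results.
#' @export
construct_validity <- function(segments,
                                    candidate_params = c(paste0("h", 1:5),
                                                         "t_e", "t_i"),
                                    fs = NULL, config = default_config()) {
  if (is.list(segments) && !is.null(segments$segments)) {
    if (is.null(fs)) fs <- segments$fs
    segments <- segments$segments
  }
  if (is.null(fs)) stop("fs must be given")
  ns <- length(segments)
  if (ns < 2) stop("need at least 2 segments")
  gcfg <- config$features$grid
  grid <- frequency_grid(gcfg$lo_hz, min(gcfg$hi_hz, 0.45 * fs), gcfg$by_hz)
  m <- single_source_model(source_params())
  prior <- network_priors(m, config)
  csds <- lapply(segments, function(seg)
    mar_csd(as.numeric(seg), fs, order = config$features$mar_order,
            grid = grid))
  scl <- common_scale(m, csds, config)
  results <- lapply(csds, function(cs)
    invert(m, cs, prior, config = config, scale = scl))
  X <- cbind(intercept = rep(1, ns),
             linear = seq(-1, 1, length.out = ns))
  pnames <- paste0("R1.", candidate_params)
  gp <- peb_fit(results, X, pnames, config = config)
  Fs <- c(null = peb_reduce(gp, effect_mask(gp, character(0))),
          stats::setNames(
            vapply(pnames, function(p)
              peb_reduce(gp, effect_mask(gp, p)), numeric(1)),
            candidate_params))
  Fcand <- Fs[-1]
  winner <- names(Fcand)[which.max(Fcand)]
  est <- vapply(results, function(r)
    r$posterior$mean[[paste0("R1.", winner)]], numeric(1))
  list(winner = winner, F = Fs,
       bayes_factor = max(Fcand) - max(Fs[names(Fs) != winner]),
       estimates = est, results = results)
}
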