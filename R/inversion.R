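#' Gaussian prior density over model parameters
#'
#' @param mean Named numeric vector of prior means (log-scalings /
#'   effect sizes).
#' @param cov Prior covariance matrix (or a vector of variances).  Entries
#'   with zero variance mark fixed parameters, which are excluded from
#'   optimisation but retained in the parameter vector so that model
#'   spaces with different free subsets stay dimension-aligned.
#' @return Object of class `prior_density`.
#' @export
prior_density <- function(mean, cov) {
  mean <- stats::setNames(as.numeric(mean), names(mean))
  if (is.null(dim(cov))) cov <- diag(as.numeric(cov), length(mean))
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-8)))
    stop("prior covariance must be symmetric")
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("prior covariance must be positive semi-definite")
  if (is.null(names(mean))) names(mean) <- paste0("p", seq_along(mean))
  dimnames(cov) <- list(names(mean), names(mean))
  structure(list(mean = mean, cov = (cov + t(cov)) / 2), class = "prior_density")
}

#' Default priors for a network model
#'
#' One free parameter per intrinsic field of every source (5 gains and 2
#' time constants with prior variance 1/16; the 2 input-noise nuisance
#' parameters get a looser variance of 1, because the observed fluorescence
#' spectrum's overall tilt folds in the calcium-kernel response, roughly
#' two extra powers of frequency, which the input spectral exponent must be
#' able to absorb) and one per structurally present extrinsic connection
#' (prior variance 1/8, prior mean 0 = connection at its baseline value in
#' `m`).  Extrinsic parameters are deviations added to the baseline
#' coupling in `m`, so the null point of the prior reproduces `m` exactly.
#'
#' @param m A [network_model()].
#' @param config Package configuration.
#' @return A [prior_density()].
#' @export
network_priors <- function(m, config = default_config()) {
  vi <- config$inversion$prior_var$intrinsic
  ve <- config$inversion$prior_var$extrinsic
  vn <- config$inversion$prior_var$noise
  nm <- character(0); vr <- numeric(0)
  for (i in seq_len(m$n_sources)) {
    r <- m$region_names[i]
    nm <- c(nm, paste0(r, ".", c(paste0("h", 1:5), "t_e", "t_i",
                                 "noise_amp", "noise_exp")))
    vr <- c(vr, rep(vi, 8), vn)
  }
  for (i in seq_len(m$n_sources)) for (j in seq_len(m$n_sources)) {
    if (m$mask_fwd[i, j] == 1) {
      nm <- c(nm, paste0("fwd.", m$region_names[i], ".", m$region_names[j]))
      vr <- c(vr, ve)
    }
  }
  for (i in seq_len(m$n_sources)) for (j in seq_len(m$n_sources)) {
    if (m$mask_bwd[i, j] == 1) {
      nm <- c(nm, paste0("bwd.", m$region_names[i], ".", m$region_names[j]))
      vr <- c(vr, ve)
    }
  }
  prior_density(stats::setNames(numeric(length(nm)), nm), vr)
}

# Apply a named parameter vector to a network model.  Intrinsic entries set
# the source log-scalings; extrinsic entries are added to the baseline
# coupling parameters.
apply_params <- function(m, theta) {
  nms <- names(theta)
  out <- m
  for (i in seq_len(m$n_sources)) {
    r <- m$region_names[i]
    p <- out$sources[[i]]
    g <- function(field) {
      k <- paste0(r, ".", field)
      if (k %in% nms) theta[[k]] else NULL
    }
    h <- p$h
    for (q in 1:5) if (!is.null(v <- g(paste0("h", q)))) h[q] <- v
    out$sources[[i]] <- source_params(
      h = h,
      t_e = if (!is.null(v <- g("t_e"))) v else p$t_e,
      t_i = if (!is.null(v <- g("t_i"))) v else p$t_i,
      noise_amp = if (!is.null(v <- g("noise_amp"))) v else p$noise_amp,
      noise_exp = if (!is.null(v <- g("noise_exp"))) v else p$noise_exp)
  }
  ext <- grep("^(fwd|bwd)\\.", nms, value = TRUE)
  for (k in ext) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    i <- match(parts[2], m$region_names)
    j <- match(parts[3], m$region_names)
    if (is.na(i) || is.na(j)) stop("unknown region in parameter ", k)
    if (parts[1] == "fwd") out$a_fwd[i, j] <- m$a_fwd[i, j] + theta[[k]]
    else out$a_bwd[i, j] <- m$a_bwd[i, j] + theta[[k]]
  }
  out
}

# Stack a cross-spectrum into a real data vector: Re of the upper triangle
# (incl. diagonal) then Im of the strict upper triangle, frequency-major.
csd_vectorise <- function(cs) {
  n <- dim(cs$csd)[1]
  nf <- dim(cs$csd)[3]
  iu <- which(upper.tri(matrix(0, n, n), diag = TRUE))
  is <- which(upper.tri(matrix(0, n, n)))
  out <- numeric(0)
  re <- vapply(seq_len(nf), function(k) Re(cs$csd[, , k])[iu],
               numeric(length(iu)))
  y <- as.numeric(re)
  if (length(is) > 0) {
    im <- vapply(seq_len(nf), function(k) Im(cs$csd[, , k])[is],
                 numeric(length(is)))
    y <- c(y, as.numeric(im))
  }
  y
}

#' Fit a network model to an observed cross-spectrum (variational Laplace)
#'
#' Gauss-Newton ascent on a free-energy objective with Gaussian priors and
#' posterior.  The observed CSD is first rescaled so its mean auto-spectral
#' power matches the prior-mean model prediction (the scale is returned;
#' a global scale carries no information about coupling).  Observation
#' noise has precision `exp(lambda) I` with `lambda` updated by Newton
#' steps inside the same ascent.  Steps that would decrease F are
#' Levenberg-damped and retried; accepted F values are therefore
#' non-decreasing.  Deterministic given inputs.
#'
#' @param m Baseline [network_model()] (architecture + operating point).
#' @param data A [cross_spectrum()] to fit.
#' @param prior A [prior_density()]; defaults to [network_priors()].
#' @param config Package configuration (`inversion$max_iter`,
#'   `inversion$tol_f` control convergence: ascent stops when the F change
#'   stays below `tol_f` for 2 consecutive iterations).
#' @param rescale_data Match data scale to the model before fitting
#'   (default TRUE; disable for self-inversion experiments in model units).
#' @param scale Explicit data scale overriding the automatic one; pass a
#'   common value across related datasets (segments, windows) so that
#'   between-dataset amplitude differences remain visible to the model
#'   rather than being normalised away.
#' @return Object of class `inversion_result`: posterior mean/covariance,
#'   `free_energy`, `predicted` spectrum, `variance_explained`,
#'   `iterations`, `converged`, `f_trace`, `data_scale`, `lambda`.
#' @export
invert <- function(m, data, prior = network_priors(m, config),
                   config = default_config(), rescale_data = TRUE,
                   scale = NULL) {
  stopifnot(inherits(data, "cross_spectrum"))
  grid <- data$grid
  theta0 <- prior$mean
  np <- length(theta0)
  free <- which(diag(prior$cov) > 1e-12)
  if (length(free) == 0) stop("invert: no free parameters")
  P0 <- solve(prior$cov[free, free, drop = FALSE])
  mu0 <- theta0[free]

  predict_csd <- function(theta) transfer_csd(apply_params(m, theta), grid,
                                              config = config)
  base_pred <- predict_csd(theta0)
  if (is.null(scale)) {
    scale <- 1
    if (rescale_data) {
      ds <- mean(auto_spectra(data))
      ms <- mean(auto_spectra(base_pred))
      if (ds <= 0) stop("invert: data has no power")
      scale <- ds / ms
    }
  }
  # fixed whitening weights: each frequency's entries are scaled by the
  # data's mean auto-power there, so the fit targets relative rather than
  # absolute spectral error (CSD estimator noise scales with power); the
  # single precision hyperparameter scales this whole diagonal
  nd <- dim(data$csd)[1]
  s_f <- apply(data$csd, 3, function(S) {
    S <- matrix(S, nd, nd); mean(Re(diag(S)))
  }) / scale
  s_f <- pmax(s_f, 1e-6 * max(s_f))
  n_re <- nd * (nd + 1) / 2
  n_im <- nd * (nd - 1) / 2
  wvec <- c(rep(s_f, each = n_re),
            if (n_im > 0) rep(s_f, each = n_im))
  y <- csd_vectorise(data) / scale / wvec
  ny <- length(y)
  gfun <- function(theta) {
    g <- tryCatch(csd_vectorise(predict_csd(theta)), error = function(e) NULL)
    if (is.null(g)) NULL else g / wvec
  }

  mu <- mu0
  full_theta <- function(muf) { th <- theta0; th[free] <- muf; th }
  g0 <- csd_vectorise(base_pred) / wvec
  e <- y - g0
  # effective-SSE floor caps the attainable noise precision (~80 dB SNR) so
  # noiseless self-inversion keeps the curvature matrix well conditioned
  sse_floor <- 1e-8 * max(sum(y^2), 1e-12)
  sse0 <- max(sum(e^2), sse_floor)
  lam0 <- log(ny / sse0)
  vlam <- config$inversion$lambda_prior_var
  lam <- lam0

  update_lambda <- function(sse, lam) {
    sse <- max(sse, sse_floor)
    for (it in 1:8) {
      gr <- -0.5 * exp(lam) * sse + ny / 2 - (lam - lam0) / vlam
      hs <- -0.5 * exp(lam) * sse - 1 / vlam
      lam <- lam - gr / hs
    }
    lam
  }
  free_energy <- function(e, muf, lam, Sq_logdet) {
    sse <- sum(e^2)
    d <- muf - mu0
    vpost <- 1 / (0.5 * exp(lam) * sse + 1 / vlam)
    -0.5 * exp(lam) * sse + 0.5 * ny * lam - 0.5 * ny * log(2 * pi) -
      0.5 * drop(t(d) %*% P0 %*% d) + 0.5 * logdet(P0) + 0.5 * Sq_logdet -
      0.5 * (lam - lam0)^2 / vlam + 0.5 * log(vpost / vlam)
  }
  jac <- function(muf, g_at) {
    h <- 1e-3
    J <- matrix(0, ny, length(free))
    for (q in seq_along(free)) {
      up <- muf; up[q] <- up[q] + h
      dn <- muf; dn[q] <- dn[q] - h
      gu <- gfun(full_theta(up))
      gd <- gfun(full_theta(dn))
      if (is.null(gu) && is.null(gd)) {
        J[, q] <- 0
      } else if (is.null(gu)) {
        J[, q] <- (g_at - gd) / h
      } else if (is.null(gd)) {
        J[, q] <- (gu - g_at) / h
      } else J[, q] <- (gu - gd) / (2 * h)
    }
    J
  }

  g_cur <- g0
  e <- y - g_cur
  lam <- update_lambda(sum(e^2), lam)
  J <- jac(mu, g_cur)
  Pq <- crossprod(J) * exp(lam) + P0
  Fc <- free_energy(e, mu, lam, -logdet(Pq))
  f_trace <- Fc
  nu <- 1e-6
  small_steps <- 0L
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(config$inversion$max_iter)) {
    iters <- it
    grad <- exp(lam) * crossprod(J, e) - P0 %*% (mu - mu0)
    accepted <- FALSE
    for (tries in 1:10) {
      step <- tryCatch(solve(Pq + nu * diag(diag(Pq)), grad),
                       error = function(e) NULL)
      if (!is.null(step)) {
        mu_new <- mu + drop(step)
        g_new <- gfun(full_theta(mu_new))
        if (!is.null(g_new)) {
          e_new <- y - g_new
          lam_new <- update_lambda(sum(e_new^2), lam)
          J_new <- jac(mu_new, g_new)
          Pq_new <- crossprod(J_new) * exp(lam_new) + P0
          F_new <- tryCatch(free_energy(e_new, mu_new, lam_new, -logdet(Pq_new)),
                            error = function(e) -Inf)
          if (is.finite(F_new) && F_new > Fc - 1e-8) {
            dF <- F_new - Fc
            mu <- mu_new; g_cur <- g_new; e <- e_new
            lam <- lam_new; J <- J_new; Pq <- Pq_new
            Fc <- F_new
            f_trace <- c(f_trace, Fc)
            nu <- max(nu / 3, 1e-8)
            accepted <- TRUE
            small_steps <- if (dF < config$inversion$tol_f)
              small_steps + 1L else 0L
            break
          }
        }
      }
      nu <- max(nu, 1e-6) * 10
    }
    if (!accepted) { converged <- small_steps >= 1L; break }
    if (small_steps >= 2L) { converged <- TRUE; break }
  }

  Sq <- robust_inv(Pq)
  post_mean <- full_theta(mu)
  post_cov <- matrix(0, np, np, dimnames = list(names(theta0), names(theta0)))
  post_cov[free, free] <- (Sq + t(Sq)) / 2
  predicted <- predict_csd(post_mean)
  res <- structure(list(
    posterior = list(mean = post_mean, cov = post_cov),
    free_energy = Fc, lambda = lam, f_trace = f_trace,
    predicted = predicted, data_scale = scale,
    iterations = iters, converged = converged,
    prior = prior, free = free, n_data = ny), class = "inversion_result")
  res$variance_explained <- variance_explained(res, data)
  res
}

#' Fraction of cross-spectral variance explained
#'
#' `R^2 = 1 - SS_res / SS_tot` over all real and imaginary CSD entries,
#' with the total sum of squares taken about the data mean.  Values below
#' zero (model worse than the mean) are clipped to 0 with a warning.
#'
#' @param result An [invert()] result.
#' @param data The fitted [cross_spectrum()].
#' @return Fraction in `[0, 1]`.
#' @export
variance_explained <- function(result, data) {
  y <- csd_vectorise(data) / result$data_scale
  if (sum(y^2) <= 0) stop("variance_explained: data has no power")
  p <- csd_vectorise(result$predicted)
  sst <- sum((y - mean(y))^2)
  ssr <- sum((y - p)^2)
  r2 <- 1 - ssr / sst
  if (r2 < 0) {
    warning("model underperforms the data mean; variance explained clipped to 0")
    r2 <- 0
  }
  min(r2, 1)
}

#' Common data scale for a set of related cross-spectra
#'
#' The ratio of the mean observed auto-power (pooled over all datasets) to
#' the prior-mean model's: sharing this scale across windows or segments
#' keeps their relative amplitudes -- which carry gain information -- in
#' the fitted features.
#'
#' @param m Baseline [network_model()].
#' @param csds List of [cross_spectrum()] objects.
#' @param config Package configuration.
#' @return Positive scalar.
#' @export
common_scale <- function(m, csds, config = default_config()) {
  ds <- mean(vapply(csds, function(cs) mean(auto_spectra(cs)), numeric(1)))
  ms <- mean(auto_spectra(transfer_csd(m, csds[[1]]$grid, config = config)))
  if (ds <= 0) stop("common_scale: data has no power")
  ds / ms
}

#' Invert a sequence of windowed cross-spectra
#'
#' First-level analysis: each window is fitted independently with the same
#' baseline model, prior, and a [common_scale()]; per-window failures are
#' caught, marked and skipped.  Results are ordered by window time.
#'
#' @param m Baseline [network_model()].
#' @param windows List of [cross_spectrum()] objects (optionally with a
#'   `window_times` attribute; otherwise windows are numbered).
#' @param prior A [prior_density()].
#' @param config Package configuration.
#' @return Object of class `window_inversions`: list of results, window
#'   times, aggregate variance explained.
#' @export
invert_windows <- function(m, windows, prior = network_priors(m, config),
                           config = default_config()) {
  if (length(windows) < 1) stop("invert_windows: need >= 1 window")
  times <- attr(windows, "window_times")
  if (is.null(times)) times <- seq_along(windows)
  ord <- order(times)
  results <- vector("list", length(windows))
  scale <- common_scale(m, windows, config)
  ssr <- sst <- 0
  for (k in ord) {
    results[[k]] <- tryCatch(
      invert(m, windows[[k]], prior, config = config, scale = scale),
      error = function(err) {
        warning("window ", k, " failed: ", conditionMessage(err))
        structure(list(failed = TRUE, message = conditionMessage(err),
                       converged = FALSE), class = "inversion_result")
      })
    r <- results[[k]]
    if (is.null(r$failed)) {
      y <- csd_vectorise(windows[[k]]) / r$data_scale
      sst <- sst + sum((y - mean(y))^2)
      ssr <- ssr + sum((y - csd_vectorise(r$predicted))^2)
    }
  }
  structure(list(results = results, window_times = times,
                 variance_explained = if (sst > 0) max(0, 1 - ssr / sst)
                 else NA_real_),
            class = "window_inversions")
}
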