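#' Ordered bilateral region set
#'
#' Regions are five bilateral pairs ordered rostro-caudally; each pair
#' contributes a left and right region named `<pair>_L` / `<pair>_R`.
#'
#' @param pairs Character vector of pair names in rostro-caudal order.
#' @return Object of class `region_set` with fields `pairs`, `names`
#'   (interleaved L/R), `pair_index`, `side`.
#' @export
region_set <- function(pairs = default_config()$experiment$region_pairs) {
  if (any(duplicated(pairs))) stop("duplicate region pair names")
  nms <- as.character(t(outer(pairs, c("L", "R"), paste, sep = "_")))
  structure(list(pairs = pairs, names = nms,
                 pair_index = rep(seq_along(pairs), each = 2),
                 side = rep(c("L", "R"), length(pairs))),
            class = "region_set")
}

#' Factorial model space of baseline architectures
#'
#' Enumerates the 6 x 2 x 2 = 24 combinations of: hub identity (none or
#' one of the five bilateral pairs; the hub pair connects reciprocally to
#' every other region), presence of neighbouring connections (reciprocal
#' links along the rostro-caudal chain on each side), and presence of
#' homotopic connections (reciprocal left-right links within each pair).
#' Connections toward the hub, and caudal-to-rostral chain links, populate
#' the forward mask; their reciprocals the backward mask.  Homotopic links
#' are entered symmetrically in the forward mask.  The all-off combination
#' is the null model with no extrinsic connectivity.
#'
#' @param regions A [region_set()] of 5 bilateral pairs.
#' @return List of 24 models, each with `id`, `hub`, `neighbouring`,
#'   `homotopic`, `mask_fwd`, `mask_bwd`.
#' @export
build_factorial_space <- function(regions = region_set()) {
  stopifnot(inherits(regions, "region_set"))
  if (length(regions$pairs) != 5)
    stop("the factorial space is defined over 5 bilateral pairs")
  models <- list()
  id <- 0L
  for (hub in c("none", regions$pairs)) {
    for (neigh in c(FALSE, TRUE)) {
      for (homo in c(FALSE, TRUE)) {
        id <- id + 1L
        models[[id]] <- c(list(id = id, hub = hub, neighbouring = neigh,
                               homotopic = homo),
                          arch_masks(regions, hub, neigh, homo))
      }
    }
  }
  models
}

#' Structural masks for one architecture hypothesis
#'
#' @param regions A [region_set()] (any number of pairs).
#' @param hub `"none"` or a pair name; the hub pair connects reciprocally
#'   to all other regions (into-hub links are forward).
#' @param neighbouring Reciprocal links along the rostro-caudal chain on
#'   each side (caudal-to-rostral is forward).
#' @param homotopic Reciprocal left-right links within each pair
#'   (entered symmetrically in the forward mask).
#' @return List with `mask_fwd`, `mask_bwd`.
#' @export
arch_masks <- function(regions, hub = "none", neighbouring = FALSE,
                       homotopic = FALSE) {
  n <- length(regions$names)
  mf <- matrix(0, n, n, dimnames = list(regions$names, regions$names))
  mb <- mf
  if (hub != "none") {
    hub_idx <- which(regions$pair_index == match(hub, regions$pairs))
    if (length(hub_idx) == 0) stop("unknown hub pair: ", hub)
    others <- setdiff(seq_len(n), hub_idx)
    for (h in hub_idx) for (o in others) {
      mf[h, o] <- 1   # forward: other region -> hub
      mb[o, h] <- 1   # backward: hub -> other region
    }
  }
  if (neighbouring) {
    for (p in seq_len(length(regions$pairs) - 1)) {
      for (s in c("L", "R")) {
        rostral <- which(regions$pair_index == p & regions$side == s)
        caudal <- which(regions$pair_index == p + 1 & regions$side == s)
        mf[rostral, caudal] <- 1  # forward: caudal -> rostral
        mb[caudal, rostral] <- 1
      }
    }
  }
  if (homotopic) {
    for (p in seq_along(regions$pairs)) {
      lr <- which(regions$pair_index == p)
      mf[lr[1], lr[2]] <- 1
      mf[lr[2], lr[1]] <- 1
    }
  }
  list(mask_fwd = mf, mask_bwd = mb)
}

#' Network model for an architecture hypothesis
#'
#' @param arch One element of [build_factorial_space()].
#' @param regions The matching [region_set()].
#' @param a_value Baseline coupling parameter placed on present connections.
#' @param sources Optional list of [source_params()] (default prior means).
#' @return A [network_model()].
#' @export
architecture_model <- function(arch, regions = region_set(), a_value = 0,
                               sources = NULL) {
  n <- length(regions$names)
  if (is.null(sources))
    sources <- replicate(n, source_params(), simplify = FALSE)
  network_model(sources,
                a_fwd = arch$mask_fwd * a_value,
                a_bwd = arch$mask_bwd * a_value,
                mask_fwd = arch$mask_fwd, mask_bwd = arch$mask_bwd,
                region_names = regions$names)
}

#' Bayesian model reduction
#'
#' Closed-form evidence and posterior for a model whose prior differs from
#' the inverted (full) model's prior only in means/covariances: with full
#' prior `N(m0, C0)`, full posterior `N(m, C)` and reduced prior
#' `N(mr, Cr)`, the reduced posterior is Gaussian with precision
#' `C^-1 + Cr^-1 - C0^-1`, and the log-evidence difference is the Gaussian
#' integral of the prior ratio under the posterior.  Parameters switched
#' off by a reduced model keep their dimension with mean 0 and variance
#' 1e-8 (pinned at "no effect"), keeping all reductions comparable.
#'
#' @param full An [invert()] result (or any list with
#'   `posterior$mean`/`posterior$cov` and matching `prior`).
#' @param full_prior The [prior_density()] used for the full inversion
#'   (defaults to `full$prior`).
#' @param reduced_prior A [prior_density()] of the same dimension.
#' @return List with `dF` (log-evidence difference reduced - full),
#'   `mean`, `cov` (reduced posterior).
#' @export
reduce_model <- function(full, full_prior = full$prior, reduced_prior) {
  if (length(reduced_prior$mean) != length(full_prior$mean))
    stop("reduced prior must have the same dimension as the full prior")
  bmr_gaussian(full$posterior$mean, full$posterior$cov,
               full_prior$mean, full_prior$cov,
               reduced_prior$mean, reduced_prior$cov)
}

# Gaussian Bayesian model reduction in moment form.  Variances below
# 1e-12 are floored to keep precisions finite.
bmr_gaussian <- function(m, C, m0, C0, mr, Cr) {
  floor_cov <- function(S) {
    d <- diag(S)
    if (any(d < 1e-12)) diag(S)[d < 1e-12] <- 1e-12
    S
  }
  C <- floor_cov(C); C0 <- floor_cov(C0); Cr <- floor_cov(Cr)
  iC <- robust_inv(C); iC0 <- robust_inv(C0); iCr <- robust_inv(Cr)
  iCp <- iC + iCr - iC0
  ev <- eigen((iCp + t(iCp)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("reduced posterior covariance not positive definite")
  Cp <- robust_inv(iCp)
  w <- iC %*% m + iCr %*% mr - iC0 %*% m0
  mp <- drop(Cp %*% w)
  quad <- drop(t(mp) %*% iCp %*% mp - t(m) %*% iC %*% m -
                 t(mr) %*% iCr %*% mr + t(m0) %*% iC0 %*% m0)
  dF <- 0.5 * (logdet(Cp) - logdet(C) + logdet(C0) - logdet(Cr)) + 0.5 * quad
  list(dF = dF, mean = stats::setNames(mp, names(m)), cov = Cp)
}

#' Reduced prior for an architecture hypothesis
#'
#' Starting from the full-model prior (all connections of the union mask
#' present), pins the extrinsic parameters of connections absent from
#' `arch` at mean 0 with variance 1e-8.
#'
#' @param full_prior [prior_density()] of the full model.
#' @param arch Architecture (element of [build_factorial_space()]).
#' @param regions The [region_set()].
#' @return A [prior_density()].
#' @export
architecture_prior <- function(full_prior, arch, regions = region_set()) {
  pr <- full_prior
  nms <- names(pr$mean)
  for (k in grep("^(fwd|bwd)\\.", nms)) {
    parts <- strsplit(nms[k], ".", fixed = TRUE)[[1]]
    i <- match(parts[2], regions$names)
    j <- match(parts[3], regions$names)
    present <- if (parts[1] == "fwd") arch$mask_fwd[i, j] else arch$mask_bwd[i, j]
    if (present == 0) {
      pr$mean[k] <- 0
      pr$cov[k, ] <- 0
      pr$cov[, k] <- 0
      pr$cov[k, k] <- 1e-8
    }
  }
  pr
}

#' Family-wise Bayesian model comparison
#'
#' Posterior family probabilities from per-model log evidences under a
#' flat prior over models: each model's posterior probability is the
#' softmax of its evidence, and a family's probability is the sum over its
#' members.
#'
#' @param F Numeric vector of log evidences (free energies), one per model.
#' @param partition Named list of index vectors: disjoint, exhaustive
#'   families.
#' @return Named numeric vector of family probabilities (sums to 1).
#' @export
compare_families <- function(F, partition) {
  if (!all(is.finite(F))) stop("non-finite model evidences")
  idx <- unlist(partition)
  if (any(lengths(partition) == 0)) stop("empty family")
  if (length(idx) != length(F) || !setequal(idx, seq_along(F)) ||
      any(duplicated(idx)))
    stop("partition must assign every model to exactly one family")
  lp <- F - log_sum_exp(F)
  vapply(partition, function(ii) exp(log_sum_exp(lp[ii])), numeric(1))
}

#' Standard family partitions of the factorial space
#'
#' @param models Output of [build_factorial_space()].
#' @return List with `hub` (6 families) and `short_range` (4 families:
#'   neighbouring x homotopic).
#' @export
factorial_families <- function(models) {
  hub <- split(seq_along(models), vapply(models, `[[`, character(1), "hub"))
  sr <- split(seq_along(models),
              vapply(models, function(m)
                paste0("neigh", as.integer(m$neighbouring),
                       ".homo", as.integer(m$homotopic)), character(1)))
  list(hub = hub, short_range = sr)
}

#' Score all architectures by Bayesian model reduction
#'
#' Inverts the full (union-mask) model once against `data`, then scores
#' each of the 24 architectures by BMR, returning evidences relative to
#' the full model.
#'
#' @param data A [cross_spectrum()] of the 10-region baseline recording.
#' @param regions A [region_set()].
#' @param config Package configuration.
#' @param a_value Baseline coupling for the full model.
#' @return List with `F` (length 24), `models`, `full` (inversion result),
#'   `families` (posterior probabilities per comparison).
#' @export
baseline_architecture <- function(data, regions = region_set(),
                                  config = default_config(), a_value = 0) {
  models <- build_factorial_space(regions)
  union_mask_f <- Reduce(`+`, lapply(models, `[[`, "mask_fwd")) > 0
  union_mask_b <- Reduce(`+`, lapply(models, `[[`, "mask_bwd")) > 0
  full_arch <- list(mask_fwd = union_mask_f * 1, mask_bwd = union_mask_b * 1)
  m_full <- architecture_model(full_arch, regions, a_value = a_value)
  prior <- network_priors(m_full, config)
  inv <- invert(m_full, data, prior, config = config)
  F <- vapply(models, function(arch) {
    rp <- architecture_prior(prior, arch, regions)
    reduce_model(inv, prior, rp)$dF
  }, numeric(1))
  fams <- factorial_families(models)
  list(F = F, models = models, full = inv,
       families = lapply(fams, function(p) compare_families(F, p)))
}
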