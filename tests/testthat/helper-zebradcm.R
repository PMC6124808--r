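# Shared fixtures: everything is generated in code at test time.

default_grid <- function() frequency_grid(0.25, 10, 0.25)

# Draw a random single-source model restricted to the quasi-linear regime
# where the linearised spectrum is the correct oracle: stability margin at
# most -10 /s and linear-predicted output sd at most 0.05 (both computed
# from linear theory, not from simulation).
random_stable_source <- function() {
  repeat {
    p <- source_params(h = stats::rnorm(5, 0, 0.4),
                       t_e = stats::rnorm(1, 0, 0.2),
                       t_i = stats::rnorm(1, 0, 0.2),
                       noise_amp = stats::rnorm(1, 0, 0.3))
    m <- single_source_model(p)
    eff <- zebradcm:::network_effective(m)
    ok <- tryCatch({
      x0 <- fixed_point(m)
      J <- zebradcm:::nm_jacobian(x0, eff)
      margin <- max(Re(eigen(J, only.values = TRUE)$values))
      if (margin > -10) FALSE
      else {
        g <- frequency_grid(frequencies = seq(0.25, 100, by = 0.25))
        pwr <- 2 * sum(auto_spectra(transfer_csd(m, g))[, 1]) * 0.25
        sqrt(pwr) <= 0.05
      }
    }, error = function(e) FALSE)
    if (ok) return(m)
  }
}

# Miniature seizure experiment for recovery tests: 1 fish, 1 bilateral
# pair, 30 min with onset at 10 min.  Effects sit on parameters whose
# spectral signatures survive the indicator kernel at 20 Hz (tonic gain
# increase via h1, monophasic excitatory-time-constant decrease): see the
# methods vignette on identifiability.
mini_true_beta <- function(regions) {
  pn <- regions$names
  B <- matrix(0, 2, 4,
              dimnames = list(c("tonic_step", "pk_monophasic"),
                              c(paste0(pn, ".h1"), paste0(pn, ".t_e"))))
  B["tonic_step", paste0(pn, ".h1")] <- 0.35
  B["pk_monophasic", paste0(pn, ".t_e")] <- -0.3
  B
}

mini_experiment <- function(seed, null_beta = FALSE) {
  regions <- region_set("Tect")
  B <- mini_true_beta(regions)
  if (null_beta) B[] <- 0
  experiment_design(n_fish = 1, duration_s = 1800, ptz_onset_s = 600,
                    region_pairs = "Tect", true_beta = B, seed = seed)
}

# windowed MAR cross-spectra of one recording
windowed_csds <- function(x, fs, w, grid, order = 8) {
  starts <- zebradcm:::window_starts(ncol(x), fs, w)
  len <- round(w$length_s * fs)
  csds <- lapply(starts, function(s)
    mar_csd(x[, s:(s + len - 1), drop = FALSE], fs, order, grid))
  attr(csds, "window_times") <- (starts - 1) / fs + w$length_s / 2
  csds
}

# summary-level stand-in for first-level inversion results (fast PEB tests)
fake_first_level <- function(mus, sd = 0.05) {
  lapply(mus, function(mu) {
    S <- diag(sd^2, length(mu))
    dimnames(S) <- list(names(mu), names(mu))
    structure(list(posterior = list(mean = mu, cov = S)),
              class = "inversion_result")
  })
}
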