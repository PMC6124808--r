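---
title: "Models and methods in zebradcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in zebradcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(zebradcm)
```

zebradcm infers slow changes in effective brain connectivity from regional
calcium-imaging time series recorded during acute, chemically induced
seizures.  The chain is: a biophysical forward model of each region's
oscillatory activity; an observation model for the calcium indicator; a
cross-spectral summary of the data; Bayesian inversion of the forward model
against those summaries; model comparison over network architectures; and a
hierarchical model of how the fitted parameters drift over the course of a
seizure.  This vignette records the models, the numerical choices, and the
limits of what a passing test establishes.

## The regional source model

Each region ("source") is a three-population neural mass: a pyramidal
projection population (P), excitatory interneurons (E) and inhibitory
interneurons (I).  Population p's membrane potential responds to presynaptic
firing through a second-order synaptic kernel,

$$\ddot v_p = \frac{u_p}{T_p^2} - \frac{2}{T_p}\dot v_p - \frac{v_p}{T_p^2},$$

where `u_p` collects gain-weighted presynaptic firing and `T_p` is the
population's time constant (excitatory populations use `T_E`, the inhibitory
population `T_I`).  The kernel is normalised so its steady-state gain equals
the connection gain, which keeps gains order-1 and dimensionless.  Firing is
a centred sigmoid of membrane potential with unit slope at the origin, so
the origin is always a fixed point and the linearisation there has unit
firing gain.

The five intrinsic connections follow the ordering of the standard LFP-type
source: H1 (E to P), H2 (P to E), H3 (P to I) excitatory; H4 (I to P), H5
(I to I) inhibitory.  Each source also has a steady-state noise input with
power spectrum $\mathrm{amp}^2 / f^{\mathrm{exp}}$ ("pink" at the prior
mean) entering the E population.  Between regions, forward connections
drive the target's E population and backward connections its P population,
with coupling strength `ext_scale * a` -- a linear effect-size
parameterisation in which `a = 0` means the connection is absent (this is
what lets Bayesian model reduction switch connections off by pinning `a` at
zero).

All inference operates on log-deviations from prior means (`gain =
prior_mean * exp(h)`), so the prior means only set the operating point.
The defaults are

| parameter | prior mean | role |
|---|---|---|
| H1..H5 | 0.8, 0.8, 1.0, 1.5, 0.6 | intrinsic gains (a.u.) |
| T_E, T_I | 4 ms, 16 ms | synaptic time constants |
| amp, exp | 0.01, 1 | input-noise amplitude and exponent |
| sigmoid slope | 4 | fixed, not a free parameter |
| ext_scale | 0.2 | a.u. per unit extrinsic parameter |

The operating point was chosen once, by requiring the phenomenology the
package must reproduce: linear stability over the whole plus/minus one
log-unit range of every intrinsic parameter, a spontaneous spectral peak
near 10 Hz, low-frequency power strictly increasing in H1, and rising
low-frequency power (toward instability) along the "seizure direction"
(faster excitation, slower and weaker inhibition).  The noise amplitude is
small enough that fluctuations stay in the sigmoid's quasi-linear range --
a requirement, because the spectral predictions are linearisations (next
section).

## Spectra: simulation and linear prediction

`simulate_lfp()` integrates the stochastic network with fixed-step RK4
(compiled code) under zero-order-hold pink-noise input synthesised in the
frequency domain, discards the first 10% as burn-in, and is bitwise
reproducible for a fixed seed.  `transfer_csd()` linearises the dynamics
about the fixed point and propagates the parameterised input spectra
through the transfer function, giving a Hermitian, positive semi-definite
cross-spectral density (CSD) on any frequency grid.  The two routes are
held together by an oracle-equivalence test: Welch spectra of 200-s
simulations match the linearised prediction with median relative error
below 20% over 1-10 Hz.

That test samples "random stable models" with two a-priori restrictions
computed from linear theory alone: a stability margin of at least 10 /s and
a linear-predicted output sd of at most 0.05.  Draws outside this regime --
nearly marginal resonances or saturating amplitudes -- are not in the
quasi-linear regime where a linearised spectrum is the right oracle, and
the package's own analyses never operate there (the synthetic generator
shrinks unstable excursions back toward baseline rather than simulate
them).

## Observation model

Fluorescence is LFP convolved with a composite indicator kernel: an
inverted-quadratic rise of 250 ms normalised to 1 at its end, then an
exponential decay with a 1000 ms time constant (GCaMP6F-like).  Kernel
times are in milliseconds throughout.  `apply_kernel()` convolves at the
input rate, low-passes at 0.9 of the output Nyquist (FFT brick-wall), and
decimates; it is linear and shift-covariant before decimation, and the
convolution is exact on an impulse when no decimation is requested.
Whether to convolve-then-decimate or the reverse was an open choice; we fix
convolve-then-decimate, which is the physically ordered sequence (the
indicator acts on the underlying signal, the camera samples the result).

## Data features

Sliding-window Fourier amplitude spectra (60 s windows, 10 s steps) feed
the k-by-k "delay-delay" matrix: per window, the vector of per-channel mean
0-10 Hz power, correlated across windows (Pearson).  Window amplitude is
the Fourier modulus; the windowed estimator is deliberately plain (one DFT
per window, no taper) since the matrix is a visualisation of slow state
changes, not an inferential quantity.  Windows with zero variance become
missing rows/columns rather than propagating NaN.

For model fitting, each 60-s window (50-s steps) is summarised by the CSD
of a least-squares vector autoregression (default order 8, after mean and
linear-trend removal), evaluated on 0.25-10 Hz at 0.25 Hz -- the measured
band at 20 Hz sampling.  The VAR order is a compromise: high enough to
resolve sub-2 Hz seizure peaks within a 60 s window, low enough to stay
well-conditioned on 1200 samples.  `eigenmode_summary()` provides the
leading spectral mode for display, with a deterministic sign convention
(largest-magnitude weight rotated positive).

## Variational inversion

`invert()` fits a network model to an observed CSD by variational Laplace:
a Gaussian posterior over the log-scaling parameters, a Gauss-Newton
ascent on the free energy with Levenberg damping and step rejection (so
accepted free energies are non-decreasing), finite-difference sensitivities
of the CSD prediction, and convergence when the free-energy change stays
below 0.01 nat twice in a row (at most 128 iterations).  Everything is
deterministic, so repeated inversions give bitwise-identical free energies.

Three data-feature choices matter and are worth stating plainly:

* **Vectorisation.**  The real parts of the upper-triangular CSD entries
  and the imaginary parts of the strictly upper entries are stacked across
  frequencies.
* **Whitening.**  Each frequency's entries are divided by the data's mean
  auto-power at that frequency.  Without this, the indicator kernel's
  roughly f^-2 tilt concentrates essentially all squared error in the
  lowest bin and the likelihood ignores the rest of the band.  The
  observation-noise precision remains a single log-hyperparameter scaling
  this fixed diagonal, updated by Newton steps inside the same ascent.
* **Common scale.**  A global scale carries no information about coupling,
  so data are rescaled to the model's units -- but windows or segments of
  one recording share a single common scale (`common_scale()`).  Their
  relative amplitudes are exactly the gain signature that a 20 Hz,
  kernel-filtered recording retains best; normalising each window
  separately destroys it (and, empirically, destroys the construct-validity
  recovery).

Noiseless self-inversion is protected by an effective-SSE floor
(about 80 dB SNR) so the curvature matrix stays well-conditioned.  Prior
variances are 1/16 on intrinsic gains and time constants and 1/8 on
extrinsic couplings.  The input-noise priors are the package's own choice:
1/16 on the amplitude (amplitude is informative once windows share a common
scale) but 1 on the spectral exponent, because fluorescence inverted
without kernel correction -- deliberately, as in the construct-validity
experiment -- needs the input exponent to absorb the kernel's roughly +2
contribution to the spectral slope.

`variance_explained()` is an R-squared over all real and imaginary CSD
entries (total sum of squares about the data mean), clipped below at zero
with a warning.

## Architectures and Bayesian model reduction

The baseline model space is factorial: hub identity (none or one of five
bilateral pairs; a hub pair connects reciprocally with every other region),
neighbouring connections (reciprocal rostro-caudal chain links per side),
and homotopic connections (reciprocal left-right links), giving 6 x 2 x 2 =
24 architectures, the all-off member being the null network.  Conventions
that were genuinely open, fixed here: the chain order is the
rostro-caudal region order; connections *toward* the hub and
caudal-to-rostral links are "forward"; homotopic links sit symmetrically in
the forward matrix; the hub's own left-right edge belongs to the homotopic
factor only.

`reduce_model()` scores any architecture from a single inversion of the
union ("full") model by Gaussian Bayesian model reduction: the log-evidence
difference is the closed-form Gaussian integral of the prior ratio under
the full posterior.  Absent connections keep their dimension with prior
mean 0 and variance 1e-8 -- genuinely off under the linear coupling
parameterisation.  The implementation is validated against analytic
evidence in conjugate linear-Gaussian models to 1e-6.  `compare_families()`
sums softmax model posteriors within disjoint families under a flat model
prior.

## The hierarchical (PEB) model

`peb_fit()` models window-to-window variation of first-level posterior
means as a linear mixture of temporal basis functions.  With windows w,
selected parameters mu_w and first-level posterior covariances S_w:

$$\mu_w = B^\top x_w + e_w,\qquad e_w \sim N(0,\; S_w + e^{-\gamma} I),$$

with a N(0, 1/16) prior on every effect in B and the between-window log
precision gamma optimised against the exact marginal likelihood (broad
Gaussian prior, deterministic 1-D search).  Because the marginal model is
linear-Gaussian, the group evidence is exact, reduction over effect subsets
(`peb_reduce()`) re-evaluates that evidence with pinned effects at the
full model's gamma, and the empirical-prior update of each window's
posterior is conjugate -- so shrinkage (trace of covariance never
increasing) holds by construction.  This is a summary-statistic empirical
Bayes: the first-level prior is not subtracted before the second level, a
simplification relative to the full nested scheme that matters only when
first-level priors dominate the posteriors; effect signs and model
comparisons, the quantities under test, are insensitive to it in all our
recovery experiments.

The temporal basis is: a tonic step at PTZ onset; a monophasic
pharmacokinetic effect, implemented as a double exponential
$(1-e^{-\tau/\tau_1})\,e^{-\tau/\tau_2}$ with tau1 = 480 s and tau2 =
20000 s so the analytic peak sits at onset + 1802 s (30 minutes, the
stated peak effect) and the effect stays above 0.5 at two hours; a linear
ramp from onset scaled to max 1; the three lowest non-constant DCT
components over the post-onset windows (three is a convention for "a few
slow oscillatory drifts"; more would start absorbing the seizure effects
themselves); and per-fish indicator columns treated as nuisance effects, which
double as intercepts.  Effect-set comparisons (forward / backward / both /
neither; per-region or all-region intrinsic) pin the seizure-effect rows of
excluded parameters while nuisance columns stay free.

For the construct-validity analysis (`construct_validity()`), the
between-segment design is an intercept plus a linear regressor -- linear
rather than categorical because the generative manipulation is a linear
ramp in one parameter.

## Synthetic data: the stated world

`generate_experiment()` emulates the target experiment: 3 fish, 10
regions (5 bilateral pairs: Tect, Crbl, RHbr, MHbr, CHbr_RSc), 150 min at
20 Hz with PTZ onset at 30 min.  Ground-truth parameter trajectories are
the temporal basis times a true effect matrix, plus per-fish random
intrinsic offsets (sd 0.05).  Parameters are frozen over 50-s segments
(the quasi-static assumption the windowed first level makes anyway) but the
dynamical state is carried continuously across segments, so there are no
splice artefacts to blend away.  Unstable excursions are shrunk
geometrically toward baseline until linearly stable, with a logged
warning.  Fluorescence is kernel-convolved, decimated, and given white
measurement noise at SNR 10 (the recordings' true SNR is unreported;
regional averages over thousands of pixels are high-SNR, and the value is
config-exposed).

The default effect directions mimic the reported findings: excitation/
inhibition balance tips toward excitation (the direct excitatory gain H1
rises while intrinsic inhibitory gains fall), excitatory time constants
fall and inhibitory ones rise, forward coupling into the tectal hub falls,
and DCT components on H1 create intermittent broadband bursts.  Effects
are 1.75x stronger in the tectum and rostral hindbrain than elsewhere
(0.75x) -- the regional heterogeneity the recordings show, and the reason
window-by-window channel-power patterns change between phases at all.
Two generator properties deserve emphasis:

* **Stable regional heterogeneity.**  Regions carry fixed input-amplitude
  offsets (a rostro-caudal gradient, caudal-most pair strongest).  Without
  it, all regions would be statistically identical at rest, the channel
  power-pattern vector would be pure estimation noise, and the delay-delay
  matrix could show no phase structure even in principle.
* **Near-critical seizure dynamics.**  At the default effect sizes most
  post-onset segments reach the linear-stability boundary and are
  geometrically shrunk back into the stable region (logged).  This is not
  an accident to be tuned away: large low-frequency seizure power in this
  model class *is* proximity to instability, and the clipping rule is what
  lets the generator state strong effects while every simulated segment
  remains integrable.

What the generator does **not** emulate: photon and motion noise,
indicator saturation and bleaching, spatial heterogeneity within regions,
and any seizure mechanism other than smooth parameter drift.  A green
end-to-end test therefore establishes that the pipeline recovers smooth
synaptic-parameter fluctuations expressed through this model class -- not
that real seizures are so generated.

## Identifiability at 20 Hz, and what recovery tests may demand

A 20 Hz, kernel-filtered recording retains two robust signatures:
overall gain (hence H1, the direct input-path gain, and with it the
excitation/inhibition balance) and the sub-10 Hz spectral envelope (hence
T_E, whose kernel shapes the band edge).  Parameters whose signatures live
near or above 10 Hz -- T_I's inhibitory resonance, and H4/H5's shaping of
it -- are largely invisible after the indicator kernel, and inversions
redistribute their effects onto neighbouring parameters (H3 and H4 are
exactly degenerate at the fixed point, entering only through their loop
product; priors break the tie symmetrically).  Recovery tests are therefore
stated over identifiable directions: the miniature recovery experiment puts
its ground-truth effects on H1 (tonic) and T_E (monophasic), and the
construct-validity experiment varies H1.  Demanding sign recovery of T_I or
H4 fluctuations from 20 Hz fluorescence would test the wrong thing -- the
data do not carry that information, which is also why value-level (rather
than trend-level) recovery is out of scope.

## Numerical choices and degenerate inputs

* Fixed points by damped Newton with the analytic Jacobian; the centred
  sigmoid makes the origin an exact root, but the solver still verifies the
  derivative norm (< 1e-8) and reports the worst source on failure.
* Linear instability of a proposed model is an explicit error, distinct
  from fixed-point non-convergence; during inversion such proposals are
  rejected by step-halving rather than surfacing to the user.
* Transfer functions use the Jacobian's eigendecomposition when its
  conditioning allows (kappa < 1e10), falling back to direct solves.
* Matrix inversions throughout use Cholesky with escalating jitter;
  zero prior variances mark fixed parameters and are floored at 1e-12 only
  inside Gaussian algebra.
* The integration step must satisfy dt <= T_E/4 (RK4 is comfortably
  accurate there for the sub-10 Hz band of interest).
* Ties in eigenvector signs are broken by rotating the largest-magnitude
  component positive, everywhere a decomposition is user-visible.

## Known limitations

* The inversion is a local MAP scheme; strongly non-Gaussian or multimodal
  posteriors (near instability, or with strong coupling degeneracies) are
  summarised by one mode.
* The second level is summary-statistic empirical Bayes (see above), not
  the fully nested hierarchical scheme.
* Extrinsic-coupling fluctuations are weakly identified from two-channel
  miniatures; their recovery needs the full 10-region design and more
  windows than the miniature budget provides.
* Band-power surfaces beyond 10 Hz are generative extrapolations of the
  fitted model, not measurements; they are exactly as trustworthy as the
  model class.
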