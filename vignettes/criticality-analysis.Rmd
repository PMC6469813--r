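---
title: "Critical oscillations on a disordered lattice: model and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical oscillations on a disordered lattice: model and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(croscillations)
```

## The model

`croscillations` simulates the CROS ("CRitical OScillations") model: an
`L x L` square lattice of stochastic spiking neurons, 75% excitatory and
25% inhibitory, with open boundaries. Each neuron connects only within the
`ell x ell` square centred on it (`ell = 7` by default, so an interior
neuron has at most 48 possible targets), with connection probability
decaying exponentially with Euclidean distance, `P(r) ~ exp(-r/a0)` with
`a0 = 1` lattice spacing. The two free parameters are the excitatory and
inhibitory connectivity fractions `r_E` and `r_I`: the fraction of its
local neighbourhood each neuron of that type innervates. Synaptic weights
depend only on the (pre, post) type pair: `W_EE = 0.02`, `W_EI = 0.011`,
`W_IE = W_II = -2`.

Each neuron `i` carries a synaptic current `I_i` and a spiking-rate
variable `R_Si`, both with exponential decay (`tau_I = 9` ms;
`tau_P = 9` ms excitatory, 12 ms inhibitory; `dt = 1` ms):

* `I_i(t+dt) = (I_i(t) + sum_j W_ji S_j(t)) (1 - dt/tau_I)`
* `R_Si(t+dt) = (R_Si(t) + I_i(t)) (1 - dt/tau_P) + P0 dt/tau_P`
* spike with probability `clamp(R_Si, 0, 1)`; after a spike `R_S` is reset
  to -2 (excitatory) or -20 (inhibitory).

`P0 = 1e-6` for excitatory neurons (a constant Poisson-like drive, so the
model has no absorbing state) and 0 for inhibitory ones. The population
activity `A(t) = sum_i S_i(t)` is the model's output signal. As `r_E`
grows at fixed `r_I`, the network passes from near-silence through an
oscillation onset (a spectral peak near the alpha band emerges) into a
strongly active oscillatory regime. All analyses in the package live on
this one-dimensional signal.

## Design choices in the model construction

Two constructions of the disordered connectivity are implemented, because
the verbal description ("each neuron connects to a random fraction of its
neighbours, with exponentially distance-decaying probability") admits
both:

* **`degree = "exact"` (default).** Each neuron connects to exactly
  `round(r * N_local)` targets, sampled without replacement with weights
  `exp(-r)`. The realized connectivity fraction is then exact per neuron.
* **`degree = "bernoulli"`.** Every in-range target is connected
  independently with probability `p(r) = min(1, C exp(-r))`, with `C`
  normalizing the expected out-degree to the stated fraction (capped
  probabilities are iteratively renormalised over the uncapped targets).

The two differ in the amount of out-degree disorder. In our `L = 50`
simulations the Bernoulli variant places the oscillation onset near
`r_E ~ 0.14`, while the exact variant places it near `r_E ~ 0.12` — the
location at which the reference description of this model reports the
`L = 50` transition — and produces slightly stronger long-range temporal
correlations at onset. We therefore ship `"exact"` as the default and keep
`"bernoulli"` switchable; all invariant tests (distance decay, sign
structure, reproducibility, expected fractions) cover both.

A second deliberately exposed ambiguity is `cros_params(current_timing)`:
whether the rate-variable update reads the previous step's published
current (default, the literal simultaneous-update reading) or the current
already updated with this step's synaptic input. The alternative weakens
the measured temporal correlations at onset in our runs; it exists for
sensitivity analysis only.

The compiled core draws one uniform per neuron per step in fixed neuron
order from an internal xoshiro256+ stream seeded jointly by the dynamics
and disorder seeds, so a trace is a bit-reproducible pure function of
`(topology, n_steps, seed)`. The R-level reference stepper `cros_step()`
implements the identical recurrences on an explicit state and accepts the
uniforms as an argument; the test suite verifies the two trajectories
coincide on deterministic cascades and that the analytic fixed points
(`R_S* = P0`; current decay factor exactly `8/9` per step) hold to
floating precision.

## Avalanches and the kappa index

Because the model is never silent, avalanches are defined against a
threshold `theta = Gamma * median(A)` (`Gamma = 0.5` by convention;
median over the full trace, zeros included, per realization). An
avalanche is a maximal run of steps with `A(t) > theta` (strict
inequality fixes ties when `Gamma * median` is an integer); its duration
is the run length `T` in ms, and its size is either the total spike count
`s_g` or the supra-threshold area `s_theta = s_g - T * theta`. We use
`s_theta` throughout (switchable), as it is the more robust definition.
Events cut off by either end of the trace are censored and counted, not
truncated.

The `kappa_index()` compares the empirical CDF of sizes or durations with
a reference bounded power law `x^-mu` on `[x_min, x_max]` at `b = 10`
log-spaced points: values near 1 indicate scale invariance, below 1 a
subcritical (exponential-like) distribution, above 1 a supercritical
bump. Reference exponents of interest are the directed-percolation
values: mean-field `tau = 3/2`, `tau_t = 2`; two-dimensional
`tau = 1.268`, `tau_t = 1.450`. Since heat maps of kappa require choosing
`x_min`/`x_max`, the analysis battery uses the maximum-likelihood minima
(10 for sizes, 4 for durations) and the pooled 99th percentile by
default; both are configurable.

## Maximum-likelihood fits and model comparison

`fit_truncated_powerlaw()` fits `P(x) ~ x^-mu exp(-x/x0)` for `x >= x_min`
by continuous maximum likelihood, with the normalizing integral (an upper
incomplete gamma function) evaluated by adaptive quadrature stabilized in
log space. The lower bounds are fixed — `s_min = 10` for sizes,
`T_min = 4` for durations — never scanned. Durations are integers but the
continuous likelihood is used for comparability across size definitions
(a deliberate convention; the discrete variant would change exponents by
less than the realization spread at our sample sizes). When the fitted
cutoff lands far beyond the bulk of the data (beyond 10 times the 99th
percentile) the fit is flagged as effectively a pure power law.

Goodness relative to pure power-law, lognormal and exponential
alternatives (each fitted to the same tail) is assessed with the
normalized loglikelihood-ratio statistic: `R > 0` favours the truncated
power law, with a two-sided normal `p` from the variance of the
per-observation loglikelihood differences. The transition region of the
model is operationally the set of parameter cells where the truncated
power law wins all three comparisons. Note one structural caveat the
tests encode: the truncated family nearly nests the exponential
(`mu -> 0`), so against exponential data the ratio is negative but rarely
large.

## Spectral order parameter

The spectrum of `A(t)` is the FFT periodogram normalized by `L^2` and
total time, smoothed by averaging non-overlapping blocks of 500 raw
frequency bins (~0.45 Hz per smoothed point for a `2^20` ms trace). The
order parameter `phi` is the fraction of spectral area in the oscillation
peak: with `f_peak` the argmax in a 4–45 Hz search band, `f_minus` the
nearest local minimum below it within 4–18 Hz and `f_plus` its symmetric
reflection, a chord is drawn between the spectrum values at `f_minus` and
`f_plus`; `phi = phi_p / (phi_p + phi_u)` where `phi_p` is the area above
the chord and `phi_u` the area under it (trapezoidal quadrature). `phi`
is zero when no peak qualifies. The qualification rule — the peak must
exceed the chord by at least twice the median within-block standard error
across the band — is our operational reading of "only nonzero when a peak
is detectable"; the median (not the peak block's own) standard error is
used because a narrow line inflates its own block variance. Both the
search band and the significance factor are arguments.

## DFA

`dfa()` implements standard detrended fluctuation analysis: integrate the
mean-subtracted series, split into non-overlapping windows (trailing
partial window dropped), remove a linear trend per window (order
configurable), pool residual RMS into `F(n)`, and fit
`log10 F ~ log10 n` over a fixed 4–14 s range. Window sizes default to 20
per decade from 100 ms to 20 s. The calibration `v = 2 alpha - 1` against
spectrally synthesized `1/f^v` noise (`colored_noise()`) is part of the
test suite: white noise gives `alpha ~ 0.5`, `1/f` noise `alpha ~ 1`, a
random walk `alpha ~ 1.5`.

The band-filtered variant (`dfa_band()`) first extracts the alpha-band
amplitude envelope: zero-phase band-pass with the squared magnitude
response of a 5th-order Butterworth design over 8–16 Hz, then the modulus
of the analytic signal (frequency-domain Hilbert construction). The
band-pass is applied spectrally — multiplying the spectrum by `|H(f)|^2`
with zero phase, the exact equivalent of forward–backward recursive
filtering — because high-order narrow-band recursions in
transfer-function form carry percent-level passband gain errors. The
first and last second of the envelope are trimmed before DFA.

## Scaling relations

Three independent probes of criticality are implemented on an avalanche
catalog, all restricted to durations strictly longer than 10 ms with at
least 10 events:

1. `mean_size_vs_duration()`: the slope of `log <s>` vs `log T`, the
   `1/(sigma nu z)` exponent.
2. `shape_collapse()`: mean temporal profiles per duration are
   interpolated onto a common 100-point `t/T` grid and rescaled by
   `T^(gamma-1)`; `gamma` is scanned over [1, 3] in steps of 0.01 and the
   collapse error is the across-duration variance averaged over the grid,
   normalized by the squared span of the grand-mean profile. The argmin
   is a second, independent `1/(sigma nu z)` estimate. The normalization
   makes the error a dimensionless shape mismatch, so the curve is
   unimodal for well-formed families; the grid step bounds the resolution
   at 0.01.
3. `crackling_check()`: the consistency condition
   `1/(sigma nu z) = (tau_t - 1)/(tau - 1)` with the MLE exponents on the
   right. No verdict is returned — in this model the left side sits
   systematically below the right side across the transition region, and
   that gap is a finding, not a failure of the code.

## Synthetic generators as ground truth

Every analysis stage has a seeded generator whose parameter it must
recover, and these recovery loops are the core of the test suite:
`sample_bounded_powerlaw()` (inverse-CDF, with a deterministic
plotting-position mode for exact kappa identities),
`sample_truncated_powerlaw()` (rejection sampling from a pure power-law
proposal, acceptance rate tracked), `colored_noise()` (spectral synthesis
with `f^(-v/2)` amplitudes and random phases), `oscillatory_signal()`
(sinusoid plus white noise) and `profile_family()` (avalanche profiles
built exactly on the collapse scaling form with a parabolic scaling
function, optionally with multiplicative lognormal noise). What these
fixtures deliberately do not emulate: correlations between successive
avalanches, non-parabolic profile shapes, and the activity-dependent
threshold coupling of real catalogs — so passing recovery tests validates
the estimators, not the model.

## Orchestration and problem sizes

`analyze_trace()` runs the full battery on one trace; `run_sweep()`
builds, simulates and analyses a grid of `(r_E, r_I)` cells with seeds
derived deterministically from one base seed, so any sweep is exactly
reproducible from its configuration row; `transition_scan()` aggregates
the continuously varying exponents along `r_E`, flags transition cells by
the loglikelihood triple-win rule (majority across realizations), and
reports the `(tau, tau_t)` spread and the Pearson correlation between
single-run band-filtered DFA exponents and `tau`.

The package's reference protocol is `L = 50`, `2^20` steps of 1 ms, five
disorder realizations per parameter point — a desk-scale profile where
one simulation takes tens of seconds. `L = 300` (the scale at which the
sharpest published exponent values were obtained) is fully supported by
the same functions but is a cluster-scale computation: a single `2^20`
step run at `L = 300` processes 36 times more neurons per step. The test
suite and the acceptance script use the `L = 50` profile; the vignette's
statements about model behaviour at `L = 300` are not re-verified here.

## Known limitations

* At `L = 50` the raw-activity DFA exponent at the oscillation onset
  averages ~0.9 over five realizations in our runs, below the ~1.09
  reported for the original implementation at the same nominal point;
  off-transition values match. The fluctuation function holds its
  steepest slopes up to ~3–5 s and flattens within the 4–14 s fit range,
  indicating our networks decorrelate somewhat faster at onset. Both
  update-timing readings and both connectivity constructions were
  measured; the shipped defaults are the closest pair. The residue most
  likely reflects an unpublished convention of the original code.
* The avalanche definition is the global-threshold one; the per-site
  binarization plus time-binning pipeline used on experimental M/EEG data
  is out of scope.
* Continuous likelihoods are used for integer durations (see above).
* The shape-collapse objective fixes one specific normalization of the
  collapse error; other published objectives differ by monotone
  transformations and can shift `gamma` by about the grid step on noisy
  catalogs.
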