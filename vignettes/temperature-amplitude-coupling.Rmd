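---
title: "Temperature-amplitude coupling in circadian clock models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-amplitude coupling in circadian clock models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempamp)
```

## The scientific question

Most biochemical reaction rates rise two- to three-fold per 10 °C, yet the
circadian period barely moves (temperature compensation, conventionally
0.85 < Q10 < 1.15, with the reciprocal-frequency convention for periods).
`tempamp` implements one candidate explanation, *temperature–amplitude
coupling*: if the reactions whose speed-up would lengthen the period are
also the reactions that inflate the oscillation's amplitude, a stronger
temperature sensitivity of those reactions can cancel the generic
period-shortening of uniformly faster kinetics. The package provides the
models, the temperature machinery, the random-parameterization screen that
quantifies the coupling, the bifurcation and fast–slow analyses that
explain it, and estimators that recover rhythm parameters from sampled
expression data.

## Models

Two ODE models are built in (see `clock_model()`):

* **Goodwin oscillator** (`"goodwin"`): mRNA *M*, cytosolic protein *R*,
  nuclear repressor *P*; Hill repression of transcription with
  cooperativity *n*, Michaelis–Menten degradation of *M* and *R*, linear
  production/removal of *P*. The rate constants `vs, vm, ks, vd, k1, k2`
  are treated as temperature-sensitive; the Michaelis constants
  `KI, KM, KD` and `n` are structural. The repression term is written
  `vs*KI^n/(KI^n + P^n)` so that `vs` is the term's only
  temperature-sensitive factor. The wiring diagram admits a few algebraic
  variants; this one is the standard variant uniquely consistent with that
  parameter list, and it sustains a limit cycle at the packaged standard
  set (period 23.6 time units) — the validation required of the choice.
  With the reversible-nuclear-transport variant the standard set also
  oscillates (period 25.3), so the adopted form is a documented modeling
  decision, not a fact forced by the printed numbers.
* **Two-variable reduction** (`"twovar"`): fast mRNA *X* with
  self-activation (Hill coefficient `gamma`) and repression by slow
  inhibitor protein *Y*; `eps` (default 0.02) sets the time-scale
  separation. Rates `k, v, a, s, d` are temperature-sensitive; `h, Kv,
  Ks, alpha, gamma, eps` structural. Two printed parameterizations ship
  as `twovar_params("low")` (298 K) and `twovar_params("high")` (308 K).

An exact law anchors much of the test suite: multiplying every rate of
either model by a constant c rescales time by 1/c, so the period becomes
period/c while the orbit — hence every amplitude — is unchanged. The suite
exploits the matching discretization (step dt/c over horizon t/c) so the
law can be verified to near machine precision independently of integrator
error.

## Numerics

Integration is classical fixed-step fourth-order Runge–Kutta with
dt = 0.01 by default; the two built-in models run through compiled
kernels, and other models defined with `define_clock_model()` integrate
via `deSolve::rk4()`. Halving dt moves measured periods by well under
0.5 % for both printed parameter sets (a test asserts this). Trajectories
dipping below −1e−6 or leaving the finite range raise integration-failure
errors rather than being clamped.

Sustained oscillation (`detect_sustained_oscillation()`) is judged on the
reference variable (the first state) after discarding the first half of
the run: at least 5 interior maxima, peak-height and inter-peak-interval
coefficients of variation ≤ 0.05, and a peak-to-trough excursion of at
least 1e−3 of the temporal mean. All four knobs are arguments. Period is
the mean spacing of the last 5 quadratic-interpolated peaks; amplitude is
max − min per variable over that window (a half-range option exists for
comparison with sinusoid-fit amplitudes, which report half peak-to-trough).
An independent zero-crossing period estimator in the test suite agrees
with the peak-based one within 1 %.

## Temperature

Rates follow the Arrhenius law `k_i(T) = A_i exp(-E_i/(R T))`, anchored so
that `k_i(T_ref)` reproduces the reference rates exactly. Only the ratio
`E_i/R` is identifiable from rate pairs, so the gas-constant-like scale
`R` is an explicit field of `arrhenius_model()`. For the two-variable
model the five printed (298 K, 308 K) rate pairs and activation energies
(335, 1057, 893, 480, 322 for `k, v, a, s, d`) pin the scale by a
one-parameter least-squares fit (`fit_arrhenius_scale()`); the fit,
performed at call time in `twovar_arrhenius()`, gives R ≈ 0.0821 and maps
the 298 K set onto the printed 308 K set within 2 % per rate. Period Q10
uses the reciprocal (frequency) convention, the only convention under
which a longer period at higher temperature reads as Q10 < 1
("overcompensation"). For inhibition sweeps, "transcription" means
`{k, v}` and "translation" `{s}` in the two-variable model — both
configurable.

## The screen

`run_screen()` reproduces the random-parameterization protocol: basal sets
drawn per-rate uniformly in [0.5, 2] × the standard rates, then per-rate
speed-up factors drawn uniformly in [1.5, 2.5] (each rate independently,
so mRNA and protein degradation can speed up unequally; the grand mean
increase is ~2-fold). For each basal/scaled pair that both oscillate, the
record carries the relative period (scaled/basal) and per-variable
relative amplitudes with their geometric mean (`gma`). "Nearly unchanged
period" is operationalized as relative period ≥ 0.95 (configurable); the
headline statistic is the fraction of such records with `gma` > 1.

Horizons are chosen adaptively: basal runs last 40 expected cycles of the
slowest basal set, scaled runs 40 cycles of their own basal period, so
slow oscillators are never truncated. The default test scale is 100 basal
× 20 speed-up sets; all draws are pure functions of the protocol seed
(basal draws use `seed`, speed-up draws `seed + 1`).

Two findings from running this protocol deserve explicit statement.
First, the coupling property itself is robust here: relative amplitude
rises strongly with relative period (record-level correlation ≈ 0.67),
the best-period-maintaining decile of records has mean `gma` > 1, and no
record with relative period ≥ 0.95 has `gma` ≤ 1. Second, the *oscillating
fraction* of scaled sets is about 92 % under this package's detector —
the scaled runs split cleanly into machine-precision limit cycles and
fixed points, so the fraction is insensitive to every detector knob. A
reference full-scale screen of this protocol reports 41.4 % sustained;
that fraction evidently depends on a convergence test whose calculation
time and tolerance are not stated and could not be reconstructed (several
model-variant and criterion reinterpretations were tried; none moved the
fraction below ~62 %). The package reports its own honestly measured
census rather than tuning the detector toward an external count.

## Bifurcation and fast–slow analysis

`find_fixed_point()` reduces the two-variable steady state to a scalar
equation by substituting the inhibitor nullcline, brackets the first sign
change on a fine grid, polishes with `uniroot`, and classifies stability
from the analytic Jacobian (validated against central finite differences).
`find_hopf()` bisects on the maximum eigenvalue real part; with the 308 K
set it locates the supercritical Hopf point of the positive-feedback rate
at v ≈ 0.866 (bracket 1e−4). Near the Hopf point the model shows the
canard behavior typical of fast–slow systems: amplitude grows like
√(v − v_c) only for v − v_c ≲ 0.002 and then explodes to relaxation size
within a few thousandths — tests that probe "amplitude → 0" therefore
sample inside that window.

`fastslow_period()` computes the relaxation-oscillation period in the
singular limit eps → 0: the fast variable sits on a stable (decreasing)
branch of its nullcline Y(X), the slow variable drifts by dY/dt = G, and
the period is the sum over the two branch segments of dY/G between the
fold values of Y (quadrature over X with the analytic nullcline slope;
folds located by slope sign changes plus root polishing). The singular
term is independent of eps and scales exactly as 1/c under common rate
scaling. Because the singular limit alone is ~5 % off at eps = 0.001, the
default adds the standard O(eps^{2/3}) fold-delay correction
(3 z0 / 2^{2/3}) · (eps² / (|F_XX| |F_Y G|))^{1/3} per fold, where z0 ≈
2.3381 is the first Airy-function zero and the derivatives are evaluated
at the fold. The 3/2 factor over the naive Airy blow-up time was fixed
against the classical van der Pol expansion T = T0 + 3 z0 eps^{2/3} and
verified on van der Pol numerically (0.03 % at eps = 1e−4) — an oracle
independent of this model. With the correction, the approximation agrees
with full simulation within 2 % at eps = 0.001; without it, the error
shrinks monotonically over eps ∈ {0.02, 0.01, 0.005, 0.001}, as a
singular limit should.

## Rhythm estimation

`fit_harmonic()` is a grid-scan cosinor: for each candidate period
(default 20–28 h, step 0.1 h) it solves the linear least-squares problem
in {1, cos, sin} and keeps the period with minimal residual. It stands in
for AR-spectral rhythm software on the reasoning that the acceptance
standard here is parameter recovery on synthetic data, not
output-matching of a specific tool. Amplitude is the sinusoid amplitude
(half peak-to-trough; multiply by 2 when comparing with the trajectory
pipeline's max − min convention). `fit_damped_sine()` fits
y = y0 + A e^{−x/t0} sin[π(x − xc)/w] by Levenberg–Marquardt
(`minpack.lm::nls.lm`), reporting the period as 2w; the initial guess
derives from a cosinor fit, and a `detrend` option removes a
least-squares line first, as is customary for drifting luminescence
baselines. `q10_report()` combines replicate fits into a group Q10
(frequency convention for periods, plain ratio convention for amplitudes
— the latter makes amplitude Q10 invariant to the half- vs full-range
choice) and a two-sided Student's t-test (equal variances by default,
Welch optional).

## Synthetic data

`generate_expression_dataset()` emulates the study design the estimators
assume: sampling every 4 h from 32 to 96 h post-stimulation (17 points),
three independent replicates, two temperatures (35/38 °C), cosine
waveforms with per-gene, per-temperature period/amplitude/acrophase/mesor,
additive Gaussian noise proportional to amplitude, and optional
normalization to the first sampled time (×100). The cosine waveform is
the fitter's own model class — by design, so recovery tests measure the
estimation machinery, not waveform mismatch; subsampled ODE trajectories
provide non-sinusoidal shapes where that matters (one test checks the
cosinor period against the trajectory metric this way). What passing these
tests does *not* show: robustness to non-Gaussian qPCR noise,
non-stationary waveforms, or amplitude drift within the window.
Normalization to the first time point preserves fitted periods always,
but preserves amplitude *ratios* exactly only when the anchor value is
amplitude-independent (e.g., sampling starts at a zero crossing of the
cosine); otherwise each condition is rescaled by its own anchor. The
designed-in coupling default follows the strongest experimentally observed
coupling: an amplitude ratio of 2.03 per 3 °C, i.e. an amplitude Q10 of
2.03^{10/3} ≈ 10.6.

## Problem sizes and reproducibility

Default problem sizes (the package's own choices, stated here so results
are interpretable): screens run 100 × 20 parameter sets; sweeps and
bifurcation scans use single runs of 40 cycles at dt = 0.01; fast–slow
validation integrates down to eps = 0.001 at dt = 2e−4; noisy-recovery
experiments use 11–200 seeded repetitions. Every stochastic entry point
takes an explicit integer seed and is a pure function of it;
`run_workflow()` echoes its config and seed beside every output.

## Known limitations

* The Goodwin equations are a reconstruction from a wiring diagram plus a
  parameter list; the reversible-transport variant remains plausible.
* The sustained-oscillation fraction of the screen is criterion-dependent
  in principle (though not in practice here, where outcomes are bimodal).
* The fold-delay correction is leading-order; at eps = 0.02 it
  overshoots by ~1 %, and higher-order (eps ln eps) terms are ignored.
* `find_fixed_point()` returns the first root in the bracket; systems
  with multiple coexisting steady states need a caller-supplied bracket.
* The cosinor scan step bounds period resolution (0.1 h by default), and
  no multiple-testing correction is applied across genes.
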