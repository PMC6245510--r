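---
title: "Two-pathway LNK models of retinal contrast adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-pathway LNK models of retinal contrast adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnkadapt)
```

## The model

Retinal ganglion and amacrine cells adapt to temporal contrast: when the
standard deviation of a flickering stimulus increases, their gain drops,
their responses speed up, their baseline potential sags, and — most
distinctively — their temporal filtering shifts from integrating
(monophasic) to differentiating (biphasic), raising the median temporal
frequency of the response. This package implements the modelling framework
used to study where these adaptive properties come from when signals travel
through two parallel pathways (On and Off) that sum at the recorded cell.

Each pathway is a linear–nonlinear–kinetic (LNK) cascade:

1. **Linear filter** `F(t)`, with taps in 1/s so that the convolution
   `g(t) = ∫ F(τ) s(t−τ) dτ` of the dimensionless stimulus is
   dimensionless. The stimulus `s(t)` is normalized luminance,
   `(I − M)/M`, whose standard deviation is the contrast.
2. **Static sigmoid nonlinearity**
   `u(x) = clamp(((erf(κx + b1) + 1)/2)^a + b2, 0, 1)`.
   `κ` is a fixed standardizer (the reciprocal SD of `g` over the fitted
   record, not a free parameter), `b1` sets the threshold, the exponent
   `a ∈ [0, 20]` sharpens rectification, and `b2` is a small vertical
   offset. The output `u(t)` is clamped to `[0, 1]` so it can scale
   kinetic rates. We normalize the pre-offset maximum to exactly 1 by the
   `2^a` denominator; a literal variant in which the activation rate
   constant appears in the denominator is available as a dialect in
   `eval_nonlinearity()` for comparison with other parameter conventions.
3. **Four-state kinetics block** modelling synaptic vesicle release:
   Resting → Active (rate `u(t)·k_a`), Active → Inactivated1 (`k_fi`),
   Inactivated1 → Resting (`k_fr`) or → Inactivated2 (`k_si`), and
   Inactivated2 → Resting (`u(t)·k_sr` by default). The occupancy row
   vector `P(t)` obeys `dP/dt = P·Q(u)`, and the pathway output is the
   active-state occupancy `A(t) = P_2(t)`.

The cell output is `r(t) = c · Σ_p w_p A_p(t) + d` in millivolts. Pathway
outputs sum; all nonlinear interaction between pathways is absent by
construction, which is what makes in-silico pathway blocking (zeroing a
weight) interpretable.

## Numerical core

`u(t)` is piecewise constant over each sample, so each integration step is
propagated *exactly* with the matrix exponential `exp(Q(u_t)·dt)`.
Exponentials are cached per distinct value of `u`; frame-held stimuli
(intensity redrawn every 30 ms) produce one `u` value per frame, so the
cache stays small and the trajectory agrees with a per-interval
matrix-exponential oracle to machine precision. Occupancies are
renormalized each step to hold `ΣP = 1` against floating-point drift;
conservation holds to better than 1e−9 over hundreds of seconds.

Inside the fitting objective `u` varies every sample (the fitted filter is
not frame-aligned), so exact caching would degenerate; there the propagator
quantizes `u` to 4096 levels with a direct-indexed cache. The quantization
error on `A(t)` is below 3e−4, two orders of magnitude under the noise
level of any fitted recording, and the final reported model is always
re-simulated with the exact propagator.

Kinetics start from the steady state implied by the mean drive over the
first 2 s; the same 2 s are flagged burn-in and excluded from every
downstream statistic. For `u = 0` the chain has two absorbing sets, so
`steady_state_occupancy()` refuses `u = 0` rather than return an arbitrary
vector; callers use a floor of 1e−6.

## Stimuli

`make_contrast_schedule()` and `generate_flicker()` reproduce the standard
protocol: spatially uniform Gaussian flicker, intensity redrawn every 30 ms
and held within the frame, contrast redrawn every 20 s uniformly from
0.05–0.35, 300 s per record. Contrast-segment boundaries snap to the
nearest frame boundary (20 s is not an integer multiple of 30 ms), which
preserves the frame-hold invariant at a worst-case boundary error of half a
frame. Gaussian draws are not truncated at zero luminance: the models
consume the normalized stimulus, so physical clipping is irrelevant here.
`generate_bar_flicker()` provides the one-dimensional spatial variant with
35%/5% contrast alternation (4 s/16 s), and `generate_flash()` the
uniform-field flash used for On/Off classification.

## Descriptive LN models and adaptation metrics

`estimate_filter()` computes the reverse-correlation filter as the ratio of
the averaged cross-spectrum to the averaged stimulus auto-spectrum over
1 s segments stepped every 0.1 s. Two engineering choices matter:
segments are Hann-tapered (the source protocol does not state a taper; an
untapered variant differs negligibly on these stimuli but leaks more at
segment edges), and the denominator carries a ridge of 1% of its mean power
— the division corrects the mild coloring introduced by the frame hold, not
a deconvolution at empty bands, and the ridge keeps the highest frequencies
from amplifying noise. The filter is truncated to a 0.6 s window and scaled
so the variance of the linear prediction equals the stimulus variance,
which fixes the units of the binned nonlinearity
(`estimate_nonlinearity()`, 40 equal-population bins by default; equal
population keeps the sparsely sampled tails stable).

The four adaptation metrics quantify how the fitted LN model changes with
contrast:

* **gain** — occupancy-weighted average slope of the binned nonlinearity;
* **delay** — time of the filter's first negative trough, refined by
  three-point parabolic interpolation;
* **median frequency** — the first crossing of one half by the cumulative
  normalized filter power spectrum (zero-padded to 4096 points so the
  frequency grid does not depend on filter length), linearly interpolated
  within the crossing bin; for a pure point mass this convention lands
  within one grid step of the mass;
* **offset** — 4 s segment means of the trace normalized by the
  whole-record SD.

The bandwidth-adaptation index is the ordinary least-squares slope of
median frequency against contrast (Hz per unit contrast). Spectra are
computed from the fitted filter; `response_spectrum()` provides the raw
Welch periodogram of a trace where the response-side view is wanted.

## Fitting

`fit_lnk()` fits one- or two-pathway LNK models by bound-constrained
quasi-Newton optimization (L-BFGS-B). Design choices, made where the
source protocol defers to prior work:

* the filter lives in a 12-function log-spaced raised-cosine basis over
  0.6 s — smooth, causal, and low-dimensional;
* rate constants are optimized as log10 values in [−1, 2.7] (0.1–500 /s),
  which removes scale pathologies;
* the output scale, offset and pathway weights are profiled in closed form
  at every objective evaluation, so the optimizer never sees them;
* `κ` is recomputed as `1/sd(g)` from the current filter at each
  evaluation — a cheap deterministic function of the basis weights that
  removes the filter-amplitude non-identifiability smoothly — and the value
  from the final filter is stored as the model's constant;
* optimization is staged: the filter is initialized from the
  reverse-correlation LN filter (sign-split between pathways for
  two-pathway fits), eight random restarts explore the
  nonlinearity-plus-kinetics subspace with the filter held fixed, and the
  best solution is polished jointly over all parameters. A full multi-start
  in the joint space costs several times more and, in parameter-recovery
  experiments, found the same optimum.

Cross-validation follows the interleaved design: consecutive 300 ms blocks
are dealt round-robin into five folds, so every fold samples every contrast
epoch. The staged search runs on the first training set; the other folds
are warm-started from its solution with a short refit. Reported test
correlations are the mean over folds.

Parameter recovery is the package's acceptance surface for the fitter:
on a noiseless 300 s record generated from the fitter's own model family
(`synth_recovery_experiment()`, sampled at 5 ms to keep the experiment
desk-scale), the cross-validated correlation exceeds 0.995 and the
kinetic rates return within a few percent (fast rates) to a few tens of
percent (slow rates, which 300 s of data only softly identify). Recovery
of `k_a` is not asserted: `k_a` trades against the nonlinearity's output
scale whenever the data do not pin the saturation, a genuine
non-identifiability of the cascade.

## The synthetic reference cell

`make_reference_cell()` builds the ground-truth On-Off cell used by every
property test. Its structure encodes the qualitative physiology, not any
fitted values (none are published for these recordings):

* **Off pathway**: nearly monophasic negative filter (gamma-difference,
  trough ≈ 68 ms, rebound 0.25 of the trough), low-threshold steep
  nonlinearity (`κ = 3`, `b1 = −0.75`, `a = 1.6`) that activates already at
  5% contrast.
* **On pathway**: sharper, delayed positive filter (peak ≈ 140 ms,
  gamma order 8) with a pronounced negative rebound, high-threshold shallow
  nonlinearity (`κ = 1.5`, `b1 = −2.4`, `a = 1`) that stays nearly silent
  below ~15% contrast; weight 0.65 versus 1 for Off.
* **Kinetics**: similar across pathways (k_a ≈ 60, k_fi ≈ 20, k_fr ≈ 10,
  k_si ≈ 2, k_sr ≈ 1.2 /s, jittered ±8% by seed), within the 1–100 /s
  range typical of bipolar-cell release. In the reference cell `u` scales
  the activation rate only: with the slow-recovery rate also u-scaled, the
  steady-state ratio of resting to slow-inactivated occupancy becomes
  independent of drive and contrast steps produce slow *facilitation*;
  activation-only scaling yields the classic picture in which high contrast
  slowly depletes the reserve pool — a transient response peak after a
  contrast step, then decline, and a sagging baseline.

The filter and threshold placement were chosen once so that the cell
reproduces the qualitative phenomena the analyses target: at low contrast
only the Off pathway responds and the cell integrates; rising contrast
recruits the delayed-positive On pathway, the summed effective filter turns
biphasic, and the median frequency climbs steeply (≈ 3–4 Hz/σ for the full
cell versus ≈ 0.5–1.2 Hz/σ with the On pathway silenced), while gain, delay
and offset adaptation are essentially unchanged by silencing. The On/Off
threshold separation, not the kinetics, carries the differential
adaptation: exchanging the two nonlinearities approximately swaps the
pathways' output-versus-contrast curves (`α`, the OLS slope of σ(c), and
`β`, the decay constant of a saturating exponential `σ∞(1 − e^{−c/β})`
fit by profiled one-dimensional least squares), whereas exchanging the
kinetics blocks moves `α` and `β` by a few percent.

`synth_recording()` adds Gaussian noise low-passed at 50 Hz (second-order
Butterworth, forward-backward), rescaled after filtering so the noise SD is
exact; the default noise level in the pipeline is 10% of the clean-signal
SD. `synth_spike_train()` converts the membrane potential to an
inhomogeneous Poisson train through a rectified-linear rate. What the
generator does **not** emulate: spike waveforms riding on the membrane
potential, electrode drift, crossover inhibition between pathways, and any
spatial structure beyond an outer-product receptive field — so passing
tests demonstrate correctness of the analysis pipeline on data satisfying
the model's assumptions, not robustness to every pathology of real
recordings.

## Study-condition analyses

`kinetics_response_curve()` probes a kinetics block in isolation with the
canonical threshold nonlinearity `N0(x) = max(x, 0)`, whose mean and SD
both grow linearly with contrast. One unit-variance frame-noise
realization is shared across the contrast grid (common random numbers), so
adjacent grid points differ only through the kinetics and the curve's
increments are not swamped by independent sampling noise. On a 10-point
contrast grid from 0.05 to 0.5 (40 s epochs) the SD of `A(t)` increases
with mean drive with strictly decreasing increments — the discrete
concavity that defines kinetic adaptation.

`bandwidth_grid_search()` varies the Off pathway's fast inactivation and
fast recovery rates over a log-spaced grid spanning a factor of 5 each way
(a factor-25 span), simulating 30 s epochs at 5% and 35% contrast with
shared stimuli across grid points, and fitting an LN filter per contrast.
The convex-hull area of the resulting (low-contrast, high-contrast)
median-frequency points is several times larger for the intact two-pathway
cell than for the Off pathway alone.

`exchange_analysis()` uses seven contrasts from 0.05 to 0.35 at 30–40 s
per contrast. The `α` regression is unconstrained OLS (not through the
origin): with σ in the full-output normalization of the magnitude curves,
a non-adapting pathway still shows slope ≈ 1, and the
no-adaptation reference statement survives. `β`'s functional form — a
saturating exponential through the origin — matches the "plateau onset"
meaning: smaller `β` means adaptation begins at lower contrast.

## Problem sizes and reproducibility

Every analysis takes an explicit seed and derives independent sub-streams
from it, so schedules, stimulus draws, noise, and optimizer restarts are
individually reproducible; synthetic recordings store their full
provenance. The default problem sizes — 300 s records for estimation
benchmarks, 30–40 s epochs per contrast for the property analyses, 5 × 5
kinetics grids, 5 ms sampling for fitting and 1 ms elsewhere — were chosen
as the smallest sizes at which the quantities being tested are stable to
within the tolerances asserted; all of them are function arguments, and
longer runs sharpen the estimates without changing any conclusion.

## Known limitations

* Two pathways at most, four kinetic states, additive combination: the
  framework deliberately excludes crossover inhibition and divisive
  structures.
* The spike-removal criterion (derivative > 5 mV/ms and amplitude > 15 mV
  over a 50 ms running median, ±3 ms interpolation) is a documented
  stand-in for the unpublished original; its thresholds are exposed as
  arguments.
* `k_a` and the nonlinearity scale are jointly identified only when the
  record drives the nonlinearity into saturation.
* Fitted filters live in the raised-cosine span; filters with structure
  sharper than the earliest basis bump cannot be represented exactly
  (correlation with the generating gamma-difference filter still exceeds
  0.999 in recovery experiments).
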