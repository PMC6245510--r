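# lnkadapt

Tools for studying how retinal contrast adaptation — and in particular the
adaptive shift in temporal bandwidth — arises from two parallel neural
pathways with different synaptic thresholds. The package is aimed at
computational and sensory neuroscientists who want to simulate, fit and
dissect linear–nonlinear–kinetic (LNK) cascade models of On-Off retinal
cells without access to raw electrophysiology.

## The model

Each pathway is an LNK cascade. A normalized flicker stimulus *s(t)*
(zero mean; SD = contrast σ) is passed through a temporal filter,

&nbsp;&nbsp;*g(t) = ∫ F(τ) s(t − τ) dτ*,

then a static sigmoid nonlinearity

&nbsp;&nbsp;*u(x) = clamp( ((erf(κx + b₁) + 1)/2)ᵃ + b₂, 0, 1 )*,

whose output drives a four-state first-order kinetic model of synaptic
release (Resting, Active, two Inactivated states). The occupancy row vector
obeys *dP/dt = P·Q(u)* with activation rate *u(t)·k_a*, fast
inactivation/recovery *k_fi*, *k_fr*, slow inactivation *k_si* and slow
recovery *u(t)·k_sr*. The pathway output is the active-state occupancy
*A(t)*, and the cell response is

&nbsp;&nbsp;*r(t) = c · (w_ON·A_ON(t) + w_OFF·A_OFF(t)) + d*&nbsp;&nbsp;(mV).

Because the pathways sum, blocking one (setting its weight to zero) is the
in-silico analogue of pharmacologically silencing the On pathway, and the
subtraction `control − blocked` recovers the other pathway's contribution
exactly.

Around this core the package provides: Gaussian-flicker/flash/bar-flicker
stimulus generation with contrast schedules; reverse-correlation LN model
estimation (spectral filter estimate, equal-population binned
nonlinearity, spike-triggered averages, temporal PC1); adaptation metrics
(gain, delay, response offset, median temporal frequency and its slope
versus contrast); pathway analyses (decomposition, output-magnitude curves
σ(c) with their α/β summary statistics, component exchange, kinetics-rate
grid search); constrained LNK fitting with interleaved 5-fold
cross-validation; and a synthetic-data module that generates ground-truth
cells, calibrated noisy recordings and Poisson spike trains so every stage
is testable end to end.

## A worked example

Simulate the reference On-Off cell across contrasts, fit LN models per
contrast, and compare the bandwidth shift with and without the On pathway:

```r
library(lnkadapt)

cell <- make_reference_cell(seed = 1)
contrasts <- seq(0.05, 0.35, length.out = 5)

full    <- adaptation_summary(cell, contrasts, epoch_length = 40, rng_seed = 47)
blocked <- adaptation_summary(silence_pathway(cell, "On"), contrasts,
                              epoch_length = 40, rng_seed = 47)

full$per_contrast
#>   contrast     gain       delay median_frequency
#> 1    0.050 59.48849 0.080099783         2.751386
#> 2    0.125 27.08417 0.067870419         3.418343
#> 3    0.200 16.01921 0.066828276         3.854200
#> 4    0.275 12.91319 0.002720292         3.906284
#> 5    0.350  9.80181 0.017472891         3.877416

full$frequency_shift$slope
#> [1] 3.653332
blocked$frequency_shift$slope
#> [1] 1.214151
```

At 5% contrast the cell's LN filter is monophasic and its median temporal
frequency low; by 35% the filter has turned biphasic and the median
frequency has climbed — a shift of about 3.7 Hz per unit contrast. With
the On pathway silenced the shift shrinks threefold (≈ 1.2 Hz/σ) while the
per-contrast gains change by only a few percent: the bandwidth shift needs
both pathways, gain adaptation does not. The mechanism is threshold
separation, which `exchange_analysis(cell)` makes explicit — swapping the
two nonlinearities approximately swaps the pathways' output-versus-contrast
curves, while swapping their kinetics blocks barely moves them.

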