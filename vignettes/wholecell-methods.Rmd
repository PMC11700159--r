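---
title: "Whole-cell patch-clamp analysis with synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-cell patch-clamp analysis with synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wholecell)
```

## What this package does

`wholecell` implements the analysis chain for episodic whole-cell
patch-clamp recordings of cultured neurons — the kind of experiment where a
neuron is stepped through a grid of current injections in current clamp and
a grid of voltage injections in voltage clamp, and per-cell electrical
features are then compared across genotype/treatment groups. Because raw
recordings of this kind are rarely public, the package pairs the analysis
with a synthetic-cell generator that produces recordings with *exact* ground
truth, so every stage — spike detection, feature extraction, passive-property
fitting, leak subtraction, and the statistical layer — can be validated by
parameter recovery rather than by eye.

The emulated study contrasts wild-type (WT) cortical neurons with
neurofibrillary-tangle-bearing (Tau) neurons, with and without treatment by
the adiponectin-receptor agonist AdipoRon (AR), plus an APP/PS1 amyloid
model that is electrophysiologically indistinguishable from WT.

## Recording model and protocols

A `Sweep` is one uniformly sampled trace (10 kHz by convention) with a
command step described by its amplitude relative to holding and a half-open
step window `[onset, offset)`: the sample at the offset belongs to the
post-step epoch. The half-open convention makes the downstream definitions
("first 10 ms following voltage application", spike exclusion at the window
edge) unambiguous.

Three protocols are built in:

* **Current clamp**: 20 pA steps from −100 to 480 pA (30 amplitudes),
  repeated five times; run once from the cell's resting potential and once
  while holding near −60 mV (the "standardized" condition).
* **Voltage clamp**: 10 mV injections from a −60 mV holding potential,
  covering 0–100 mV plus the mandatory −10 mV leak step
  (absolute commands −70 … +40 mV).
* **Membrane test**: −5 mV pulses from −60 mV for passive properties.

The source protocols do not state the pre/step/post durations, so the
package fixes its own defaults (current clamp 100/500/400 ms, voltage clamp
50/300/150 ms, test pulse 50/150/50 ms) and stores them explicitly in every
container rather than assuming them at read time. The 0 mV injection is
included as a recorded sweep; the five current-clamp repetitions are treated
as exchangeable.

## Spike detection and rheobase features

Spikes are detected on the raw trace with first-order finite-difference
slopes (no additional smoothing, matching analysis of already
Bessel-filtered acquisitions): an up-crossing of +30 mV/ms must be followed
within 10 ms by a down-crossing of −15 mV/ms, and the voltage between the
two crossings must pass above 0 mV. Crossing times are sample-aligned (no
sub-sample interpolation for detection); candidate pairs are resolved
greedily left-to-right, so an up-cross consumed by an accepted event cannot
seed a second event. A brute-force enumeration of all crossing pairs serves
as the test oracle; the two implementations agree on 100% of randomized
traces.

Spikes are classified by the step window: up-cross inside the window of a
depolarizing step → *evoked*; before onset → *spontaneous*; at/after offset
or during a non-depolarizing step → *rebound*. Only evoked spikes enter
counts and rheobase statistics; the per-cell exclusion counts are logged so
the bookkeeping is auditable.

Rheobase is the minimum depolarizing amplitude with at least one evoked
spike in *any* repetition (the literal reading of "minimum current necessary
to elicit a spike"; the first repetition achieving it supplies the spike).
For the first spike at rheobase:

* **threshold** — voltage at the maximum of the second finite difference in
  the 3 ms window ending at the up-cross (earliest sample wins ties);
* **latency** — time from step onset to threshold (ms);
* **amplitude** — threshold to peak (mV);
* **width** — full width at half amplitude, linearly interpolated between
  samples (half-amplitude chords are tolerance-sensitive, so sub-sample
  interpolation is used here although detection is sample-aligned);
* **end** — first sample after the peak back below threshold. If the spike
  never re-crosses its threshold before the sweep ends, the width is
  undefined and the spike is excluded from the width statistics.

F-I curves report the evoked count per amplitude as the mean across
repetitions (an assumption — pooling was also defensible), plus the
per-repetition proportions of firing at least one and exactly one spike.

## Voltage clamp: leak subtraction and early/late currents

The −10 mV step is the measure of passive (leak + capacitive) current; its
trace — averaged across repetitions when present — is scaled by
`injection / −10` and subtracted from every sweep, then each trace is zeroed
on its pre-step mean. Capacitive transients are *not* blanked from the early
window, matching the plain reading of the source analysis; because the
transient scales linearly with the injection it is removed by the
subtraction for a linear cell. Per injection the pipeline reports the
maximum inward (most negative, clamped to ≤ 0) and maximum outward (≥ 0)
currents in the first 10 ms of the step, and the mean current over the last
third of the step (the steady-state/late current, signed so that negative
means net inward). Cell-level maxima are taken across the depolarizing
injections (0–100 mV).

## Passive properties

Input resistance, series resistance and capacitance come from the −5 mV
membrane-test response: repetitions are averaged, the baseline is the
pre-step mean, and the step-evoked current is fitted with
`I(t) = I_ss + (I_peak − I_ss)·exp(−t/τ)` from one sample after the edge
(avoiding the command discontinuity), with `I_peak` extrapolated to the step
onset. Then `R_s = ΔV/(I_peak − I_base)`,
`R_in = ΔV/(I_ss − I_base) − R_s`, and `C_m = τ·(R_in + R_s)/(R_in·R_s)`.
This single-exponential two-compartment estimator is the standard whole-cell
membrane-test model; the source describes only "the fit", so the package
adopts this as its project definition, fits the onset transient only, and
averages repetitions before fitting. When the transient is faster than one
sample the capacitance is unreliable: `R_in` is then recovered from the
steady state alone and `C_m`/`R_s` are reported as `NA` with a flag.
Initialization uses the 1/e point of the transient; if the full-window fit
is implausible (wrong transient sign, or τ pinned at the window length) the
fit is retried on a transient-dominated window of ~20 initial decay
constants.

## Statistical layer

* **ROUT outliers (Q = 0.05)** — univariate version: median center, robust
  SD from the 68.27th percentile of absolute residuals (n/(n−1) corrected),
  then an outside-in t-type test under FDR control
  (`p_i < Q·(n−i+1)/n`, stopping at the first failure). Applied per group.
  The full nonlinear-regression form of ROUT is out of scope.
* **Kruskal–Wallis + Dunn** for four-group per-cell endpoints, with
  tie-corrected pooled-rank variance for the Dunn z. The source names
  "Dunn's tests" without its multiplicity adjustment; Holm is the default
  here (uniformly more powerful than Bonferroni at the same family-wise
  level), with Bonferroni and Šidák available.
* **Mann–Whitney U** for the two-group (APP/PS1) design: exact enumeration
  for both n ≤ 8 without ties, else the tie-corrected normal approximation.
* **Mixed-design repeated-measures ANOVA** for spike counts and IV curves
  across steps, with the Greenhouse–Geisser ε̂ estimated from the pooled
  within-group covariance (bounded to `[1/(k−1), 1]`, exactly 1 for two
  levels) multiplying the within and interaction degrees of freedom;
  incomplete subjects are excluded listwise; Tukey HSD runs on the group
  means of subject averages. The implementation is validated against both a
  direct evaluation of the ε̂ formula and `car::Anova`.
* **Origin-constrained curve F-tests** — `Y = Plateau·(1 − exp(−K·x))`
  through the origin for "one or more spikes" curves and lines through the
  origin for "exactly one spike" curves, compared between groups by the
  extra-sum-of-squares F-test. Fits start from `(max(y), 1/median(x))` with
  a 1e−10 sum-of-squares tolerance and K bounded below at 1e−8, for
  deterministic behavior.

Significance is α = 0.05 throughout. Type-I error of each test is verified
by 500-replicate null simulation at 10 cells/group (all within 3–7%).

## The synthetic generator

Subthreshold membrane potential follows a leaky RC equation
`dV/dt = (V_rest − V)/(R_in·C_m) + I/C_m`, propagated *exactly* by its
piecewise closed form (including a per-spike adaptation current that decays
exponentially) and evaluated on the 10 kHz grid — there is no numerical
integration error and cohorts are bit-reproducible from a single
hierarchically split seed. When V crosses threshold outside refractoriness,
a stereotyped triangular spike template (linear rise to threshold +
amplitude over one FWHM, symmetric fall through an afterhyperpolarization)
is inserted and logged, giving analytically exact threshold/amplitude/width
ground truth. Template insertion, not Hodgkin–Huxley dynamics, is a
deliberate choice: the artifact tests the *analysis*, not membrane
biophysics, and a conductance model would have no exact feature truth to
recover. The generator warns when a parameterization violates the detection
criteria (rise slope ≤ 30 mV/ms, or peak ≤ 0 mV); rare drawn cells in noisy
cohorts may legitimately fall below detectability, as weak spikes do in real
recordings.

Voltage-clamp responses are the sum of a two-compartment passive response
(leak plus a capacitive transient with the series-resistance time constant,
both exactly linear in the injection), a Boltzmann-activated transient
inward component (peak normalized at a 0 mV absolute command), a delayed
Boltzmann-activated outward component, and a persistent component
proportional to the injection. The three active components are gated to
depolarizing injections only, so the −10 mV leak sweep is purely passive —
a rectification that is physiologically sensible and necessary for the
persistent current to survive leak subtraction.

Group presets encode only effect *directions* (the source reports no group
parameter values): Tau neurons have elevated input resistance, reduced
capacitance, a depolarized resting potential, elevated threshold, smaller
and broader spikes, strong adaptation (hence low spike counts and a
tendency to fire a single spike), and reduced voltage-gated currents; AR
restores Tau parameters to the WT values except for a narrower spike, and
gives WT cells weaker adaptation (more robust spiking); APP/PS1 equals WT.
Magnitudes and dispersions (lognormal, CV ≈ 0.05–0.15 for positive
parameters; 1–1.5 mV SD for voltages) are package choices documented here,
not reproductions of the source magnitudes. Default group sizes follow the
study design (WT 64, WT+AR 13, Tau 40, Tau+AR 31); tests and the
acceptance script use smaller cohorts (12–24 cells/group, and coarser F-I
grids where the endpoint does not depend on grid density) to keep runtimes
in minutes.

What passing tests do and do not show: recovery at zero noise demonstrates
the estimators are exact on their own generative model; calibration and
direction tests demonstrate the statistical layer and presets behave as
designed. None of this certifies behavior on real recordings with drift,
access-resistance changes, seal leaks or biological spike-shape variability,
which the generator deliberately does not emulate.

## Containers and interoperability

Each cell/condition is archived as a directory: a `meta.json` sidecar
(identity, genotype, treatment, condition, resting potential, sampling rate,
protocol descriptions) plus one CSV per protocol
(`sweep, repetition, time_s, command, response`), numbers written with 17
significant digits so round-trips are bit-identical. The container is meant
for per-cell archival and import; a full cohort of 10 kHz sweeps is
impractical as text, so the analysis drivers regenerate cohorts
deterministically from their seed instead. Import adapters for proprietary
acquisition formats are out of scope; any reader that can produce the CSV
layout above interoperates.

## Numerical choices and edge cases

* Threshold crossings in the generator are strict (`V > threshold`): a step
  whose steady state equals the threshold exactly never fires, which keeps
  the analytic rheobase bound exact on the grid.
* Ties in the second-derivative maximum resolve to the earliest sample.
* Zero robust scale in ROUT (all values equal) removes nothing; n < 4 warns
  and removes nothing.
* All-tied Kruskal–Wallis input returns H = 0, p = 1 rather than NaN.
* `leak_subtract` with a single −10 mV sweep returns an identically zero
  trace for that sweep; with repetitions it subtracts their mean.
* Degenerate membrane-test transients (shorter than one sample) fall back
  to steady-state resistance with flagged capacitance.

## Limitations

Space-clamp error, series-resistance compensation, bridge balance, liquid
junction potentials and electrode drift are not modeled — matching the
source analysis, which disclaims space clamp. The generator's spike shape
is stereotyped; spike-frequency adaptation is a single exponential current.
The Dunn adjustment choice (Holm) is a documented assumption, as are
mean-over-repetitions F-I counts and onset-only membrane-test fits.
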