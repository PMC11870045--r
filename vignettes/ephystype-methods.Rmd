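---
title: "Models and methods behind ephystype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ephystype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephystype)
```

# The generative model

`ephystype` analyses current-clamp recordings; its correctness rests on a
simulator whose every spike has exact, recorded ground truth. The model is
a hybrid: adaptive exponential integrate-and-fire (AdEx) subthreshold
dynamics, with each model spike replaced by a stereotyped action-potential
waveform. A pure integrate-and-fire neuron has no spike downstroke, so
half-width and afterhyperpolarization would have no ground truth to
recover; the pasted waveform trades biophysical fidelity for exact
testability, which is the purpose of the module.

The membrane equation (units: mV, pA, nS, pF, ms) is

$$C_m \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
  - w - g_h h (V - E_h) - g_{BK}^{act} (V - E_K)
  - g_{tonic} (V - E_{Cl}) - g_{GIRK} (V - E_K) + I + I_{bg} + \xi(t)$$

with subthreshold adaptation $\tau_w \dot w = a_w (V - E_L) - w$, a sag
(h-type) gate $\tau_h \dot h = h_\infty(V) - h$ activating on
hyperpolarization, and an Ornstein–Uhlenbeck current noise $\xi$ with
stationary SD `sigma_noise` and correlation time `tau_noise` (exact
discrete update, so the stationary SD is independent of the step size).

When $V$ reaches the numerical trigger `V_cut`, the stereotyped waveform
is pasted from the last subthreshold sample: a linear rise to `peak`
(0.25 ms), a linear fall to `onset − ahp_depth` (0.75 ms), then an
exponential recovery towards `V_reset` over 6 ms (covering the medium-AHP
window) that is clamped never to descend below the AHP floor — so
`ahp_depth` is exact ground truth regardless of where `V_reset` sits. The
analytic half-width of the piecewise-linear flanks,
$\mathrm{rise}/2 + \mathrm{fall}\cdot\frac{A/2}{A + \mathrm{ahp\_depth}}$
with $A$ the onset-to-peak amplitude, is recorded per spike. Spike
increments $w \mathrel{+}= b_w$ and the BK increment are applied at the
trigger; gating variables keep integrating through the pasted segment.

## The BK mechanism

The BK-like conductance is the pharmacological pivot of the analysis: the
BK blocker (paxilline) must lower rheobase at high extracellular calcium,
and the GABAb agonist (baclofen) must *raise* maximum firing at high
calcium yet lower it at low calcium. A purely spike-triggered conductance
cannot move rheobase — it only acts after the first spike — so the model
splits $g_{BK}$ into a tonically active fraction
$\varphi_{BK} g_{BK}$ (subthreshold, shifts rheobase) and a
spike-triggered increment $(1-\varphi_{BK}) g_{BK}$ decaying with
$\tau_{BK}$ (accumulates across a train, caps sustained firing). Both are
multiplied by `ca_scale` ∈ [0, 1], the stand-in for extracellular calcium
availability (1 ≈ 2.5 mM recording solution, 0 ≈ BK functionally silent).

Drug conditions are invertible spec transformations:

* **baclofen** — adds `g_GIRK` (default 0.8 nS) and multiplies $g_{BK}$
  by a suppression factor (default 0.2). The suppression factor is a free
  calibration knob: no quantitative value is available for how strongly
  GABAb activation suppresses BK, only the direction; 0.2 is chosen so
  that at `ca_scale = 1` the removed spike-triggered BK cost outweighs the
  added GIRK leak (maximum frequency rises), while at `ca_scale = 0` only
  the GIRK cost remains (maximum frequency falls).
* **paxilline** — $g_{BK} \to 0$; **picrotoxin** — $g_{tonic} \to 0$;
  **APV + DNQX** — background drive $I_{bg} \to 0$.

A known limitation: empirically the GABAb agonist slightly *lowered*
type 1 rheobase at high calcium; in this model the GIRK leak's
subthreshold cost exceeds the tonic-BK relief, so simulated baclofen
raises rheobase. The calibrated direction contracts cover paxilline's
rheobase effect and baclofen's maximum-frequency effects at both calcium
levels; the baclofen–rheobase direction is not reproduced.

## Presets

Three presets encode the empirical types and preserve the orderings
tau: type2 > type1 > type3, input resistance: type2 > type1 > type3,
rheobase: type3 > type1 > type2:

* **type1** (continuously adapting): moderate passive properties; small
  per-spike adaptation increments with long decay (b_w = 2 pA,
  tau_w = 800 ms; spike-BK 0.16 nS, tau_BK = 300 ms) so inter-spike
  intervals lengthen *gradually* — strong single-spike jumps would make
  the first interval less than half the median of the rest and trip the
  burst classifier.
* **type2** (bursting): lowest rheobase, highest input resistance and
  tau; depolarized reset (−47.5 mV, just below threshold) produces the
  initial doublet; a large, slow sag conductance (g_h = 3 nS, reversal
  −20 mV, tau_h = 100 ms) produces both the sag and a rebound spike on
  release from the −200 pA pulse.
* **type3** (irregular): highest rheobase, lowest input resistance and
  tau; OU current noise (10 pA SD, 5 ms correlation) makes firing
  irregular. The noise level is a compromise: visibly irregular
  inter-spike intervals while the −10 pA test pulse remains analysable.

Each preset's `V_cut` sits 2–3 mV above its `V_T` (−43/−44/−40 mV), so
the extracted spike threshold is a clean, noise-free feature separating
the types — mirroring the empirical finding that threshold differs
between the adapting and irregular types.

Cohorts jitter the passive and adaptation parameters log-normally with
SD 0.08 (≈8% coefficient of variation) and the reversal/threshold
potentials by ~1 mV — the within-type spread typical of curated slice
data sets after quality control.

# Feature extraction

All operational definitions follow standard practice for Clampfit-style
analysis:

* **Spike detection**: one event per upward 0 mV crossing followed by a
  local maximum, 1 ms refractory. Spikes with peak-to-threshold amplitude
  below 5 mV (spikelets during depolarization block) are excluded from
  frequency counts.
* **Threshold**: voltage at the first sample before the peak where the
  two-point forward-difference dV/dt reaches 5 mV/ms and stays above it
  up to the rising flank (backward search capped at 10 ms). The
  forward difference at the native 20 kHz sampling is used without
  smoothing.
* **Shape**: amplitude = peak − threshold; half-width by linear
  interpolation of the two half-amplitude crossings; fAHP and mAHP are
  the threshold voltage minus the minimum within 4 and 6 ms *after the
  spike peak* (the peak is the unambiguous fiducial; whether the
  empirical 4/6 ms latencies are referenced to peak or threshold is
  ambiguous, and the peak reading is adopted throughout). Depths are
  reported as computed, without clamping at zero.
* **Excitability**: rheobase is the lowest step with ≥1 accepted spike;
  frequencies are counts over the 500 ms step; mean frequency averages
  all depolarizing steps. AP-train statistics (mean ISI, amplitude
  change, burst/adaptive category, per-spike shape) are measured at the
  step whose count is nearest 50% of the maximum, ties toward the lower
  current.
* **Burst/adaptive category** (no standard operational definition
  exists, so the package fixes one): *burst* if the first ISI is shorter
  than half the median of the remaining ISIs (≥3 spikes); else *adaptive*
  if the last ISI exceeds the first by more than 30%; else *neither*. It
  is one categorical feature — the 18-feature count only works that way.
* **Passive properties**: resting potential from the pre-pulse baseline;
  a single exponential is fitted to the −10 pA test-pulse onset
  transient (bounded Levenberg–Marquardt: asymptote constrained near the
  observed tail, tau ∈ [0.5, 150] ms) and cross-checked against the 63%
  criterion. R_in uses the fitted asymptote rather than the raw tail
  because a 100 ms pulse is only ~2.5 tau for high-resistance cells.
  Cp = tau/R_in (the voltage-clamp membrane test used empirically is not
  available from current-clamp data). The test and sag pulses are
  repeated (32 and 4 sweeps) and averaged — the standard remedy for
  estimating a 3 mV deflection under mV-scale voltage noise; the rebound
  flag is evaluated per sweep, since averaging washes out spikes. A fit
  with RMSE above 20% of the observed deflection, or a runaway
  asymptote/time constant, yields a missing tau with a warning.

Cells with more than 4 missing features are excluded (flagged and
logged); for clustering only, remaining missing values are imputed by the
feature median with a recorded flag.

# Hill F-I fitting

`fit_hill()` fits $y = a x^b/(c^b + x^b)$ by bounded Levenberg–Marquardt
(ftol = ptol = 1e−10, ≤10⁴ evaluations). Initialization
$a_0 = \max F$, $c_0$ = current at the first $F \ge a_0/2$, $b_0 = 2$;
bounds $a \in (0, 3a_0]$, $b \in (0, 100]$, $c \in (0, 3\max x]$ —
chosen for stability on sparse 10 pA grids. Zero-frequency points are
kept: they constrain the midpoint. A fit that ends on a bound or exceeds
the cap is returned with `converged = FALSE` (best iterate kept). If the
fitted maximum exceeds the largest observed frequency the fit is flagged
`extrapolated_max` — the cell's F-I curve had not plateaued.

Steepness is reported as the slope at the midpoint, $ab/(4c)$ in Hz/pA —
the units of the empirically reported gains — rather than the
dimensionless exponent *b*; both are stored. Under current rescaling
$x \to sx$: $\hat c \to s\hat c$, steepness $\to$ steepness$/s$, and
$a, b$ unchanged (verified on exact model data).

# Event detection

Spontaneous PSCs are found by sliding a peak-normalized biexponential
template (defaults 0.5 ms rise, 5 ms decay, 30 ms long — manually fitted
empirical templates are not recoverable, so a generic fast-EPSC shape is
used) across the negated current trace. In each window the template is
optimally scaled and offset by least squares; the detection score is
scale/SE(scale) (the Clements–Bekkers statistic). Events are score
maxima of contiguous supra-criterion runs with fitted amplitude ≥ 5 pA;
the criterion defaults to 3.5, the conventional value for this
statistic. Fitting the offset per window makes detection invariant to DC
shifts. Rolling sums are exact (cumulative sums); the template
cross-correlation uses FFT convolution.

# Clustering and typing

Features are z-scored before Ward clustering — they span four orders of
magnitude (pA versus dimensionless ratios), so unscaled Euclidean
distances would be meaningless. The rebound flag is encoded 0/1; the
burst/adaptive category defaults to two 0/1 dummies (19 columns,
documented as such) because a single ordinal column would impose an
arbitrary metric between categories; `encoding = "ordinal"` gives the
strict 18-column reading (0/0.5/1). Ward uses `hclust(method =
"ward.D2")` on Euclidean distances; its merge sequence is verified in
the tests against an exhaustive greedy minimum-variance-increase oracle,
and its heights equal $\sqrt{2\,\Delta\mathrm{ESS}}$. k = 3 by default
(the empirical dendrogram cut), configurable; no automatic selection.
Cluster ids are renumbered by descending size.

Random-forest importance: 500 trees, impurity (Gini) importances
normalized to sum 1, stratified 5-fold cross-validated accuracy with an
explicit seed (none of these are specified empirically; these are the
conventional choices). Classes with fewer than 5 members switch the
accuracy to leave-one-out, flagged. PCA loadings are signed so each
component's largest-magnitude loading is positive.

# Statistics

The normality gate is applied to the paired *differences* (the natural
vector for a paired test) at α = 0.05: normal → paired t, else Wilcoxon
signed-rank (exact for n ≤ 25 when ties and zeros allow, otherwise the
continuity-corrected normal approximation). All-zero differences return
p = 1 with a degenerate flag. Group comparisons gate per group: all
normal → one-way ANOVA with Holm–Šidák-adjusted pairwise t tests, else
Kruskal–Wallis with tie-corrected Dunn z tests (Holm-adjusted). Percent
changes are reported rounded to the nearest integer alongside full
precision — the rounding convention that reproduces the published 19%,
20%, 30% and 34% worked examples; two published values (28%, 49%) appear
truncated rather than rounded and are treated as known half-unit
discrepancies. No family-wise correction is applied across the whole
study, matching the source analysis.

The simulated type-I error of the two-stage gate (Gaussian null, n = 10,
5,000 replicates) is ≈0.045–0.05, within the ≤0.07 sanity bound — the
gate does not meaningfully inflate the nominal level.

# Numerical choices and problem sizes

* Integration: fixed-step exponential-Euler at dt = 0.05 ms (one sample
  at 20 kHz), no adaptive stepping — bit-for-bit reproducibility given
  (spec, protocol, condition, seed). All stochastic stages take an
  explicit master seed and expand it deterministically per sweep.
* Divergence guard: subthreshold voltage outside [−150, +80] mV aborts
  with the sweep index.
* The resting potential is found by bracketing the stable root of the
  steady-state current balance on a grid (the balance also has an
  unstable root past the exponential threshold); tonically active
  specifications without a subthreshold fixed point start from `V_reset`.
* Reference problem sizes: cohorts of 25 cells (17/3/5 per type) with a
  25-step family, a 4-sweep sag pulse and a 32-sweep test pulse per
  cell; the spike-count oracle runs on 1,250 randomized sweeps; the
  detection benchmark uses one 60 s trace at 20 kHz (~120 events); the
  statistical-gate calibration uses 5,000 replicates. These sizes give
  stable estimates for every calibrated contract while keeping a full
  run of the suite in the low minutes.

# What the generator does and does not emulate

The synthetic data reproduce: square-pulse step families, sag/test
pulses, gap-free firing and PSC traces with known events; three firing
phenotypes with realistic passive-property spreads; drug-condition
conductance changes with the published effect directions; OU current
noise. They do **not** reproduce: conductance-based action potentials
(spikes are stereotyped), multi-compartment or Hodgkin–Huxley kinetics,
synaptic networks, electrode/access-resistance artifacts, bridge
imbalance, or liquid-junction potentials — so passing tests demonstrate
the *analysis* is correct against known ground truth, not that the model
reproduces any particular real recording. Real-data idiosyncrasies
(drift, partial depolarization block, access-resistance changes — the
35 MΩ / 30% drift exclusion rule applies to real recordings only) are
out of scope, and the published cluster-level statistics (PCA variance
fractions, random-forest accuracy, tau importance) depend on the real
recordings and are not reproduction targets.
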