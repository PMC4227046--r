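---
title: "Measuring motoneuron excitability: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring motoneuron excitability: models, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(mnphys)
```

## The scientific problem

Neonatal mouse spinal motoneurons fall into two physiological classes that
can be told apart from their response to a long (5 s) liminal current pulse.
*Immediate-firing* cells discharge from pulse onset at a nearly constant
rate; they are S-type motoneurons (innervating slow-contracting muscle
fibers), express Errβ, lack chondrolectin and MMP9, and are resistant in
amyotrophic lateral sclerosis (ALS). *Delayed-firing* cells start to fire
seconds after pulse onset with an accelerating discharge — the delay
shrinking, and eventually vanishing, as the injected current grows; they are
F-type motoneurons, the population vulnerable in ALS. Contrasting these two
classes between wild-type (WT) and mSOD1(G93A) mutant littermates tests
whether early intrinsic hyperexcitability marks the cells that later
degenerate.

`mnphys` implements the complete measurement pipeline behind that
comparison — intrinsic-property extraction from current-clamp protocols,
firing-pattern classification, mixed-mode-oscillation (MMO) analysis on slow
current ramps, SWC dendritic morphometry with a slice-plane inclusion rule,
and the group statistics — together with a synthetic motoneuron generator
that provides ground truth for every stage, since the original recordings
are not publicly deposited.

## The measurement model

All protocol constants mirror the acquisition conventions of neonatal
slice electrophysiology (10 kHz digitization; liquid junction potential not
corrected):

* **Input conductance** $G_{in}$: 500 ms pulses from −100 pA to +20 pA in
  30 pA steps, 10 repeats each; steady-state deflection = mean over the last
  100 ms of the pulse; $G_{in}$ is the inverse slope of the least-squares
  V–I line.
* **Rheobase**: 5 s square pulses increasing by 50 pA from zero (100 pA
  steps above 0.9 nA, 20 s between pulses); the rheobase is the smallest
  tested amplitude eliciting at least one overshooting action potential.
* **Voltage threshold** $V_{th}$: on the first spike of the rheobase sweep,
  the voltage at which $dV/dt$ first exceeds 10 mV/ms. The derivative is a
  central difference after a 0.2 ms boxcar (raw differences at 10 kHz are
  noise-dominated), and the crossing voltage is linearly interpolated
  between samples — reporting the first discrete sample instead would bias
  the threshold upward by up to one sample's rise (~1 mV on a fast
  upstroke).
* **AP shape and AHP**: thirty 1 ms suprathreshold pulses, averaged after
  peak alignment; amplitude = peak − baseline, width at half-amplitude, and
  the after-hyperpolarization relaxation fit by
  $V(t) = V_{rest} - A e^{-(t - t_0)/\tau}$ from the trough until recovery
  to within 5% of the trough depth. The asymptote is held at the measured
  resting potential (the trough is located on a 1 ms-smoothed trace):
  leaving it free makes $\tau$ poorly identified on a window that stops
  near recovery.
* **Ramps**: triangular ramps at 0.1 nA/s (three trials). Recruitment /
  derecruitment currents are the injected currents at the first ascending
  and last descending spikes; the discharge frequency is read from the
  inter-spike interval (ISI) containing recruitment + 0.5 s; the F–I gain
  is the least-squares slope of instantaneous frequency on current over the
  ascending *primary range*.
* **Firing pattern**: *delayed* when the first-spike latency on the rheobase
  sweep exceeds 500 ms, or exceeds 200 ms with an accelerating discharge
  (positive Theil–Sen slope of instantaneous frequency on time, ≥3 spikes);
  *immediate* otherwise. Immediate cells fire within tens of milliseconds
  of pulse onset and delayed cells after seconds, so the cutoffs sit far
  from both modes; both are exposed in `run_config()`.
* **MMO detection**: inside each ISI (excluding 10 ms after the preceding
  spike and ~5 ms before the next upstroke), subthreshold local maxima with
  ≥1 mV prominence below the measured threshold, counted on a 2 ms-smoothed,
  detrended segment (the detrending removes the AHP-recovery ridge the
  oscillations ride on). A cell is MMO-positive when ≥2 oscillations occur
  in each of ≥2 ISIs. The sub-primary/primary boundary is the current at the
  end of the last MMO-containing ascending ISI; a primary range must span
  more than 0.05 nA above the boundary, otherwise the gain is declared
  absent (delayed cells, whose MMOs persist to the ramp peak, therefore have
  no measurable gain — matching their phenomenology).

**Morphometry.** Reconstructions from 400 µm slices are partial, so only
radial dendrites that stay within the slice plane and above 50 µm depth are
analyzed: `apply_slice_filter()` removes every subtree from the first
too-deep node onward (a plunging trunk removes its whole dendrite). Metrics
follow the standard definitions: primary dendrites = children of the soma;
branching points = non-soma nodes with ≥2 children (higher-order nodes count
once); total length = summed inter-node Euclidean distances; dendritic
paths = tip-to-soma trajectory lengths; terminal segments = tip to nearest
branching point. Soma area is an externally measured scalar (brightfield
images), never derived from the SWC.

**Group statistics.** Summaries are mean ± SD with range and N. Two-group
property contrasts use two-tailed Mann–Whitney (exact enumeration below a
combined n of 20 without ties), contingency tables the probability-mass
two-tailed Fisher exact test, and distribution contrasts the two-sample
Kolmogorov–Smirnov test. The rheobase–conductance relation is fit with a
zero intercept, $I = G\,U$, so the slope $U$ is a voltage:
$U = 1000\,\Sigma GI / \Sigma G^2$ mV. Slopes are compared by (i) a t test
on the slope difference with $SE(U) = \sqrt{SSR/(n-1)/\Sigma G^2}$
(per-group variances, $n_A + n_B - 2$ df — the historical analysis does not
state its variance pooling; the Monte-Carlo null calibration below validates
this choice) and (ii) a Chow test with $k = 1$. Shapiro–Wilk checks residual
normality first. No multiple-testing correction is applied anywhere: every
reported p-value is raw, as in the original tables.

## The synthetic generator

`sample_population()` draws ground-truth cells from the published per-group
summary rows (`mn_reference_table()`). Three design decisions matter:

* **Moment-matched truncated normals.** Each printed row (mean ± SD with
  range) describes data already confined to the printed range, so the
  generator solves for the underlying normal whose *truncated* moments
  reproduce the printed mean and SD, then samples by rejection. Some rows
  are arithmetically infeasible (the printed SD exceeds the largest SD any
  distribution on the printed range can have, e.g. a threshold row of
  −44 ± 7 mV on [−50, −41]); the solver then pins the mean and accepts the
  closest achievable SD, keeping the truncation acceptance probability
  workable.
* **Pattern-specific anchoring of the Ohmic law.** Every cell satisfies
  $rheobase = G_{in} \Delta V / 1000$ exactly, but the printed rheobase,
  conductance and threshold rows of a group are not mutually consistent
  under independent draws, so one quantity must be derived. For immediate
  cells the threshold is the biologically primary quantity (its
  hyperpolarization in the mutant is the central finding, and $U$ of the
  zero-intercept law is close to the mean ΔV), so the generator draws
  resting potential, threshold and rheobase and derives the conductance.
  For delayed cells the measured first-spike threshold is contaminated by
  seconds of accommodation during the pre-spike depolarization and sits
  well above the subthreshold law; the generator therefore draws the
  conductance from its row, draws the *emission* ΔV around the group's
  $U = 1000\,\bar I/\bar G$ value (≈23 mV for WT delayed, a few mV of
  cell-to-cell scatter), derives the rheobase as their product — which also
  reproduces the rheobase-grows-with-conductance scatter — and renders the
  first-spike threshold with an accommodation offset drawn from the printed
  delayed ΔV row.
* **Phenomenological discharge laws.** The latency of delayed cells follows
  $L(I) = delay\_scale \cdot \max(0, (2R - I)/R)$ — a linear decay vanishing
  at twice rheobase, the simplest law consistent with a delay that
  "progressively decreases and disappears". `delay_scale` has no published
  distribution (one worked example at 2.9 s); 2.5 ± 1.0 s on [1, 4.5] s
  keeps the first spike inside the 5 s pulse. Delayed discharge accelerates
  from 0.6× to 1× of its asymptotic rate across the pulse; immediate
  discharge is constant-rate. On ramps, immediate cells follow
  $f = f_0 + gain \cdot (I - I_{rec})$ and delayed cells a rate law
  calibrated so the ISI at recruitment + 0.5 s matches the cell's drawn
  `f_half_second_true`. MMO-positive cells carry 2 mV damped ~150 Hz
  oscillations in their ISIs, only below the cell's sub-primary ceiling;
  MMO incidence per group follows the published proportions (49/50, 31/31,
  13/15, 3/11). Gaussian recording noise defaults to 0.3 mV SD.

Trace synthesis has two modes. **Template** mode composes sweeps
analytically: RC charging (τm = 20 ms — not separately tabulated; a typical
neonatal motoneuron value) toward $V_{rest} + I/G_{in}$, stereotyped spikes
whose upstroke derivative grows exponentially (τ = 0.3 ms) through 10 mV/ms
exactly at the rendered threshold, a linear repolarization sized so the
width at half-amplitude equals the cell's value, and a mono-exponential AHP.
Action-potential amplitudes are floored at an overshoot of +5 mV because the
experimental inclusion criterion retains only cells with overshooting
spikes, and the spike detector (peaks above 0 mV) encodes that criterion.
**Mechanistic** mode integrates (in compiled code) a leaky integrate-and-fire
cell with a slowly inactivating potassium conductance
($dh/dt = -h/\tau_h$ during depolarization, $\tau_h = delay\_scale/\ln 2$,
~100 pA of K current at threshold, $E_K = -90$ mV): the K current delays the
threshold crossing at liminal currents and its inactivation produces the
delayed, accelerating discharge. The two modes agree on the measured
rheobase within one search step, which is the designed contract between
them.

Synthetic dendritic trees (`generate_tree()`) draw the primary-dendrite
count, bifurcation count (spread uniformly across dendrites, random binary
topology), total length and terminal-segment lengths from the Table rows,
rescaling all segment lengths so the summed length equals the drawn total.
Nodes are laid every 10 µm; each dendrite descends linearly in depth along
its path (inter-node distances stay exact, so the drawn total length is
recovered to machine precision), staying within the slice by default —
the printed morphology rows describe post-filter reconstructions — while a
`deep_fraction` option renders plunging dendrites to exercise the filter.
The mSOD1-delayed branching row is not tabulated; 47 ± 17 on [26, 85] comes
from the published 0.18 mm/branch-point slope at that group's 8.7 mm mean
length.

## What the synthetic data do and do not show

The generator reproduces the *summary structure* of the real populations —
marginal distributions per property, the Ohmic law, the qualitative
discharge phenomenology and the published MMO incidences — but not
everything real recordings contain: no bridge-balance or series-resistance
artifacts, no slow drift or seal degradation, white rather than 1/f noise,
stereotyped rather than history-dependent spike waveforms, and only the
correlations explicitly built in (threshold–rheobase, conductance–rheobase).
Passing the recovery suite therefore demonstrates that the *measurement
pipeline* is unbiased at realistic signal-to-noise under the published
population structure; it does not validate the pipeline against acquisition
artifacts absent from the model.

## A worked example

```{r pipeline, eval = FALSE}
res <- run_pipeline(
  groups = list(c("WT", "immediate"), c("mSOD1", "immediate")),
  n_per_group = 20, seed = 1, protocols = c("rheo", "iv"),
  morphology = TRUE)
res$summary
res$comparison

# rheobase-conductance law of the two groups
wt <- dplyr::filter(res$population, genotype == "WT")
ms <- dplyr::filter(res$population, genotype == "mSOD1")
cmp <- compare_slopes(wt$g_in, wt$rheobase, ms$g_in, ms$rheobase)
tidy(cmp)
plot_slope_comparison(cmp, labels = c("WT", "mSOD1"))
```

## Numerical choices and degenerate inputs

* Sample interval 1e-4 s throughout (10 kHz); all seeds are threaded
  explicitly, and every generator call is bit-reproducible under a fixed
  seed.
* The AHP fit starts from a log-linear estimate and uses `nls`
  (Levenberg–Marquardt via `minpack.lm` as fallback); a flat post-spike
  trace (< 0.5 mV trough) is an error, not a zero.
* Spike detection requires an overshooting local maximum with a 1 ms
  refractory separation; an empty train is a valid result everywhere except
  classification, which needs at least one spike.
* Trifurcations count as single branching points; SWC validation rejects
  duplicate ids, orphaned parents, multiple roots and cycles, naming the
  offending node.
* Zero-variance specification rows collapse the population onto the row
  means (used in tests); an empty truncation interval is an error after a
  bounded number of rejection attempts.
* The test-suite and acceptance problem sizes (populations of 200–1000
  cells, 200 trees, 10^4 null simulations) are chosen so each recovered
  mean has a standard error several times smaller than its acceptance
  band.

## Known limitations

* The discharge laws are phenomenological; the mechanistic mode reproduces
  the qualitative delayed/immediate phenotypes but is not a biophysically
  detailed conductance model (no A-current kinetics, no synaptic input,
  no temperature dependence).
* Ramp synthesis is template-only; mechanistic mode covers the square-pulse
  protocols.
* The generator treats cells as independent; per-animal clustering is out
  of scope, mirroring the original analysis.
* Immediate-cell conductance is a derived quantity and may exceed the
  printed conductance range for extreme threshold/rheobase pairs; the
  printed conductance row is anchored exactly in the delayed groups, where
  the published comparison needs it.
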