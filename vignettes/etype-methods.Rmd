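---
title: "Classifying Lamina VII e-types and dissecting their Kv3 currents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Lamina VII e-types and dissecting their Kv3 currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l7ephys)
```

## The scientific problem

Parasympathetic preganglionic neurons (PGNs) in Lamina VII of the
lumbosacral spinal cord drive bladder contraction; their quiescence
during filling is thought to depend on recurrent inhibition by
fast-firing interneurons in the same lamina. Distinguishing these cell
classes electrophysiologically — and establishing that the fast-firing
class owes its phenotype to high-voltage-activated Kv3 potassium
channels — requires a chain of analyses: firing-pattern feature
extraction from current-clamp step families, unsupervised e-type
classification, pulse-train fidelity, pharmacological isolation of
TEA- and DTX-sensitive currents with Boltzmann activation fits,
evoked/spontaneous synaptic-current analysis, neurite morphometrics,
and object-based colocalization of Kv3 puncta with synaptic boutons.

`l7ephys` implements this chain as tested, reusable functions, and
pairs every analysis with a synthetic-data generator that emulates the
four firing archetypes of the lamina. Because the generators emit
exact ground truth (spike times, conductance components, planted event
amplitudes, planted angles and colocalization), every extractor in the
package is validated against what was actually put in — no recordings
are required to exercise the full pipeline.

## The synthetic population: what it emulates

`simulate_current_clamp()` is deliberately phenomenological. The
analyses consume waveforms and spike times, not channel mechanisms, so
spikes are inserted as stereotyped templates on a passive subthreshold
trajectory; a Hodgkin–Huxley-style generator would add parameters
without adding testability, and its "ground truth" would itself need a
detector. A template is parameterized exactly by the quantities the
extractor measures:

* **base width** (rising to falling crossing of the threshold
  voltage), **amplitude** (peak − threshold), **repolarization
  duration** (peak to falling crossing), **AHP amplitude and
  duration** — per-archetype means and between-cell SDs follow the
  published per-e-type AP statistics (e.g. the fast-bursting type:
  width 1.3 ± 0.4 ms, AHP 21.6 ± 5.9 mV);
* a quadratic pre-depolarization joins the template continuously to
  the local baseline and reaches the 10 mV/ms detection criterion
  exactly at the parameterized threshold voltage, so detector and
  generator agree about where an AP begins.

Spike counts on a 1-s step are `round(gain * (I - rheobase))`, exact
at any noise level, so F–I curves and failure rates can be checked
against planted truth sample by sample. The fast-bursting archetype's
F–I is anchored to the published control (60.25 Hz) and TEA
(35.75 Hz) rates at 140 pA with a 20-pA rheobase; the other three
archetypes are calibrated only qualitatively (slower, mutually similar
rates), because no per-type F–I parameters are published.

Firing patterns are built from ISI profiles: a geometric slowdown
whose *total* range is bounded (`last/first ISI = 1 + 4 * adaptation`;
a constant per-pair ratio would compound absurdly over a 60-spike
train), an initial three-ISI burst at a quarter of the regular
interval, optional pauses, multiplicative log-normal ISI jitter
rescaled so the count stays exact, and a delayed first spike for the
steady-delayed type. Two guards keep the synthetic traces inside the
regime where "an AP" is well defined: per-cell waveform draws are
winsorized at ±2 SD (an unconstrained log-normal tail can produce a
spike whose upstroke is slower than its own AHP recovery — not an
action potential), and spike counts are capped at the refractory
ceiling, with bursting cells capped at 40% of it so burst ISIs stay
clearly below half the regular interval.

What the generator does **not** emulate: channel kinetics, sag/Ih
trajectories, electrode artifacts, slow drift, seal instability, or
biological covariation between features. Passing tests therefore show
that the *analysis chain* is correct and well calibrated on data with
the assumed statistical structure, not that real Lamina VII recordings
will cluster this cleanly.

## Feature extraction and detection choices

`detect_aps()` uses a slope criterion (default 10 mV/ms). Numerical
choices that matter:

* the slope is a backward difference over an adaptive span (capped at
  0.2 ms) chosen so that the slope estimate's noise SD stays well
  below the criterion at 50 kHz; a plain per-sample derivative is
  unusable at that rate with 0.3 mV noise;
* the threshold is assigned by walking back from the upstroke's slope
  maximum to the interpolated criterion crossing — anchoring at the
  candidate sample itself would inherit the (noisy) anchor position;
* candidate peaks are reached by climbing from the anchor past
  noise-scale apexes to the *first* local peak (a windowed argmax can
  skip to a later, taller AP);
* a genuine AP must exceed its threshold by 10 mV, show an upstroke
  at least 1.5x the criterion, and fall by at least 8 mV afterwards.
  The last rule rejects the template's own AHP-recovery ramp, which
  ends in a 5.5-mV ease-down and otherwise mimics a small spike.

The seven clustering features (maximal rate, adaptation index, ISI
CV, accommodation, burst/pause/delay flags) are computed on the
maximal-firing sweep (ties towards the larger current), with rheobase
and first-spike latency from the lowest suprathreshold sweep. The
burst/pause/delay rules (first-two-ISI mean < 0.5x median; any ISI
> 3x median; rheobase latency > 100 ms) are declared, configurable
defaults — the source terminology names these events without defining
them.

## E-typing

Features are z-scored (sample-SD convention; binary flags scaled like
continuous features by default, switchable), clustered with Lloyd
k-means over `k = 1..8` with 10 random restarts per k, and the cluster
number selected at the maximum second difference of the inertia curve
(normalized by the total SS; ties to the smaller k). Two design points
deserve note:

* a monotone geometric inertia decay has its maximal raw second
  difference at k = 2 regardless of structure, so a log-linearity
  check (R² > 0.995 of `log(inertia) ~ k`) declares such curves
  structureless, warns, and reports k = 1;
* on the default population (96 cells, 24 per type) the elbow selects
  k = 4 and the labels recover the planted archetypes with adjusted
  Rand index ≥ 0.97 across seeds — these are properties of the
  calibrated archetype contrasts, verified in the test suite, not
  guarantees for arbitrary populations.

AP-waveform typing extracts the first AP at rheobase (1 ms
pre-threshold to 10 ms post-threshold, resampled to 200 points,
amplitude-normalized so shape rather than size clusters), k-means
clusters the shapes, and cross-tabulates AP-types against e-types as
column percentages.

## Kv current isolation and activation fits

`measure_family()` reads plateau currents as the mean over the final
50 ms of each 250-ms step and tail currents just after the step end,
skipping 1 ms of capacitive transient. The default tail statistic is
the mean over the first 2 ms of the search window: the deactivating
tail is largest at the window start, and a literal per-sample extremum
is an order statistic of the noise whose signal-dependent bias
distorts the foot of the activation curve and ruins the calibration of
the curve-comparison F test (the literal rule remains available as
`tail_stat = "peak"`).

`fit_activation()` fits the Boltzmann activation curve with a
deactivation floor: tails are measured against the post-step baseline,
so their expectation is `Imax * (Po(V) - Po(V_post))` with
`Po(V) = 1/(1 + exp((V50 - V)/k))`. Ignoring the floor biases V50 by
about +0.6 mV on this protocol; with it, recovery on noiseless
synthetic tails is exact. The parameterization uses a positive slope
with the `(V50 - V)/k` convention throughout.

`compare_activation_fits()` implements the extra-sum-of-squares F
test with only V50 shared between conditions (Imax and slope stay
per-dataset), because the scientific claim concerns the activation
shift. Under the null the test rejects at 5.3% (400 simulations); an
18-mV shift at realistic noise is detected in every run.

`subtract_conditions()` is exact element-wise subtraction; with the
default 50% TEA block of the Kv3-like component (the concentration
used does not fully block Kv3) the sensitive-current estimate is half
the true component, and with a full block it equals it — both are
asserted against generator ground truth.

## Synaptic analysis

Evoked PSC amplitudes use a 5-ms pre-stimulus baseline, a 20-ms peak
window after a 1-ms artifact blank, and — for the second and later
pulses — a baseline extrapolated from the single-exponential decay of
the preceding PSC. With this correction the second amplitude of
strongly overlapping pairs is recovered within 2%; without it, the
decaying residual of the first PSC biases the estimate (both behaviors
are tested). Train responses report per-pulse amplitudes and the OLS
slope of amplitude against pulse number, in pA/pulse (the units of the
published −2.66 gradient are not stated; pA/pulse is assumed).

Spontaneous events are detected by threshold (3 robust SDs of the raw
trace's MAD, falling back to an absolute 5 pA on noiseless traces) on
a lightly smoothed trace, with two plausibility rules: a 10–90% rise
time of at most 5 ms and at least 3 ms spent above half amplitude —
a synaptic event outlives a noise excursion, and without the duration
rule a bare threshold yields hundreds of false positives over 30 s.

Amplitude distributions are compared with the two-sample KS test
(exact D from the sorted samples, asymptotic p) plus binned cumulative
and relative-frequency tables for plotting.

## Morphometrics and colocalization

Endpoint angles are planar (slice-plane) angles of endpoint-minus-soma,
0° along +x, counterclockwise; anatomical axes are a per-slice
rotation applied upstream. Endpoint distance defaults to path length
along the tree (matching "dendritic length"; Euclidean is an option).
The polar profile bins mean path length in 45° sectors and overlays a
von Mises kernel density (concentration 8, roughly a 23° bandwidth —
no kernel or bandwidth is published) normalized to integrate to 1 over
the circle. Ventral-root-projection (VRP) classification is a
rule-based stand-in for the visual call: any endpoint in the 90–135°
sector whose path length reaches the cell's 60th length percentile.

Sholl analysis is 2-D with exact segment–circle crossing counts
(verified against an arc-sampling oracle), critical value at the
smallest radius of maximal crossings, and ramification index =
maximal crossings / primary neurites.

One subtlety of the morphology generator: endpoint angles of a
*branched* tree are correlated through shared lineage, so the
Rayleigh uniformity check of the zero-concentration case is run on a
star topology (every endpoint its own primary), where the
independence assumption of the test holds.

Colocalization follows the object-based rule — a punctum counts as
colocalized when its centre lies inside (or on) a bouton polygon — and
reports both percentages. The perisomatic band ROI extends 2 µm out
and 1 µm in from the traced perimeter; its area is closed-form
(Steiner formula) for convex perimeters and grid-integrated otherwise,
and a perimeter thinner than the erosion collapses gracefully to
dilation-minus-original with a warning.

## Pipeline, sizes and determinism

`run_etype_pipeline()` chains simulate → features → cluster →
summarize, writing a feature table, the e-type model, a per-e-type
waveform aggregate and a provenance record (MD5 of the config, seed,
package version); outputs from different config hashes refuse to mix.
All generators are bit-reproducible under a fixed seed (local RNG
handling leaves the caller's stream untouched).

Default problem sizes are the study's own: 96 cells (24 per type) for
clustering, 50-cell cohorts for the subtraction pipeline, 20 cells for
waveform recovery, 500 replicates for the type-I calibrations.
Population sweeps are rendered at 10 kHz (the detector's resolution
floor is 0.1 ms) and single-cell waveform analyses at the full 50 kHz
of the recording protocol.

## Known limitations

* The archetype F–I parameters beyond the fast type, and all
  between-type contrasts, are calibrated — recovery results quantify
  the pipeline, not the separability of real Lamina VII neurons.
* AHP duration is occluded at high rates (the next spike arrives
  before recovery), so its estimator is only validated at moderate
  rates.
* The e-type/AP-type overlap percentages of the source study derive
  from its recordings and are not reproducible; the cross-tabulation
  is validated at the property level (planted template shapes are
  recovered perfectly).
* Sag/Ih, kinetic (time-constant) modeling of activation, quantal
  analysis and 3-D Sholl are out of scope.
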