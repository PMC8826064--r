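---
title: "Methods: behavioral states, call rates, and active space of female-calf pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral states, call rates, and active space of female-calf pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and numerical choices behind `pairspace`:
how tag records become per-bin movement metrics and behavioral states, how
vocal behavior is compared between states, how the acoustic active space of
each call is estimated, and what the synthetic generator does and does not
emulate.

## From tag records to movement metrics

A follow is divided into half-open 10-min bins `[start, start + 600 s)`
indexed from the follow start; an event exactly on a boundary belongs to the
later bin. Timestamps are plain seconds and positions local planar
easting/northing in km (y north): the analysis only ever uses differences,
so the epoch and datum are conventions, not parameters.

Positions at bin boundaries are linearly interpolated in time between the
bracketing fixes (whales are assumed to hold course and speed between
fixes, which arrive every few minutes). Per bin we compute:

* **speed** (km/h): straight-line displacement rate between boundary
  positions;
* **speed south** (km/h): the southward component; positive moving south,
  negative moving north, near zero when stationary or moving east-west.
  This is the migratory-progress axis for a southward migration;
* **course** (degrees clockwise from north) and **course deviation**: the
  circular absolute change in course from the previous bin, in [0°, 180°].
  Small values indicate directed travel; values near 90° and above indicate
  milling. The first bin of a tag has no previous course and is excluded.
  A zero-displacement bin has no defined course; we carry the previous
  course forward with deviation 0 rather than dropping the bin;
* **ESB count**: energetic surface behaviours (breaches, pectoral/fluke
  slaps) summed over the bin;
* **surface proportion** and **dive count** from the depth record (below).

Bins whose boundaries fall outside the fix record, or any bin missing a
metric, are flagged `excluded` and take no part in clustering.

## Dive segmentation

A *deep dive* is a maximal excursion of the depth trace below 10 m lasting
strictly longer than 75 s (both comparisons strict), the conventional rule
for separating true dives from incidental body movements near the surface.
Everything else is *surface interval*, so dives and surface intervals
partition the record exactly — the partition is what makes the surface
proportion well defined. Excursion boundaries are placed where the linearly
interpolated trace crosses 10 m, which makes durations independent of the
sampling phase; at 1 Hz the residual discretisation error is well under a
second. A dive belongs, for counting, to the bin containing its start; its
time in the water column is prorated across the bins it spans when
computing surface proportions. The segmenter is verified exactly against a
naive sample-by-sample oracle on a thousand random profiles.

## Behavioral states

The six metrics are centered and scaled to unit sample SD (centering does
not change k-means geometry, only the origin; scaling is what matters for
mixing km/h, degrees, counts and proportions in one Euclidean distance).

The number of clusters is chosen by a majority vote of four internal
validity indices computed over k = 2..8 — mean silhouette width,
Calinski-Harabasz pseudo-F, Davies-Bouldin (minimised), and the gap
statistic with the first-SE rule (50 bootstrap reference sets). Ties break
toward the smallest k, and all votes are reported so disagreement is
visible. A four-index vote was chosen over a larger consensus battery as a
reproducible core; on well-separated data the indices agree unanimously.

k-means uses Lloyd's algorithm with 25 seeded restarts (taking the best
inertia) and up to 100 iterations. For k = 2 the cluster with the lower
mean raw speed is labeled *resting/milling* and the other *travelling*;
labels are therefore invariant to cluster index permutation. For k ≠ 2 the
anonymous clusters are returned for the analyst to interpret.

Dive depth is a proxy for separation risk (calves surface alone while the
female is at depth), so we ask which adult-female dive parameters predict
the state of the bin in which the dive started: logistic mixed models
(random intercept per tag, Laplace ML so AIC is comparable across fixed
effects) over all non-empty subsets of {duration, mean depth, max depth},
ranked by AIC with Wald z p-values. Predictors are standardized internally
for numerical stability and coefficients mapped back to per-unit scale;
AIC and p-values are invariant to this. Near-separable data (a strong
duration effect makes quasi-separation common) fall back from adaptive
quadrature to `nAGQ = 0`, and a fit that still fails is flagged rather
than fatal.

## Vocal response

Call counts are modeled per bin, not per follow: a negative-binomial GLMM
with log link, the bin's duration in decimal hours as a log offset, and a
random intercept per tag. The quadratic parameterization
Var = μ + μ²/θ absorbs overdispersion and zero-heavy bins. Rates are
reported as least-squares means back-transformed to calls/h; the
travelling-vs-resting contrast is a log rate ratio with a Wald z test. The
offset construction is tested by algebra: doubling every exposure halves
every rate exactly and leaves the ratio unchanged. Calf rates carry an
`is_minimum` flag — the tag rides the female, so distant calf calls can be
missed and calf rates are lower bounds.

Received levels are analysed for adult-female calls only: the tag sits a
near-constant distance from the caller, so received level tracks source
level; for the calf, received level confounds source level with separation
distance. The model is a REML linear mixed model with a tag random
intercept. Contrasts use least-squares means with the multivariate-t
adjustment; with a two-level state factor there is a single contrast and
the adjustment is a no-op (asserted in tests). Because the residual df of
a REML LMM is not uniquely defined, the t reference uses n_tags − 1 df —
conservative for a between/within design of this shape.

## Active space

For each call, ambient noise is the power sum
10·log₁₀(Σ 10^(L_i/10)) of the third-octave band levels between 40 Hz and
2.5 kHz (the band holding nearly all call energy and the wind-noise peak),
taken from the most recent noise sample no older than the 600-s sampling
cadence; calls without a recent enough sample are excluded with a recorded
reason. SNR at the tag is RL − N, and a call is assumed just audible where
SNR = 0 (hearing thresholds for the species are unknown; 0 dB SNR is the
standard convention for this population).

Transmission loss in the octave band containing the call's peak frequency
is TL(x) = a + b·log₁₀(x) with two slopes: `b_near` out to a crossover
distance and `b_far` beyond, joined continuously (a discontinuous join
would make the inversion non-unique). The base-10 logarithm is the
dB-per-decade convention of underwater acoustics. The detection distance
solves RL − TL(d) − N = 0 in closed form on whichever piece contains the
solution; every non-floored estimate is verified by forward evaluation to
1e-6 dB. When the excess level cannot overcome TL at the 1-m reference
distance the estimate is floored at 1 m and flagged; floored estimates are
excluded from the state model by default (a config switch retains them).
Monotonicity — distance strictly increasing in RL, strictly decreasing in
N — follows from the closed form and is property-tested.

Caller depth is carried but unused: depth-resolved TL is not available, so
a `near_surface` flag (< 10 m) marks calls whose distances are likely
overestimated by ignoring surface-reflection (Lloyd mirror) interference.
State comparison of distances uses a gamma log-link mixed model (strictly
positive, right-skewed response) with a tag random intercept, fitted with
glmmTMB for robustness. The two-dimensional (RL × noise) smoother used in
the original spatial-surface visualisation is deliberately replaced by a
descriptive grid-binned median surface (`distance_surface_summary()`);
flexible 2-D smoothing is out of scope.

## The synthetic generator

`simulate_pair_dataset()` produces datasets with the statistical structure
the pipeline assumes. Defaults are the study conditions: 15 follows of
2–23 bins; a two-state Markov chain with stay probabilities (0.75, 0.86)
whose stationary distribution puts ≈ 36% of bins in resting/milling;
per-state speeds 1.7 ± 0.8 vs 4.6 ± 0.9 km/h; travelling headings normal
around 180° with 18.6° SD (giving a mean course deviation near 21°),
resting headings uniform (mean deviation near 90°); dive durations
414 ± 90 s vs 262 ± 50 s and dive rates 0.83 vs 1.79 per bin; ESB Poisson
means 0.30 vs 0.21; call rates 4.6 vs 1.6 calls/h (female) and 4.6 vs 1.9
(calf); received levels truncated normal within 124–172 (female) and
124–173 dB re 1 µPa (calf); peak frequencies drawn per state over the
octave bands with modes at 125 Hz (resting) and 500 Hz (travelling); and
wind noise a bounded random walk in 94–104 dB re 1 µPa. Dive depth
distributions do not differ between states, so duration is the planted
discriminating dive variable. Within-state SDs are not published (only SEs
of cluster means), so the SD defaults were fixed once at values giving
realistic within-state variability; they are not tuned per analysis.

Planted dive durations are defined as time below 10 m, so the
generator-segmenter round trip is exact up to sampling discretisation.
Calf depth traces are not generated: calf dive statistics feed no
inference here, matching the analysis design.

What the generator does **not** emulate: fix-error structure of theodolite
versus boat positions, tidal/current drift, behaviorally driven
non-stationarity within a state, call-type structure, depth-dependent
propagation, or vessel-noise masking. Passing recovery tests on this
generator therefore demonstrates correctness of the estimators under the
assumed data-generating process, not robustness to every property of real
recordings.

## Problem sizes and numerical conventions

The test-suite simulations use the design scale of the study — 15 tags,
~150–190 usable bins, 150–200 calls — with 20 seeds for clustering
recovery and 200 replicates for the rate-recovery and null-calibration
checks; these sizes give Monte-Carlo error comfortably below the asserted
margins. Numerical conventions collected in one place: strict `>`
comparisons in the dive rule; half-open bins with boundary events in the
later bin; k-means ties broken by lowest cluster index (via `stats::kmeans`);
cluster-count ties toward smallest k; TL inversion floored at 1 m and
flagged; third-octave bands outside 40–2500 Hz ignored in the power sum;
dive/surface tiling asserted to 1e-6 s; TL continuity to 1e-9 dB.

## Known limitations

Cluster labels are defined only for k = 2; a third state (e.g. socialising)
would need a new labeling rule. The NB quadratic parameterization is fixed
at fit time (exposed as the family argument if the linear form is ever
preferred). Detection distances share one depth-independent TL model, so
near-surface calls are optimistic; the `near_surface` flag supports
sensitivity analyses but no correction is applied. The bundled TL table is
synthetic — shaped like measured shallow-water coefficients and adequate
for testing the machinery, but not a substitute for site-specific
measurements when analysing real data.
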