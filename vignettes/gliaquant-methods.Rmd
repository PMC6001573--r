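---
title: "gliaquant: models, generators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gliaquant: models, generators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaquant)
```

# Scope and design

`gliaquant` re-implements, as one tested pipeline, the quantitative
analyses that characterise how microglia respond to a soluble modulator
such as nerve growth factor: time-lapse motility statistics, voltage-clamp
I/V and miniature-EPSC analysis, amyloid-β (Aβ) degradation/release
accounting over washout time courses, and the matrix-level statistics used
for expression and cytokine panels. Because the original recordings behind
such studies are rarely deposited, every analysis stage here is paired
with a synthetic-data generator that plants known ground truth; the test
suite asserts *properties* (oracle equivalence, conservation laws,
calibration, monotonicity) rather than reproducing headline numbers.

A green test therefore establishes that the pipeline recovers what was
planted under the stated synthetic world — it does not establish that any
biological effect size is correct, and the generators deliberately do not
model photorealistic microscopy, multi-channel fluorescence, drifting
ephys baselines beyond white noise, or mechanistic uptake/efflux ODEs.

# Time-lapse motility

## The three statistics

For each tracked cell with per-frame area $A_t$ (µm²), perimeter $p_t$
(µm) and centroid $\mathbf{c}_t$ (µm):

- **cell speed** $= \overline{\lVert \mathbf{c}_{t+1}-\mathbf{c}_t \rVert} / \Delta t$
  in µm/min, over consecutive frame pairs only;
- **membrane change** $\Delta A/p = \overline{\,|A_{t+1}-A_t| \,/\, \bar p_t\,}$
  with $\bar p_t = (p_t + p_{t+1})/2$, in µm. The absolute value is used
  because the statistic indexes exploratory membrane activity: signed
  changes would cancel over an extension/retraction cycle. The divisor is
  the mean of the two frames' perimeters because neither frame is
  privileged;
- **morphing speed** = state transitions per hour between the two
  morphological endpoints, *roundish* and *polarized*. A cell is polarized
  iff it has at least two ramifications; a single long protrusion is still
  roundish. An optional debounce (state must persist ≥ d frames; default
  d = 1, the raw count) absorbs single-frame flickers.

## Segmentation, tracking, classification

Segmentation is deliberately plain and pluggable: Gaussian smoothing
(σ = 1 px), Otsu global threshold, hole filling, 8-connected labelling,
minimum-area filter (50 px²). Perimeters are exposed-pixel-edge counts;
the same estimator is used for generator ground truth, so oracle
comparisons test the chain, not two perimeter conventions. Coordinates are
0-based (row, col) pixel indices; physical µm from the top-left pixel
centre.

Tracking is greedy nearest-centroid linking with a maximum step distance;
exact distance ties are broken by larger pixel overlap with the track's
previous mask, then lower track id, making results deterministic. A track
that finds no match ends (no gap bridging); short tracks are dropped.

Ramification counting skeletonises the mask (Zhang–Suen thinning) and
counts skeleton endpoints whose radial clearance beyond the maximal
inscribed soma disk (located by a chamfer distance transform) is at least
the minimum branch length (5 px, configurable). The radial clearance is a
lower bound on the branch's true path length and is robust to the
staircase artefacts of 8-connected skeletons, which defeat naive
endpoint-to-junction walks; endpoints closer than 3 px are merged (side
spurs at a branch tip).

Movies acquired at 1 frame / 30 s can be analysed at the coarser
1 frame/min cadence via `resample_to_1min` (every 2nd frame), matching the
common practice of acquiring faster than one analyses.

## The movie generator

Cells are rendered as a filled soma disk (radius ~7–9 px) plus 0–4
tapered branches; the polarized state is rendered with ≥ 2 branches and
roundish with ≤ 1, so shape-state ground truth is unambiguous. Dynamics
per frame:

- **translocation**: a confined random walk — fresh direction each frame,
  constrained to a per-cell territory. The planted *step length* (and
  hence the speed statistic) is exact, while territories guarantee that
  cells can never overlap for any duration. Placement is rejection
  sampling with a minimum separation; an impossible request raises a
  sizing error.
- **membrane dynamics**: stochastic soma-radius fluctuation
  $r_t = r_0 + a\,\varepsilon_t$, $\varepsilon_t \sim U(-1,1)$. For a
  disk, $\Delta A/p \approx (2\pi/8)\,|\Delta r|$ under the edge-count
  perimeter, giving the analytic starting point
  $a \approx 1.9\,\cdot$ target / pixel size; a closed loop then
  re-renders and rescales $a$ until the realised mean ΔA/p on the true
  masks is within a few percent of the requested
  `membrane_change_rate`. Radius fluctuation is radially symmetric, so
  membrane activity is decoupled from centroid speed by construction —
  the property the dissociation acceptance test exercises.
- **morphing**: per-frame Bernoulli switches with probability
  `morph_transition_prob`; each switch redraws the branch set for the new
  state.

All randomness is drawn up front from one seeded stream (rendering and
calibration are deterministic), so identical spec + seed gives
bit-identical movies, and the caller's RNG state is restored.

Stated-world defaults: 29 cells per experiment, 1 h at 1 frame / 30 s,
40× objective scale (0.4 µm/px). Field size and cell density are not
published for such acquisitions; the 768² px default field was chosen
once to hold 29 non-overlapping territories at realistic density and is
configurable, not inferred.

# Voltage-clamp analysis

## Step protocol and I/V

The default protocol holds at −20 mV and steps from −140 to +60 mV in
20 mV increments, 250 ms per step, 5 s apart (the microglia protocol;
−70 mV holding is used for neurons). Step currents are the mean over the
**last two-thirds** of the step, excluding the first third so capacitive
transients (time constant τ) decay away; the window-robustness test
verifies < 1 % contamination for τ up to a tenth of the excluded third.

Difference curves are pointwise after − before on identical voltage
grids. The reversal potential is the linearly interpolated zero crossing
of the bracketing grid interval; with several crossings the one nearest
0 mV is reported and flagged ambiguous, and a curve with no sign change
raises an explicit no-reversal error. Linear interpolation across a
20 mV grid interval that contains a rectification kink biases the
estimate by up to ~1.5 mV at gain 1.3 — within the ±2 mV acceptance band
and the price of the simple estimator; fitting the two limbs separately
was deliberately left out of scope.

The sweep generator plants two linear conductances (leak and added) plus
an exponential capacitive transient; the added conductance can be
outward-rectifying (gain factor above its reversal), emulating an
agonist-activated outward slightly-rectifying current reversing near
+15 mV.

## mEPSC detection

Events are inward (negative) deflections on a −70 mV recording; the
detector reports positive magnitudes. The baseline is a rolling median
(200 ms window), robust to event density. The noise SD is estimated from
the lowest-variance half of 50 ms windows (median of their SDs), which
slightly underestimates pure noise (~2 %) but is insensitive to events
occupying a minority of windows.

Thresholds follow the conventional noise-scaled rule: amplitude
≥ k·SD **and** area ≥ k·SD·w, with k ∈ [3, 4] and a nominal event width
w = 10 ms giving the area threshold its pA·ms dimension. AND is the
conservative combination of the two listed thresholds; OR is available.
Candidate windows are extended to their surrounding zero crossings;
events riding on a previous event's decay are split at valleys between
above-threshold peaks (peaks must be separated by the refractory window,
5 ms, and by a valley ≥ 2 SD below both flanking peaks) — without this,
sensitivity at 5.5 Hz saturates near 93 % because ~7 % of Poisson events
arrive within a decay time of their predecessor. Peak amplitudes are read
off a lightly smoothed trace (0.5 ms boxcar, emulating the usual 1 kHz
analysis bandwidth), which removes most of the positive bias that raw
noise maxima add to peak estimates. A riding event's amplitude is
measured from the common baseline, not the local tail, overestimating it
by the residual decay; at physiological rates this affects a few percent
of events.

Recordings are gated by the standard series-resistance rule: discard when
Rs deviates more than 25 % from its initial value at any point.

The mEPSC generator plants biexponential events (τ_rise 0.5 ms, τ_decay
5 ms, unit-peak normalised) at Poisson times; overlaps sum linearly,
which is physically standard and deliberately stresses the detector.
Stated-world defaults are the baseline condition of such recordings:
5.5 Hz, 20.45 pA mean amplitude (lognormal, CV 0.3), 2 pA noise, 10 kHz
digitisation.

# Aβ uptake/degradation accounting

A washout time course measures the internal (immunoblot, normalised to a
housekeeping protein) and supernatant (ELISA) Aβ levels at each time
point (defaults: 3 h uptake, then +5, +9, +21 h washout). Between
adjacent time points, internal decrease = digested + released. The two
compartments are measured in incommensurate units; a calibration factor
is an explicit optional input. With calibration, the digested amount is
the internal delta minus the internal-equivalent release and the
noise-free accounting conserves mass to machine precision; without it,
the plain internal delta is reported as "digested" (the conventional
reading) and release stays in its own units. Deltas are computed per
replicate and then compared across replicates — never deltas of replicate
averages — preserving the pairing of the parallel-experiment design.
Negative deltas under noise are preserved and flagged, never clipped,
because clipping would bias cumulative digestion upward.

# Matrix statistics

- **Flag filtering**: the default drops a feature flagged below
  background in *any* sample — the strictest reading of a
  flag-filtering rule; per-"all" and majority policies are selectable.
- **Upper-quartile normalisation**: each sample is scaled so its 75th
  percentile (linear interpolation between order statistics, R type 7 —
  pinned for bit-reproducibility) equals the geometric mean of the
  pre-scaling percentiles. This makes the operation idempotent and
  symmetric across samples.
- **DEG selection**: log2 fold change between group means of log2
  intensities, gated at |log2FC| > 1, combined with a moderated t
  statistic whose per-feature pooled variance is shrunk toward the mean
  feature variance with a fixed weight (default 0.5; weight 0 is the
  ordinary t test and is what the type-I calibration test runs). Full
  empirical-Bayes hyperparameter estimation is out of scope: the
  fold-change gate dominates selection in practice, and the fixed-weight
  form keeps the weight-0 calibration exact. No multiple-testing
  correction is applied to the DEG p values (raw p < .05 with the FC
  gate).
- **PCA**: samples are observations, features variables, centred;
  covariance PCA by default (feature scaling optional — whether
  correlation or covariance PCA was used for such cytokine panels is
  typically unstated, and covariance preserves the dominance of
  high-abundance cytokines). POV per component sums to 1; each
  component's sign is fixed so its largest-magnitude loading is positive.
- **Group tests**: unpaired/paired t, one-way ANOVA with post-hoc
  Bonferroni-corrected pairwise t tests (pairwise p × number of
  comparisons, capped at 1), two-sample Kolmogorov–Smirnov. A paired test
  with zero-variance differences returns a degenerate flag instead of a
  spurious p value.

The cytokine-panel generator (`cytokine_panel_spec()`) encodes the
qualitative anti-inflammatory structure used by the PCA separation test:
an inflammatory feature subset raised several-fold by amyloid, mildly
lowered by the modulator alone, and returned to baseline under
amyloid + modulator, with two replicates of four treatments.

# Numerical and engineering choices

- Degenerate inputs: near-constant images segment to an empty labelling
  with a warning (not an error); empty traces error; constant traces give
  an empty event list; rank-0 matrices error in PCA.
- Otsu thresholding guards against floating-point ripple on constant
  images (range below 1e−12 is treated as empty).
- Binary-morphology primitives (labelling, hole filling, thinning,
  chamfer distance) are small Rcpp kernels; everything else is vectorised
  R.
- On-disk formats are plain text only (CSV/TSV/JSON): per-frame CSV plus
  a JSON sidecar for movies, long CSV plus a JSON protocol for sweep
  sets, TSV triplets for assay matrices. Configs for the CLI are JSON.
- Seeds: every generator takes an explicit integer seed, uses one local
  stream, and restores the caller's RNG state.

# Known limitations

- The rendered cells are schematic (disk + straight tapered branches);
  segmentation difficulty is far below that of real phase-contrast or
  fluorescence microglia, so segmentation accuracy results do not
  transfer to real movies.
- The reversal-potential estimator inherits up to ~1.5 mV bias from
  interpolating across a rectification kink (see above).
- The moderated t uses a fixed shrinkage weight, not estimated prior
  degrees of freedom; its p values are exactly calibrated only at
  weight 0.
- Tracking assumes cells neither divide, merge, nor leave the field;
  mitosis/merge handling and sub-pixel boundary estimation are
  out of scope.
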