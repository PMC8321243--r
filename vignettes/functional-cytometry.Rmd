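---
title: "Functional cytometry from time-lapse fluorescence imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional cytometry from time-lapse fluorescence imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcyto)
```

## The problem

Flow cytometry profiles thousands of cells but destroys their tissue
context and reads structure (surface proteins), not function.  Real-time
imaging of a second-messenger reporter — here FRET-based PKA-activity or
single-fluorophore cAMP sensors expressed in intact pancreatic islets —
reads function directly: each cell's reversible response to a sequence of
bath-applied agents (incretins at several doses, adrenaline as an
α-/β-cell marker compound, forskolin + IBMX as a positive control).  The
price is a long recording in which slow photobleaching drift, heterogeneous
sensor expression, and photon noise sit on top of the responses of
interest.  `funcyto` turns such a recording into a cells × conditions
*effect table* and profiles the population from it.

The pipeline is: detect cells on the time-averaged acceptor image → extract
per-ROI intensity traces → ratio the channels → normalize each cell to its
initial level → estimate and subtract a per-cell baseline anchored on the
agent-free (basal) episodes → fit a response amplitude per cell and agent →
rank, split, correlate and cluster the cells.

## ROI detection

Cells are detected on the average-intensity projection of the acceptor
(YFP) channel, which is the brighter of the FRET pair and perfectly
colocalized with the donor.  Detection is (i) local maxima — a pixel not
below any 8-neighbour and above at least one, standing at least
`prominence` above the image floor — followed by (ii) an 8-connected flood
fill down to `seed − tolerance`.  Maxima falling inside an already-claimed
region are merged into it (claims go to the higher maximum, processed
first), which also resolves plateau ties.  Regions whose equivalent
circular diameter, `2·sqrt(area/π)·pixel_size`, exceeds 30 µm are removed
as artefacts; the size filter is a strict post-filter and never splits or
merges regions.  No smoothing is applied before maxima detection: the
projection already averages all frames, and smoothing would bias centroids
of closely spaced cells.

Channel alignment is provided as an optional integer-pixel shift
maximizing the Pearson correlation of the two projections (ties broken
toward the smaller shift).  Sub-pixel warping and motion registration are
out of scope; the ratio is computed per ROI, not per pixel, precisely to
tolerate small residual misalignment.

## Ratio, normalization, and the basal anchor

With `I_A`, `I_D` the per-ROI acceptor and donor traces, the raw signal is
`R = I_A / I_D` and the working signal is `R/R₀`, where `R₀` is the mean of
each cell's first five timepoints.  This removes the per-cell expression
and optical-path nuisance exactly: rescaling both channels of a cell by a
common factor leaves `R/R₀` unchanged (a tested invariant).  Cells whose
initial mean is not positive cannot be normalized and are dropped with a
warning, never imputed.

The schedule of agent applications is a list of half-open, 0-based frame
intervals `[start, end)`; its complement defines the *basal regions*.  The
central assumption of the whole framework is that **every return to basal
conditions restores the initial analyte level**, so the basal samples of a
cell are repeated observations of pure drift.  Schedules must leave at
least one basal frame before the first and after the last condition.

## Baseline models

An individual baseline trace is fitted per cell, using *only* basal-frame
data (a tested invariant: permuting values inside condition intervals does
not change the fit):

* **linear**, **exponential** (`a·exp(b·t) + c`, Levenberg–Marquardt,
  initialized from the log-ratio of the first/last basal means): anchored
  on the first and last basal regions only.  Cheap, but blind to mid-run
  curvature; an exponential fit that fails falls back to linear and is
  flagged.
* **spline**: natural cubic spline interpolating the per-region basal
  means (a smoothing spline through all basal points is available as
  `spline_all_points = TRUE`; interpolating every noisy basal sample would
  reproduce noise, not drift).
* **polynomial**: least-squares polynomial over all basal data with degree
  equal to the number of basal regions minus one — one degree of freedom
  per anchor.
* **piecewise_linear / piecewise_square**: each basal region gets its own
  least-squares line; each condition interval gets a line (or one-sided
  quadratic) fitted to the two nearest basal regions, preceding and
  succeeding.  The first and last frame of each condition segment are
  averaged with the adjoining basal fits so the assembled baseline is
  continuous — without this, segment joins produce step artefacts that
  masquerade as effects.

Correction is subtraction re-anchored at the basal level:
`corrected = R/R₀ − baseline + 1`, so amplitudes read as deviations from 1.
Piecewise-linear correction removes any drift that is linear between
neighbouring basal anchors exactly, and is the routine default.

Two consequences of this design are worth knowing.  First, subtraction
does not undo the *multiplicative* nature of bleaching: a response of
fractional size `a` riding on a ratio that has bleached to a fraction
`D(t)` of its initial value survives correction with amplitude `a·D(t)`,
i.e. late responses are attenuated by however much differential bleaching
the recording accumulated.  Second, incomplete washout leaks the tail of
the previous response into the following basal region and tilts its local
fit slightly.  Both effects are small for realistic settings but set the
accuracy floor of amplitude recovery (a few percent of the amplitude).

## Signal-to-noise benchmark

The SNR of a matrix is computed per cell as the absolute difference
between the mean over the reference condition's plateau (its last half,
avoiding onset kinetics) and the mean over the immediately preceding basal
region, divided by a **pooled noise floor**: the SD of all basal-frame
values around their grand mean across cells.  The pooling is deliberate: a
fully per-cell SNR is invariant under per-cell normalization (numerator and
denominator scale together), and could not distinguish raw from normalized
data at all.  The population noise floor instead penalizes cell-to-cell
scatter (removed by normalization) and residual drift (removed by
correction), which is exactly the ordering the benchmark is meant to
expose.  The reference condition defaults to the largest response — the
forskolin + IBMX positive control.  Values are reported in arbitrary units
as mean ± SEM over cells.

## Effect quantification

For each condition, the preceding basal region is expanded by the first 20
post-addition timepoints (clipped at the next condition), so each region
holds both basal and treated data.  Estimators, all sharing the sign
convention *positive = increase upon addition*:

* **two_region** — mean of condition frames minus mean of basal frames;
  the bona fide reference, exact on ideal steps.
* **linear** — least-squares slope over the region × region span; the
  stable routine default.
* **square** — one-sided quadratic ramp `base + c·u²` (`u` = frames since
  addition), amplitude `c·u_end²`.  A full-region quadratic read out as
  end-minus-start is *not* used: its quadratic component is even about the
  region's time centre, cancels in end-minus-start, and provably collapses
  onto the linear estimate.  The one-sided ramp is the member of the
  onset-shaped family (with sigmoid and Hill) with forced-zero curvature
  before addition, and inherits the extrapolation artefacts such fits are
  known for.
* **end_start** — last minus first frame after a 3-frame moving average
  (window configurable).  Cheap, but a single contaminated end frame —
  e.g. residual relaxation from the previous agent at the region start —
  lands directly in the estimate.
* **sigmoid** — `base + A/(1 + exp(−(t − t½)/τ))`, amplitude `A`, with
  `t½` and `τ` bounded inside the region, initialized from the two-region
  estimate (`t½` at addition + 5 frames, `τ` = 3 frames).
* **hill** — `base + A·uʰ/(kʰ + uʰ)` for `u = max(t − t₀, 0)`, `t₀` fixed
  at the addition frame.  The reported amplitude is the fitted realized
  change at the region end, `A·u_endʰ/(kʰ + u_endʰ)`, not the asymptote
  `A`: when the half-saturation `k` runs toward the window end, `A` and
  `k` trade off and the asymptote is unidentified while the realized
  change remains stable.

Transcendental amplitudes are bounded to |A| ≤ 5 (a five-fold fractional
ratio change is beyond any of the sensors emulated here); fits that fail
or do not converge fall back to the linear estimate and are *flagged*,
never silently zeroed or hidden.  `compare_methods_rms()` benchmarks the
single-region estimators against the two-region reference as the RMS of
their difference over all converged (cell, condition) pairs, excluded
pairwise.

## Population profiling and clustering

The sorting statistic over a 10 + 10 frame window around an addition is
`S = sign(mean − 1) · SD`: responders both move the window mean off the
basal level and inflate its variance, so ranking by `S` orders cells by
signed response strength.  The statistic is per *cell* (cells are matrix
columns; the interval selection is over rows).  Cells are split into
`alpha_like` / `beta_like` by the sign of the marker-compound (adrenaline)
amplitude against a configurable threshold (default 0), and per-class
Pearson correlations between condition pairs are computed with two-sided
p-values (unadjusted by default; Benjamini–Hochberg optional) and
least-squares lines.

Clustering standardizes the effect table per condition (z-score), which
makes assignments invariant to per-condition affine rescaling and column
order.  k-means uses 25 random restarts per k plus a warm start from the
previous k's solution (previous centres + the worst-fitted point), which
guarantees a monotone non-increasing within-SS curve.  The elbow is
formalized as the k maximizing the second difference of that curve over
k = 1…10.  Hierarchical clustering is Ward (`ward.D2`) on Euclidean
distances of the standardized profiles, for cells or for conditions;
condition dendrograms are exportable as Newick text.  PCA contributions
are squared loadings per component as percentages (summing to 100);
zero-variance conditions are excluded with a warning.

## The synthetic-data generator

No recordings are distributed with the package, so the generator is the
test bed.  It emulates, per cell: a log-normal sensor-expression scale
(common to both channels), a log-normal resting acceptor/donor ratio,
reversible responses with saturating-exponential onset
(`1 − exp(−k/onset_tau)`) and exponential relaxation after removal, and —
per channel — multiplicative monotone bleaching (linear or exponential,
different rates per channel) plus additive Gaussian noise on the raw
intensity scale.  The response is split between the channels as
`sqrt(r)` up / `1/sqrt(r)` down, so the channels move oppositely as in a
FRET pair while their ratio carries exactly the planted curve.  With
drift and noise off, the pipeline is exactly invertible (a tested
invariant).

The canonical study conditions, used by the test suite and the acceptance
script, are chosen to emulate the kind of recording the method targets:

* 600 frames at 60 s (a 10-hour automated run), eight agents applied for
  20 frames each, separated by 50-frame basal regions (40-frame lead-in);
* `onset_tau` = 1 frame — cAMP/PKA responses at 60-s sampling rise within
  a frame or two;
* `relax_tau` = 3 frames — washout takes minutes, so basal regions carry a
  decaying remnant of the previous response (deliberately: it is the main
  realistic stressor of the basal-anchor assumption);
* bleaching rates −6·10⁻⁴ (donor) and −7.5·10⁻⁴ (acceptor) per frame:
  ≈ 30 % and 36 % channel loss over the run, i.e. ≈ 9 % residual drift in
  the ratio;
* additive noise SD 0.03 on channel intensities of order 1;
* response amplitudes uniform in [−0.5, +0.8]; marker (adrenaline)
  responses of magnitude 0.2–0.6, positive in a 25 % subpopulation;
  latent-factor amplitudes truncated at −0.9 (a response cannot drive a
  ratio below zero).

What the generator does **not** emulate: tissue motion, out-of-focus
light, FRET photophysics beyond channel-wise bleaching, shot-noise
scaling with intensity, or spatially correlated noise.  Passing tests on
this generator therefore demonstrate the correctness and calibration of
the *algorithms* under the stated statistical structure, not performance
on any particular microscope.

## Numerical choices

* Frames are 0-based and intervals half-open, matching array slicing;
  second-based schedule entries convert with round-to-nearest.
* Levenberg–Marquardt fits: tolerance 1e-8 and 200 iterations for the
  exponential baseline; 500 iterations for sigmoid/Hill.
* Degenerate inputs have defined behaviour: an all-flat image yields an
  empty ROI set; a zero basal SD excludes the cell (counted) from SNR; an
  all-identical effect table forces k = 1 with a warning; a zero-variance
  condition is excluded from PCA and correlations report `NA`.
* The elbow needs at least three scanned k values; with fewer, the largest
  k is returned.
* Ties in the cell ranking keep the original order (stable sort).

## Limitations

* Subtractive baseline correction attenuates late-run amplitudes by the
  accumulated differential-bleach factor (see above); a divisive variant
  is deliberately not offered to keep amplitudes on the additive scale the
  downstream statistics assume.
* Endpoint-anchored baselines (linear, exponential) can be beaten by a
  constant fit on mid-run basal regions they never see; the residual-SS
  guarantee holds on the regions they are anchored to.
* ROI detection assumes roughly isotropic, non-touching cells; touching
  cells separated by a saddle shallower than the tolerance merge.
* Dose–response (EC50) fitting across concentrations is out of scope —
  each concentration is a separate condition, as in the experimental
  design the package mirrors.
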