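# funcyto — functional cytometry of time-lapse fluorescence imaging

`funcyto` profiles heterogeneous cell populations in intact tissue from
time-lapse fluorescence recordings under sequential pharmacology.  The
motivating application is pancreatic islets of Langerhans expressing a
FRET-based PKA-activity sensor (or a single-fluorophore cAMP sensor),
perifused with a sequence of agents — incretins (GLP-1, GIP) at several
doses, adrenaline as an α-/β-cell *marker compound*, forskolin + IBMX as a
positive control — while two emission channels are imaged every minute for
hours.  Each cell's reversible response to every agent becomes one row of a
cells × conditions **effect table**, which is then mined like a cytometry
dataset: ranking, marker-based splitting, per-class correlations, k-means
and Ward clustering, PCA.

## The method

For ROIs detected as intensity maxima + flood fill on the average
projection of the acceptor channel (objects > 30 µm excluded as
artefacts), per-ROI mean-intensity traces give the ratio and its
normalization

    R = I_YFP / I_CFP,        R/R0,   R0 = mean of each cell's first 5 timepoints

Recurrent returns to agent-free conditions (*t_basal* regions) are assumed
to restore the basal analyte level, so basal frames sample pure
photobleaching drift.  A per-cell baseline is fitted to basal data only —
linear, exponential, interpolating spline, polynomial of degree
(#basal regions − 1), or piecewise linear/quadratic between neighbouring
basal anchors — and subtracted, re-anchoring the basal level at 1.  Agent
effects are then quantified per cell within basal regions expanded by 20
post-addition timepoints, either as the two-region reference
(mean-after − mean-before) or with single-region fits (linear, one-sided
quadratic, smoothed end−start, logistic, Hill).  A sorting statistic
`S = sign(mean − 1)·SD` over a 10 + 10 frame window around an addition
ranks responders, and the sign of the adrenaline effect splits α-like from
β-like cells.

A seeded synthetic-data generator (per-cell expression scaling,
channel-wise bleaching, saturating onset / exponential relaxation
kinetics, additive noise, planted subpopulations) makes every stage
testable without recorded data.

## Worked example

```r
library(funcyto)

labels <- c("GLP-1 @ 1 pM", "GLP-1 @ 100 pM", "GIP @ 100 pM",
            "adrenaline @ 10 uM", "forskolin+IBMX")
starts <- 40 + (seq_along(labels) - 1) * 70
sched <- timestamp_schedule(labels, starts, starts + 20,
                            70 * length(labels) + 40, 60)

cells <- random_cells(50, labels, marker_label = "adrenaline @ 10 uM", seed = 1)
sim <- simulate_traces(cells, sched,
                       drift_spec("exponential", c(-6e-4, -7.5e-4), 0.03),
                       seed = 2)

ratio     <- compute_ratio(sim$acceptor, sim$donor)
nrm       <- normalize_to_initial(ratio)
bl        <- fit_baseline(nrm, sched, "piecewise_linear")
corrected <- subtract_baseline(nrm, bl)
bl
#> Baseline model 'piecewise_linear': 50 cells, 390 frames
#>   median basal RSS 1.085; 0 fallback cell(s)

eff <- quantify_effects(corrected, sched, "linear")
eff
#> Effect table [linear]: 50 cells x 5 conditions, 0 flagged
#>           GLP-1 @ 1 pM GLP-1 @ 100 pM GIP @ 100 pM adrenaline @ 10 uM ...
#> cell_0001   -0.1827162      0.5785081   0.39159539         -0.5106238
#> cell_0002   -0.2752037      0.7904292  -0.43302951         -0.5273030
```

Amplitudes are fractional changes of the corrected `R/R0`: `+0.58` means a
58 % ratio rise upon GLP-1, `−0.51` a fall upon adrenaline (a β-like
cell).  Correction is what makes the responses legible:

```r
snr_table(list(raw = ratio, normalized = nrm, corrected = corrected),
          sched, "forskolin+IBMX")
#>    procedure snr_mean   snr_sem  n
#> 1        raw 1.719139 0.1724483 50
#> 2 normalized 4.615926 0.4191296 50
#> 3  corrected 5.447348 0.4983829 50

split <- split_population(eff, "adrenaline @ 10 uM")
table(split)
#> alpha_like  beta_like
#>         15         35
```

Against the generator's ground truth this split is 100 % accurate and the
linear-method amplitudes recover the planted values with RMSE 0.06.
Downstream, `sorting_statistic()` / `rank_cells()` order the heat map,
`effect_correlations()` computes per-class Pearson r between condition
pairs, and `kmeans_profile()` / `hierarchical_profile()` /
`pca_contributions()` discover functional subpopulations and related
stimuli.

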