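---
title: "Estimating grass canopy height from before/after-harvest point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating grass canopy height from before/after-harvest point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Sward height is a standard indicator of grass growth, conventionally
measured by probing the canopy with a ruler — accurate but far too slow for
dense spatial coverage. Remote alternatives reconstruct the field as a 3D
point cloud, either photogrammetrically (structure from motion, SfM, from
UAV or pole-mounted cameras) or with a laser scanner (LiDAR), and estimate
height as the difference between a canopy surface and a ground surface.

This package implements and evaluates the *harvest-differencing* design:
the same plot is scanned **before** and **after** cutting the grass to a
fixed stubble (3 cm), each cloud is rasterized to a digital surface model
(DSM), and canopy height is the cellwise DSM difference. Because the
"ground" epoch is a real measurement of the same plot, no terrain
classification or interpolation is required. The scientific questions are
methodological:

1. **Which per-cell height selection rule** should convert the points of a
   cell into its DSM value? Four rules pair the two epochs' aggregates:
   maximum−maximum (`maximum`), mean−mean (`average`), minimum−minimum
   (`minimum`) and maximum−minimum (`maximum_minimum`, i.e. leaf-tip
   surface minus ground surface).
2. **Which DSM resolution** (cell sizes 5–100 mm) minimises error, and how
   does the optimum depend on the sensor?
3. **How do the sensors compare** at their respective best settings?

Estimates are summarised per subplot — a 2.5 m plot split into 25 subplots
of 0.5 m — as the mean of cell values whose centers fall in the central
0.3 m comparison window (edges are excluded because lodged grass leans
across subplot borders), and scored against ruler truth as the mean ±
standard deviation of per-subplot absolute errors (MAE ± SD, in mm).

The field data behind the original study are not deposited, so the package
ships a synthetic scene and sensor simulator with known truth. Every
pipeline stage is format-driven (CSV/PLY/LAS clouds, ESRI ASCII / TIFF
DSMs), so the same functions run unchanged on real clouds.

## The synthetic scene

A scene is a smooth, almost-flat ground elevation field plus a population
of grass blades:

* **Ground**: a stationary Gaussian random field, relief sd 10 mm,
  correlation length 1 m — a levelled but not perfectly planar paddock.
* **Blades**: placed uniformly, default 1500 per m², 10 mm wide (an
  Italian-ryegrass-like sward). Tip heights above local ground are
  marginally lognormal per subplot. Subplot means are themselves drawn
  lognormally (default mean 400 mm, between-subplot CV 0.25 — swards vary
  far more from patch to patch than within half a metre), and the
  within-subplot CV defaults to 0.08. Within a subplot, heights are
  spatially coherent: a Gaussian-copula random field (correlation length
  0.15 m, 20 % independent nugget) correlates neighbouring blades. Purely
  independent tips would make every per-cell maximum an order statistic of
  the full subplot spread, which is not how a sward behaves and distorts
  the resolution sweep.
* **Harvest** replaces every tip height with the 30 mm stubble; blade
  count and positions are untouched.
* **Ruler truth** probes 5 random blades per subplot and averages their
  tip heights, mimicking the field protocol (a single operator probing
  each 0.5 m subplot five times).

## The sensor models

The simulator's purpose is to reproduce the *mechanisms* that separate the
sensors, not their exact noise magnitudes (which the study does not
report). Point densities are the study's values — 789 (UAV-SfM), 269
(pole-SfM) and 9 (LiDAR) points/cm² — jointly reduced by a `scale` factor
that preserves their ratio.

**SfM** reconstructs a *surface*, not individual leaves. The sampler
evaluates the canopy upper envelope (tallest blade tip within a 25 mm
radius) and subtracts a reconstruction depth: swaying grass is
under-resolved, so points sit below the instantaneous tips by a
height-proportional sway depth (default fraction 0.12 of local canopy
height, varying spatially with sd 0.04 over ~0.3 m — gusts and the UAV
downdraft are patchy) plus an exponential sag tail (mean fraction 0.10)
that occasionally reaches deep into the canopy. Vertical noise is a
spatially *correlated* field (marginal sd 15 mm for UAV, 8 mm for the pole
camera, correlation length 40 mm): SfM error is a coherent undulation of
the reconstructed surface, and modelling it as white noise would let
per-cell extremes grow without bound as density rises. The ground is
photogrammetrically visible with probability 0 before harvest (closed
canopy) and 0.1 after (stubble mostly occludes it).

**LiDAR** shoots beams with the study's 31.8 × 20.0 mm footprint. Within
an interception window (footprint inflated by a 30 mm leaf reach — leaning
blades intercept beams away from their base) the local leaf area gives a
cover fraction `1 − exp(−path_factor × LAI)` with `path_factor = 1.5` for
the oblique (~20°) beam path. With that probability the return is the leaf
surface: the window-mean tip elevation — the smooth surface that averaging
`n_revisits = 5` evaluations of a moving canopy reconstructs — minus an
exponential first-return penetration depth (mean 20 mm) for beams that
reflect off lower leaf material. Otherwise the beam passes between the
leaves and returns the ground. Ranging noise is 4.5 mm per evaluation,
~2 mm after revisit averaging. Before harvest the canopy intercepts nearly
every beam; after harvest roughly half the beams reach the ground, which
is exactly the asymmetry that makes the maximum−minimum rule work so well
for this sensor.

These defaults are stated assumptions, chosen once for physical
plausibility; they are configuration, not constants.

## What the simulation does and does not show

With these mechanisms the package reproduces, on replicated synthetic
scenes, the qualitative structure of the study's findings: the
maximum−minimum rule attains the lowest MAE for every sensor; the SfM
models prefer coarse DSMs (50–100 mm) while LiDAR has an interior optimum
near 20–30 mm that degrades in *both* directions; the average rule is
nearly flat in resolution; and the LiDAR error is roughly half the SfM
error, with estimate–truth correlations above 0.95. The absolute error
levels also land near the study's (≈10–19 mm vs 12–27 mm), but that
agreement is partly fortuitous: real SfM error depends on texture, wind,
camera quality and bundle-adjustment behaviour that a sampling model does
not capture. Passing tests demonstrate that the *pipeline and its
comparative conclusions* are correct under a faithful mechanism model —
not that any particular field deployment will achieve these numbers.

## Numerical and design choices

* **Binning** is half-open, `[lo, hi)`, origin at the plot's minimum
  corner; boundary points belong to the +x/+y cell. Empty cells are
  nodata and are never interpolated — interpolation would blur exactly
  the method contrast under study.
* **Differencing** requires bit-identical grids and the matching
  aggregator pair; masks propagate (no estimate where either epoch is
  empty). Negative differences are retained and counted; clipping would
  bias the minimum-based rules asymmetrically.
* **Subplot reduction** is the arithmetic mean of crop-window cell values
  (cell-center membership, half-open on the crop boundary). Subplots with
  no valid cell are excluded and flagged.
* The 30 mm stubble is **not** added back: the estimate is the raw DSM
  difference, matching the study's comparison of raw differences against
  ruler height. The resulting ~−30 mm component for same-aggregator
  methods is part of what the evaluation measures.
* **MAE ± SD** uses the sample standard deviation of per-subplot absolute
  errors. Sensor comparison selects each sensor's error-minimising
  (method, cell size) — ties favour the larger cell, which has fewer
  empty cells — then applies one-way ANOVA with Tukey's HSD (α = 0.01) to
  the per-subplot absolute errors, via `stats::aov()`/`stats::TukeyHSD()`.
* **Qualitative conclusions use replicates**: 5 independent scenes,
  compared on replicate-mean MAE; single-scene reversals of close
  orderings are expected and tolerated.
* **Random streams** are split per subsystem (ground, canopy, ruler, each
  sampler, each epoch), so changing one stage's draws never perturbs
  another's.
* **Problem sizes**: tests and the acceptance script run the replicated
  evaluation at `scale = 0.1` (about 4.9 M UAV points per epoch and ~3.6
  LiDAR points per 20 mm cell). Below a few LiDAR points per cell the
  four selection rules collapse to the same single-point estimator, so
  very small scales cannot express the method contrasts; 0.1 is the
  package's chosen compromise between fidelity and desk-scale runtime.
  The interactive pipeline default is `scale = 0.01`.

## Known limitations

* The SfM model samples a surface process; it cannot produce the
  gross reconstruction failures (holes, doubled surfaces) real
  photogrammetry sometimes does.
* Wind is represented as static sway depth and noise fields, not a
  time-resolved motion model.
* Harvest is geometrically perfect (every blade exactly at stubble
  height); real mowing unevenness would raise the after-harvest maximum
  surface and further penalise the maximum rule.
* The TIFF DSM writer stores sample values only (fixed affine height
  encoding, nodata at 0); grid geometry travels in the ESRI ASCII format
  or as reader arguments, since the package works in a local plot frame
  and deliberately does no CRS handling.

## A minimal run

```{r, eval = FALSE}
library(canopyheight)

sim <- simulate_study(scale = 0.05, seed = 1)
sweep <- run_sweep(sim$clouds, sim$layout, sim$truth)
summarize_sweep(sweep)

cmp <- compare_sensors(sweep)
glance(cmp)          # best method + cell size, MAE ± SD, Pearson r per sensor
tidy(cmp)            # Tukey HSD pairs
plot_error_sweep(summarize_sweep(sweep))
```
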