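---
title: "Quantifying post-infarction scar remodeling: models, estimators and design choices"
author: "epiScarMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying post-infarction scar remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiScarMap)
```

# Scope

epiScarMap implements the quantification chain of a two-arm porcine
post-infarction imaging study: late gadolinium enhancement (LGE) CMR scar
compartmentalization into endocardial/epicardial half-wall surface maps,
epicardial optical-mapping electrophysiology (activation, APD80,
conduction velocity), endocardial electroanatomic voltage-map scar areas,
semi-quantitative histology scoring, and exact nonparametric group
comparisons. Because no raw animal data are distributed, every stage is
exercised against a bundled synthetic-data generator whose ground truth
is known in closed form; this vignette records the models, the tunable
parameters, and the design decisions that were genuinely open.

# LGE scar compartmentalization

## Model

Scar is defined on the remote-SD scale: with `mu` and `sigma` the mean
and standard deviation of a remote healthy-myocardium (HM) region of
interest, each wall voxel carries `z = (I - mu) / sigma`. Voxels with
`z >= 2` are scar; within scar, `2 <= z < 3` is heterogeneous tissue (HT)
and `z >= 3` dense scar (DS). The wall between the endocardial and
epicardial contours is split into two transmural halves by proximity to
the bounding contours (signed-distance rule; equidistant voxels are
assigned to the endocardial half so that the split is deterministic and
exactly partitions the wall). The mean `z` of each half is projected onto
the corresponding surface reconstruction, node by node, and nodes are
classified with the same thresholds, yielding the four compartments
EnHT, EnDS, EpHT, EpDS as label-wise sums of barycentric node areas
(one third of each incident triangle).

Longitudinal change of any scalar summary is
`100 * (followup - baseline) / baseline`.

## Open choices and how they were settled

* **Projection.** "Projecting" the half-wall mean onto the surface is
  under-determined; we assign each half-wall voxel to the nearest surface
  node of its own slice (the discrete analogue of a transmural ray) and
  average the assigned voxels per node. Nodes receiving no voxel are
  flagged unmapped and excluded from area sums.
* **Compartment areas** are treated as surface areas of the labeled
  regions (not en-face projections); this interpretation is adopted and
  documented because either reading is compatible with how such tables
  are usually printed.
* **Scar mass** (TSM) thresholds voxel-level `z >= 2` before any surface
  averaging, because mass is a volumetric quantity; total myocardial
  mass (TMM) uses the whole wall. Both use a myocardial density of
  1.05 g/ml, the standard CMR convention.
* **Ventricular volumes** are slice summations (Simpson) of the
  endocardial contour areas at the end-diastolic/end-systolic phases;
  the ejection fraction follows as `100 * (EDV - ESV) / EDV`. When phase
  contours are absent the volumes are reported `NA` and areas are still
  computed.
* **Remote ROI** is an explicit input (mask or nominal `c(mean, sd)`),
  never auto-detected; automatic remote selection is not part of the
  method. A warning is raised when more than 5% of the ROI normalises to
  `z >= 2` (a clean Gaussian ROI leaves ~2.3% above that line).

## The CMR phantom

`generateCMR()` builds an annular wall per slice (circle-in-circle, the
simplest geometry exposing the endo/epi-half semantics) with scar
sectors specified by angular span, slice range, transmural compartment
and an intensity offset in remote-SD units. Tissue signal is
deterministic (`remoteMean + offset * remoteSD`); Gaussian sensor noise
(`noiseSD`, default equal to `remoteSD` so that remote myocardium reads
`Normal(remoteMean, remoteSD)`) is added on top. Setting `noiseSD = 0`
therefore gives exact construction oracles: an offset-4 region
normalises to exactly `z = 4` against the nominal remote statistics, and
compartment areas can be compared to analytic sector areas
(`span/360 * 2 pi r * thickness * nSlices`). At the 64-voxel grids and
120-vertex contour rings used in the tests, discretization keeps the
recovered DS area within ~3.5% of the analytic value; the tests assert
5%.

# Optical mapping

## From movie to maps

A voltage-dye recording is an `H x W x T` frame stack with stimulus
times and a pacing cycle length (600 ms drive train by default, emulating
right-ventricular pacing recorded with a 128 x 128, 16-bit camera).
The analysis chain is:

1. **Conditioning** — polarity is corrected so depolarisation is
   positive-going (di-4-ANEPPS fluorescence falls on depolarisation; the
   sign is detected from the pooled mean-minus-median statistic), with an
   optional spatial box blur and temporal moving average (defaults 1 px
   and 3 frames, conventional light conditioning).
2. **Beat segmentation** — one window `[t_stim, t_stim + CL)` per
   stimulus; the last `k = 3` beats of the drive train are averaged and
   each pixel's averaged beat is normalised to `[0, 1]`; flat pixels are
   invalidated.
3. **Activation** — the instant of maximum positive dF/dt, refined below
   the frame interval by quadratic interpolation. A contiguous plateau of
   maximal derivative (a linear upstroke) activates at its centre;
   separated equal maxima take the earliest; maxima touching the window
   edge invalidate the pixel.
4. **APD80** — the first time after the beat peak at which the
   normalised trace falls to 0.2 of its amplitude (linear interpolation
   between frames), minus the activation time. The reference point is
   the activation instant, consistent with the dF/dt-max convention.
5. **Conduction velocity** — the activation map's isochrone-normal
   gradient, estimated by a least-squares local plane fit over a 5 x 5
   window of valid neighbours (at least 6 required): the velocity vector
   is `grad T / |grad T|^2`, i.e. speed `1/|grad T|` along the normal of
   the isochronal lines. A plane fit rather than finite differences
   because the published descriptions of such estimators imply smoothed
   gradients, and the fit is robust to single-pixel noise. Speeds above
   a 200 cm/s physiological cap are invalidated.
6. **Regional dispersion** — `100 * (stat_HT - stat_HM) / stat_HM` on
   user-supplied HM/HT pixel masks. The regional statistic is the
   median (configurable to the mean): medians are robust to the residual
   boundary pixels of a patchy HT region, and the choice is exposed
   because either convention is found in practice.

## The optical phantom

`generateOptical()` computes per-pixel ground-truth activation as a
slowness-weighted shortest path from the wave origin (left edge for a
plane wave, or a point source) on a 16-neighbour pixel lattice, so that
a slow HT patch produces curved isochrones that exercise the gradient
estimator beyond plane waves. The lattice metric's anisotropy is below
~3%, well inside the 5% recovery tolerance asserted for regional
medians. The action-potential template has a linear upstroke centred on
the ground-truth activation instant and a raised-cosine repolarisation
scaled so the 20%-amplitude crossing falls exactly APD80 later — both
detection conventions therefore recover the configured values exactly up
to frame discretization. Polarity is inverted by default to force the
conditioning stage to handle sign. Sensor noise is a seeded standard
normal field scaled by `noiseSD`, so increasing noise at a fixed seed
scales the same perturbation (making error monotonicity in noise a
structural property, which the tests assert).

# Electroanatomic voltage maps

Bipolar amplitudes are interpolated onto the chamber mesh by
inverse-distance weighting (power 2) over the points within the 5 mm
fill threshold — mimicking clinical surface colouring; the kernel is not
prescribed anywhere, so the choice is documented rather than claimed.
Nodes farther than the threshold from every point are unmapped and
excluded. Classes: DS at or below 0.5 mV, HT in (0.5, 1.5], healthy
above 1.5 mV (the boundary at 1.5 is inclusive, consistent with a
"total scar <= 1.5 mV" reading). Triangle areas are assigned to a class
when at least two vertices share it and split into thirds otherwise, so
DS + HT + healthy equals the mapped area to within a fraction of one
triangle. Interior holes of unmapped nodes are excluded from class
areas (reported separately as unmapped area).

The synthetic study places points on an LV-like spherical cap so every
node lies within the declared spacing of a point, with per-class
amplitude draws; with point spacing at or below the mesh edge length the
interpolation recovers the constructed patch to within one triangle,
which is the asserted oracle.

# Histology

The five-level semi-quantitative scale (+ to +++++) maps to
20/40/60/80/100%. Per animal and compartment, section scores are
weighted by each section's HT extent:
`sum(extent_i * percent_i) / sum(extent_i)`. Extents may be entered in
mm^2 or in transparent-grid squares (0.64 mm^2 each, matching a
20 x 40 mm grid of 1250 squares); weighting is invariant to the unit.
Vascularization is scored on the same 5-level scale as the other four
variables even though it appears only in downstream summaries; this
keeps the variable set uniform.

# Exact rank tests

Group comparisons use the Mann-Whitney U test and the Wilcoxon
signed-rank test with *exact* p-values that remain valid under ties:
the null distribution is the permutation distribution of the mid-rank
statistic conditional on the observed values — enumerated exhaustively
for small designs and otherwise by an equivalent subset-sum shift
recursion (dynamic programming over doubled mid-ranks, which are
integers). Both routes are exact; the tests assert their equality
against an independent brute-force enumeration for all combined sizes
up to 9, with and without ties.

The two-sided p-value doubles the smaller tail and caps at 1 (the
common convention; the summed-extreme-probabilities alternative is
available behind a flag). Zero differences in the paired test are
dropped, conditioning on non-zero differences, matching the referenced
exact implementations; an all-zero sample returns p = 1 with a warning.
Because the exact test is conservative at attainable levels, the
empirical type-I error at alpha = 0.05 stays below 0.05 (about 0.03 at
5 vs 5), which the acceptance checks verify over 10,000 null
simulations. Summaries are medians with interquartile ranges using the
linear-interpolation quantile rule (type 7).

No multiplicity correction is applied across endpoints — the analysis
chain reproduces the single-endpoint alpha = 0.05 convention of the
study design it mirrors; this is reproduced, not endorsed.

# The two-arm synthetic study

`runStudy()` orchestrates the full chain per animal: two CMR phantoms
(baseline and follow-up), one optical movie, one histology table. The
arm-specific remodeling rules encode the scar-evolution scheme under
test:

* **control**: a fraction (default 0.8) of the epicardial HT sector
  converts to DS between timepoints while HT extent stays stable
  (replenished from healthy myocardium) — so ΔEpDS is large and ΔEpHT
  near zero;
* **treated**: the epicardial HT sector grows (default fraction 0.5)
  while DS is stable — so ΔEpHT is large and ΔEpDS near zero;
* endocardial remodeling is identical in both arms (default growth
  0.45 for both HT and DS).

Optical targets default to (ΔCV, ΔAPD) = (−20, +12)% for the treated
arm and (−48.3, +40)% for the control arm; per-animal values jitter
around the targets. Histology level distributions encode lower fibrosis,
better viability and vascularisation, and more and better-polarised
connexin 43 in the treated epicardial HT, with identical endocardial
distributions. Every random draw descends deterministically from one
top-level seed (fanned out per animal and stage), so the full report is
bit-reproducible.

Analysis stages receive only the generated data, never the arm label;
labels are joined at the statistics stage (a blinding analogue enforced
by data flow). Endpoints are the four CMR percentage changes, the two
optical dispersions, and the five histology variables per compartment,
each compared with the exact Mann-Whitney test and summarised as median
and IQR.

## Problem sizes

Default study geometry is a 56 x 56 x 8 CMR grid (1.4 x 1.4 x 5 mm),
48 x 48 optical pixels at 2 ms frames with 3 beats of a 600 ms drive
train, and 6 histology sections per animal with 10 treated vs 9 control
animals — small enough for a complete study in well under a minute while
keeping discretization errors a few percent. The contour-ring density of
the per-animal phantoms scales with the voxel size so that every surface
node averages a stable handful of voxels; without this, coarse grids
make node labels noise-dominated and a baseline compartment can even
quantify to zero area (a hard error, since a relative change has no
meaning there). The identical-arm false-positive calibration repeats
reduced studies (48 x 48 x 4 CMR at 1.6 mm, 24 x 24 optical at 4 ms,
2 beats, 4 sections, 4 vs 4 animals): the calibration property concerns
the statistics stage, and these are the smallest sizes at which every
replicate's baseline compartments remain non-degenerate while allowing
hundreds of replicates. The observed false-positive fraction at
alpha = 0.05 is ~0.03, consistent with the conservativeness of the
exact test.

# What the generators do and do not emulate

The phantoms are designed to make estimator semantics testable, not to
be physiologically realistic: there is no ionic or bidomain model, no
MRI physics, no motion, no fibre anisotropy, and scar geometry is
piecewise-angular rather than organic. Consequently, passing tests
demonstrate that the estimators recover known structure under controlled
noise — they do not validate the biological conclusions of any animal
study, and real-data performance (motion artefacts, illumination drift,
contact-force-dependent electrogram amplitudes) is out of scope.

# Numerical notes and limitations

* Voxels are 0-based with half-open mm extents; voxel centres sit at
  half-voxel offsets. All geometry is in mm, areas in cm^2, masses in g,
  times in ms, speeds in cm/s.
* The wall split is exact by construction (union = wall, intersection
  empty), asserted as a class invariant.
* The shortest-path travel-time phantom uses Dijkstra on a 16-neighbour
  lattice rather than a PDE fast-marching solver; its small metric
  anisotropy is absorbed by the 5% recovery tolerances.
* The CV plane fit biases speeds near strong isochrone curvature
  (within a window radius of a point source or a patch boundary);
  regional summaries use eroded ROIs and medians to stay clear of it.
* Degenerate inputs fail loudly: constant remote ROI, non-nested
  contours, empty point sets, zero sections, zero baselines in
  percentage changes, and flat optical pixels are all rejected or
  invalidated rather than silently propagated.
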