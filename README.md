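# epiScarMap

Quantification toolkit for post-infarction scar remodeling studies in
large-animal models. After a reperfused anterior infarction, the scar is
a mixture of **dense scar (DS)** — presumed inexcitable fibrosis — and
**heterogeneous tissue (HT)** — surviving myocyte bundles interleaved
with fibrotic strands — and the balance between the two, especially in
the epicardium, shapes the substrate for reentrant ventricular
tachycardia. epiScarMap implements the measurement chain used to track
that balance across modalities:

* **LGE-CMR scar compartmentalization** — wall voxels are z-scored
  against remote healthy myocardium (HM), `z = (I - mu)/sigma`;
  `2 <= z < 3` is HT and `z >= 3` DS. The wall is split into
  endocardial/epicardial halves, the half-wall mean signal intensity is
  projected onto 3D surface reconstructions, and labeled node areas give
  EnHT, EnDS, EpHT, EpDS (cm^2) plus scar/myocardial mass and
  ventricular volumes. Longitudinal change is
  `100 * (followup - baseline)/baseline`.
* **Epicardial optical mapping** — voltage-dye movies are conditioned,
  beat-averaged, and turned into activation maps (dF/dt max), APD80 maps
  (time from activation to 80% repolarisation) and conduction-velocity
  fields (local plane fit of activation time; velocity
  `grad T / |grad T|^2`, normal to the isochrones). Regional HT-vs-HM
  dispersion is `100 * (HT - HM)/HM`.
* **Electroanatomic voltage maps** — bipolar amplitudes interpolated on
  the chamber mesh (inverse-distance weighting within a 5 mm fill
  threshold); DS `<= 0.5 mV`, HT `(0.5, 1.5]` mV, healthy `> 1.5 mV`,
  with class areas in cm^2.
* **Histology scoring** — five-level ordinal scores (+ .. +++++ ->
  20..100%) weighted by section HT extent into per-animal means.
* **Exact rank tests** — Mann-Whitney and Wilcoxon signed-rank tests
  whose exact p-values remain valid in the presence of ties
  (permutation distribution of the mid-rank statistic; enumeration or an
  exact shift recursion).
* **Synthetic-data generators and a study pipeline** — phantoms with
  closed-form ground truth for every modality, and `runStudy()`, which
  simulates a complete two-arm study (10 treated vs 9 control animals by
  default) end-to-end and compares every endpoint between arms.

## Worked example

A noiseless phantom with one epicardial-half dense-scar sector, pushed
through the full CMR chain:

```r
library(epiScarMap)

spec <- syntheticCMRSpec(
  gridShape = c(64L, 64L, 8L), nContourVertices = 120L,
  scarRegions = list(list(angleStart = 0, angleSpan = 90, slices = 1:6,
                          compartment = "epi-half", offset = 4)),
  noiseSD = 0, seed = 3L)
g     <- generateCMR(spec)
masks <- splitWallHalves(g$contours, g$volume)
zvol  <- normalizeToSDUnits(g$volume, g$nominalRemote, masks)
mapEp <- projectHalfWallSI(zvol, "epi", contourSurfaceMesh(g$contours, "epi", 5))
mapEn <- projectHalfWallSI(zvol, "endo", contourSurfaceMesh(g$contours, "endo", 5))
quantifyScar(mapEn, mapEp, zvol)
#> ScarQuantification
#>   EnDS 0.00  EnHT 0.00  EpDS 11.84  EpHT 0.82  (cm^2)
#>   TSM 4.79 g  TMM 46.56 g
#>   LVEDV NA ml  LVESV NA ml  LVEF NA%
```

The 90-degree sector's analytic surface area is
`90/360 * 2*pi*26 mm * 5 mm * 6 slices = 12.25 cm^2`; the recovered
11.84 cm^2 is within the ~3.5% discretization of this grid, with the
boundary ring showing up as a sliver of HT.

An exact Mann-Whitney test with the worked two-vs-two configuration:

```r
exactMannWhitney(c(1, 2), c(3, 4))
#> mann-whitney (exact-enumeration): statistic = 0.00, exact two-sided p = 0.3333
```

And a complete synthetic study:

```r
rep <- runStudy(studyConfig(seed = 11L))
rep
#> StudyReport: 10 treated vs 9 control, 16 endpoints
#>   dEpHT    treated  55.8 [ 42.0,  70.8]  control   3.6 [ -3.6,  9.4]  p=2.165e-05
#>   dEpDS    treated   5.6 [  1.0,  12.4]  control  82.9 [ 73.7, 86.4]  p=2.165e-05
#>   cvDiff   treated -20.5 [-21.6, -19.8]  control -46.6 [-50.3,-45.9]  p=2.165e-05
#>   apdDiff  treated  11.5 [ 11.0,  12.1]  control  37.8 [ 37.3, 39.3]  p=2.165e-05
#>   ...
```

Treated-arm animals accumulate heterogeneous tissue while dense scar is
stable; control-arm animals convert HT into DS; epicardial electrical
dispersion (CV and APD) is roughly twice as large in the control arm;
endocardial endpoints do not separate. Each endpoint row reports the
arm medians with IQR and the exact Mann-Whitney p-value.

## Layout

* `R/` — S4 classes (`LGEVolume`, `ZVolume`, `SurfaceSIMap`,
  `OpticalRecording`, `ActivationMap`/`APDMap`/`CVField`, `EAMStudy`,
  `VoltageClassMap`, `RankTestResult`, `StudyConfig`/`StudyReport`) and
  the per-modality operations.
* `vignettes/scar-remodeling-pipeline.Rmd` — the models, estimator
  conventions, and design decisions, including what the synthetic
  generators do and do not emulate.
* `tests/testthat/` — unit, property and acceptance tests (construction
  oracles against closed-form ground truth; brute-force enumeration
  oracles for the exact tests).
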