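# aortamark

Automatic detection of the five aortic landmarks used in transcatheter
aortic valve implantation (TAVI) planning — the basal hinge points of the
left-, non- and right-coronary valve cusps (LCC, NCC, RCC) and the left
and right coronary ostia (LCO, RCO) — from contrast-enhanced volumetric
CT, together with the clinical measurements derived from them.

The three hinge points define the **aortic annular plane** (AAP), the
reference plane for valve sizing; the perpendicular distances from the
AAP to the ostia (the **coronary heights**,
$h = (x_{\mathrm{ostium}} - \bar{x}_{\mathrm{hinge}}) \cdot \hat{n}$)
flag patients at risk of coronary obstruction. `aortamark` implements the
full probability-map detection chain:

* NIfTI volume I/O with exact world/voxel geometry (RAS+, 0-based
  indices), isotropic cubic-spline resampling to 1.0 mm, 128³ ROI
  cropping, HU window normalisation, and ±3%/±3° similarity augmentation;
* multi-radius (3/5/7 mm) spherical label masks encoding the landmarks as
  segmentation targets (class codes LCC = 1 … RCO = 5);
* a pluggable `DetectorBackend` contract with a Gaussian **surrogate
  backend** emulating a trained three-model ensemble, sliding-window
  prediction (64³/32), and per-voxel fusion (average, then renormalise);
* the postprocessing that turns a fused class map into a point: select
  voxels with p > 0.5, single-linkage clustering at 1.1 mm, largest
  cluster, centroid of its p > 0.9 voxels;
* AAP reconstruction and coronary-height measurement;
* a seeded synthetic aortic-root CT **phantom generator** (lumen ≈350 HU,
  tissue ≈40 HU, calcium 700–1500 HU, noise, optional motion blur) with
  exactly known landmarks, so the whole chain is testable without patient
  data;
* the validation statistics: median (LQ–UQ) error summaries, Wilcoxon
  signed-rank paired tests, Pearson r², Bland–Altman limits of agreement.

## Worked example

```r
library(aortamark)

# a synthetic patient: contrast-enhanced aortic root, known landmarks
spec <- phantomSpec(seed = 42)
ph   <- generatePhantom(spec)

# full pipeline: resample -> crop -> normalise -> 3-radius prediction
# -> fusion -> cluster/centroid extraction -> plane + heights
cfg <- runConfig(jitterSd = 0.5, seed = 7)
res <- runDetection(cfg, ph$volume, ph$landmarks)

round(landmarkErrors(res$landmarks, ph$landmarks), 3)
#>   LCC   NCC   RCC   LCO   RCO
#> 0.260 0.817 0.829 0.219 0.450

res$measurements
#> lco_height_mm rco_height_mm
#>      17.10902      11.44275
deriveMeasurements(ph$landmarks)   # ground truth for comparison
#> lco_height_mm rco_height_mm
#>      17.36588      11.34667
```

Each landmark is recovered to well under a millimetre on a 1 mm grid, and
the derived coronary heights agree with the generating geometry to a few
tenths of a millimetre. `res$diagnostics` reports, per class, the number
of selected voxels, clusters, the largest-cluster size and whether the
high-confidence fallback was needed.

A cohort-level validation with the same machinery:

```r
val <- runValidation(cfg, n = 10, seed = 2024)
val$summary          # per-class and pooled median (LQ-UQ) error table
val$heightAgreement  # r^2, bias and Bland-Altman limits for the heights
```

A thin CLI wrapping these functions ships in `inst/cli/aortamark`
(subcommands `phantom`, `mask`, `detect`, `validate`, `stats`).

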