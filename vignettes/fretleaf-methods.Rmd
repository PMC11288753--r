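---
title: "Quantifying a nuclear ABA biosensor at cell-type resolution: methods and design"
author: "fretleaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a nuclear ABA biosensor at cell-type resolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretleaf)
```

## The measurement problem

A ratiometric FRET biosensor for abscisic acid (ABA), targeted to plant
nuclei, reports hormone concentration through the ratio of two emission
bands acquired under donor excitation: the acceptor-emission band (DxAm,
525--560 nm) and the donor-emission band (DxDm, 460--500 nm). A third
channel under acceptor excitation (AxAm) is proportional to sensor
abundance and independent of ABA; it is the natural channel for finding
nuclei. When ABA binds the sensor, FRET efficiency changes and the
emission ratio DxAm/DxDm shifts; comparing per-nucleus ratios between
infested and control leaves, cell type by cell type, localises the
hormone response within the leaf.

fretleaf implements this quantification end to end: 3D nucleus
segmentation from AxAm, per-nucleus emission ratios, rule-based
classification of nuclei into five leaf cell types (stomata, pavement,
spongy mesophyll, bundle sheath, vascular bundle), and the group
statistics (Welch *t*, two-way ANOVA with Tukey/Sidak post hoc,
Benjamini--Hochberg FDR, Pearson correlation). Companion morphometrics
quantify stomatal aperture (width/length ratio) and density from
impression images, and stained area from leaf-disk images (trypan blue
cell death, DAB H~2~O~2~, chlorosis).

A note on channel naming: in the source instrument configuration the
band labels appear swapped relative to the band physics (the 460--500 nm
donor-emission band is labelled as if it were acceptor emission, and
vice versa). fretleaf fixes the ratio by band — DxAm is always the
525--560 nm acceptor-emission band — and exposes `invertRatio` in
`ratioParams()` for data acquired under the opposite convention.

## The synthetic phantom generator

No raw microscopy is shipped or downloaded; every stage is validated on
synthetic phantoms with exact ground truth. The generator is first-class,
tested code, and its defaults define the study conditions used by the
test suite and by `scripts/acceptance.R`.

**Leaf scenes.** A scene is a layered population of ellipsoidal nuclei in
a 3D field (`sceneConfig()`, `generateLeafScene()`). The layering follows
the abaxial imaging order of a leaf: stomata and pavement nuclei in the
top ~12 µm, spongy mesophyll at 20--52 µm, bundle sheath at 35--62 µm,
vascular bundle at 58--76 µm of an 80 µm stack. Shape priors give the
classifier something real to work with: stomatal nuclei are small and
near-spherical (equivalent diameter ≈ 4.5 µm), pavement nuclei large and
flattened (≈ 11.5 µm, flatness ≥ 2), mesophyll intermediate (≈ 7 µm),
bundle-sheath nuclei elongated (major/minor = 3) with horizontal major
axis, and vascular nuclei small (≈ 5 µm) and clustered along a randomly
oriented "vein axis" with 8--10 µm spacing. Placement is rejection
sampling under a hard-core constraint — centres at least
`max(minCenterSeparation, sa_i + sa_j + 3)` µm apart — which guarantees
non-overlapping ellipsoids and a surface gap that segmentation smoothing
cannot bridge. Rendering refuses overlapping nuclei rather than blending
them.

**Photophysics.** Inside a nucleus with true ratio $R$ and donor-excited
total emission $T$, voxels carry $\mathrm{DxDm} = T/(1+R)$,
$\mathrm{DxAm} = T\,R/(1+R)$ and $\mathrm{AxAm} = A$. This partition
makes the quantity of interest analytically recoverable —
DxAm/DxDm $= R$ exactly in the noiseless limit and $DxDm + DxAm = T$
voxelwise — so ratio recovery is an analytic test, not a calibration.
The default noise model is Poisson shot noise plus additive Gaussian
read noise (s.d. 2 counts), matching photon-counting detectors; optical
point-spread, spectral bleed-through and photobleaching are deliberately
out of scope, so passing phantoms bounds algorithmic error only, not
these instrument effects.

**Condition structure.** Baseline true ratio is 1.0 in all classes with
per-nucleus jitter (s.d. 0.05). Infestation adds a per-class delta —
largest for stomata (+0.50) and vascular bundle (+0.45), smaller
elsewhere (+0.15 to +0.20) — and removes each spongy-mesophyll nucleus
with probability 0.3 (mite feeding kills mesophyll cells). These
magnitudes are free parameters of the generator, chosen once as a
plausible biosensor dynamic range; the source figures are graphical and
publish no per-class numbers. What the pipeline must recover is the
*pattern*: increases in all classes, stomata and vascular on top, and a
mesophyll-only viability loss.

**2D phantoms.** `generateImpression()` draws dark elliptical pores on a
bright field with 8×8-subsampled partial-coverage edges (real pore edges
are blurred over a pixel by the optics); the truth table holds each
pore's length, width and width/length ratio. `generateStainedDisk()`
renders a pale-green disk on white with stained blobs covering a target
fraction of the disk to within 1%, with the exact truth mask; blob
geometry depends only on the seed, so the same seed renders identical
masks in trypan-blue, DAB-brown or chlorosis-yellow colour.

## Segmentation and features

`segmentNuclei()` is deliberately simple, mirroring threshold-based
nucleus segmentation of biosensor stacks: Gaussian smoothing of AxAm
(sigma 1 µm, converted to voxels per axis for anisotropic grids), one
global threshold (Otsu over a 256-bin histogram of the whole volume, or
a fixed value), 26-connected component labelling, and a volume filter
(8--4000 µm³) that removes debris and any merged pair. There is no
watershed: the generator guarantees separation, and on real data a merge
is flagged by the volume filter rather than silently split.

Features (`extractFeatures()`) are computed in physical micrometres from
the anisotropic voxel size directly — no resampling, hence no
interpolation artefacts in intensity means. Semi-axes come from the
eigenvalues of the voxel-centre covariance (plus the voxel
self-variance), scaled by $\sqrt{5\lambda}$ for a uniform ellipsoid.
Two numerical caveats are documented rather than hidden: a 2 µm semi-axis
sampled at 2 µm slices is at the sampling limit and recovers with ~10-15%
error, and an Otsu threshold on a low-background stack sits below the
half-maximum, so thresholded masks are slightly dilated and measured
diameters run ~1--2 µm above truth. The classifier thresholds are
calibrated on measured features, which absorbs this bias; the moment
estimator itself is verified separately against exactly rasterised
ellipsoids.

Background is the per-channel median over unlabelled voxels
(`estimateBackground()`), requiring ≥ 1% unlabelled volume. The
emission ratio is the ratio of background-corrected per-nucleus *mean*
intensities, not the mean of voxelwise ratios, which would be
noise-amplifying. Nuclei whose corrected DxDm mean falls below
`denominatorFloor` (default 1 count) are excluded with a QC flag;
negative numerators clamp to ratio 0, never negative.

## Cell typing

`classifyNuclei()` is a deterministic, auditable rule cascade rather
than a trained classifier — there is no training data, and rules keep
every decision inspectable:

1. depth ≤ 15 µm: equivalent diameter < 7 µm → stomata; ≥ 9 µm →
   pavement; between → tie-break order (default stomata first);
2. depth ≥ 55 µm and ≥ 2 neighbour centroids within 24 µm → vascular
   bundle;
3. elongation ≥ 2.0 → bundle sheath;
4. otherwise spongy mesophyll.

Thresholds sit midway between adjacent generator priors, so separation
holds by construction on phantoms; all are exposed in
`classifierConfig()` for real data. Depth is measured from the
shallowest segmented nucleus by default (robust to mounting offset);
`depthReference = "stack_top"` uses absolute depth, which is the right
choice when a scene contains a single tissue layer and there is no
epidermal anchor. The neighbourhood radius of 24 µm makes the
second-nearest vein neighbour (at ~2 × 9 µm spacing) reliably visible to
rule 2, while mesophyll nuclei, whose depth range ends above the 55 µm
gate, can never reach it. The cascade is exhaustive and exclusive by
construction, and `confusionMatrix()` scores predictions against truth
by greedy nearest-centroid matching.

## Morphometrics

Stomatal pores are detected as dark components and fitted
subpixel-accurately from the partial-coverage shading of their edges:
orientation and major semi-axis $a$ from coverage-weighted second
moments, and the minor semi-axis closed through the exact weighted area,
$b = \text{area}/(\pi a)$. The area route matters: binary-mask moments
mismeasure pores a few pixels wide by 10--30%, while the weighted-area
fit recovers width/length within ~3% even at 10 px major axis (and
within 1% at ≥ 16 px). Aperture is reported as width/length of the pore
ellipse; no attempt is made to separate pore from guard-cell complex.
Density is a count per mm².

Stain quantification classifies pixels by colour rule — trypan blue by
blue-over-red dominance, DAB and chlorosis by HSV hue windows with a
saturation floor (hue is robust to illumination scaling) — intersected
with a disk mask fitted as a circle over the non-white region, or a
caller-supplied mask (a rosette mask turns the same computation into
whole-plant chlorotic damage). Areas are pixel counts times pixel area,
in mm²; DAB is additionally expressed in relative staining units
(sample area over control-group mean).

## Statistics

Where the analysis needs a standard test, fretleaf calls the standard
tool: `t.test` (Welch by default; the pooled-variance Student mode is a
flag, since the variance assumption is unstated in this field's typical
reports), `car::Anova` type-II with `emmeans` Tukey/Sidak post hoc
gated on significance of the relevant term, `p.adjust("BH")` for FDR,
and `cor` for Pearson. Degenerate inputs follow explicit conventions so
batch pipelines never die midway: zero-variance-equal samples give
p = 1, a perfect additive fit reports interaction SS = 0 with p = 1, and
a constant response flags all terms at p = 1. BH was chosen as the FDR
step-up; the alternative two-stage procedures would only be relevant at
far larger test families than the six comparisons used here.

The viability readout (`countComparison()`) runs Welch *t* on per-image
nucleus counts for each of the five classes plus the total, BH-corrected
across those six tests; `ratioComparison()` does the same for
per-nucleus emission ratios. Because the generator fixes per-image class
counts by configuration, count comparisons under the null are degenerate
(both arms constant, p = 1 by convention) and the null-calibration
property is carried by the ratio family, which has real between-nucleus
jitter.

## The pipeline and problem sizes

`runPipeline()` simulates n images per condition, processes each through
segmentation, ratiometry and typing, and assembles summaries, per-class
deltas, both comparison families and a reproducibility manifest; with
`render = FALSE` the per-image tables come from generator truth, which
exercises the statistical stages alone. Everything is deterministic
given the experiment seed (image i of the control arm uses scene seed
`1000·seed + i`, infested `1000·seed + 500 + i`; rendering noise uses
scene seed + 1).

Problem sizes used by the validation suite, chosen to exercise each
stage at full fidelity where it matters and batch scale elsewhere:

* reference phantom: 512 × 512 × 40 voxels at 0.5 × 0.5 × 2 µm, 40
  nuclei, 20 seeds — segmentation exactness and cell-typing accuracy;
* batch scene: 192 × 192 × 40 voxels at 0.7 × 0.7 × 2 µm, 88 nuclei (60
  mesophyll), 8 images per condition, 20 runs — infestation-pattern
  recovery;
* null calibration: 200 truth-level runs of the same design with all
  effects zeroed;
* noiseless ratio recovery uses a bright phantom (T = 30000 counts):
  at the default T = 300, 16-bit rounding alone contributes ~0.5%
  relative error, so the sub-0.1% analytic check is only meaningful
  above ~10⁴ counts.

## Worked example

```{r example, eval = FALSE}
cfg <- sceneConfig(condition = "control", seed = 7)
truth <- generateLeafScene(cfg)
stack <- renderStack(truth, cfg)
labels <- segmentNuclei(stack)
records <- extractFeatures(labels, stack, rNb = 24)
records <- computeEmissionRatios(records, estimateBackground(stack, labels))
records <- classifyNuclei(records)
confusionMatrix(records, truth)$accuracy

report <- runPipeline(experimentConfig(seed = 7))
report$deltaByClass
report$countComparison
```

## Known limitations

* The phantoms omit optical PSF, spectral bleed-through, autofluorescence
  and photobleaching; passing tests bound algorithmic error, not those
  acquisition effects.
* Touching nuclei are not split; on real data with denser nuclei a
  watershed stage would be needed in front of the feature extractor.
* Classifier thresholds are phantom-calibrated defaults, not a port of
  any instrument-specific tool; on real data they must be tuned on the
  measured feature distributions.
* Absolute ABA concentrations are out of scope: converting emission
  ratio to concentration needs an in-vitro sensor calibration.
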