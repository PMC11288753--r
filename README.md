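# fretleaf

Cell-type-resolved quantification of a ratiometric FRET biosensor for
abscisic acid (ABA) in leaves, with companion stomatal and histochemical
morphometrics.

## The problem

Spider-mite feeding triggers ABA accumulation and stomatal closure in
Arabidopsis leaves. A nuclear-localised FRET biosensor reports ABA through
its fluorescence emission ratio: under donor excitation, the ratio of the
acceptor-emission band (DxAm, 525–560 nm) to the donor-emission band
(DxDm, 460–500 nm). A third acquisition under acceptor excitation (AxAm)
tracks sensor abundance and is used to find nuclei. Resolving the ratio
per nucleus, and classifying each nucleus into one of five leaf cell
types — stomata, pavement, spongy mesophyll, bundle sheath, vascular
bundle — turns a confocal z-stack into a cell-type-resolved hormone map,
and the number of detectable nuclei per type doubles as a viability
readout (mites kill the spongy mesophyll cells they feed on).

fretleaf re-implements this quantification as a tested R pipeline:

* **phantom generation** — synthetic leaf scenes, stomatal-impression
  images and stained-disk images with exact ground truth
  (`generateLeafScene()`, `renderStack()`, `generateImpression()`,
  `generateStainedDisk()`), so every stage is testable without raw
  microscopy;
* **segmentation** — 3D nucleus segmentation from the AxAm channel:
  Gaussian smoothing, global Otsu threshold, 26-connected labelling,
  volume filter (`segmentNuclei()`, `extractFeatures()`,
  `estimateBackground()`);
* **ratiometry** — per-nucleus emission ratio
  (mean DxAm − bg) / (mean DxDm − bg), with QC flags and group summaries
  (`computeEmissionRatios()`, `summarizeRatios()`,
  `ratioIncreaseByClass()`);
* **cell typing** — a deterministic shape-and-depth rule cascade
  (`classifyNuclei()`, `confusionMatrix()`);
* **morphometrics** — stomatal aperture as the pore width/length ratio
  via subpixel ellipse fits, stomatal density per mm², stained area in
  mm² and relative DAB units (`detectStomata()`, `stomatalDensity()`,
  `stainedMask()`, `stainedArea()`, `relativeStaining()`);
* **statistics** — Welch/Student *t*, type-II two-way ANOVA with
  Tukey/Sidak post hoc, Benjamini–Hochberg FDR, per-class count and
  ratio comparisons, Pearson R² (`welchT()`, `twoWayFactorial()`,
  `bhFdr()`, `countComparison()`, `pearsonR2()`), and an end-to-end
  driver (`runPipeline()`, `writeReport()`).

The methods vignette (`vignettes/fretleaf-methods.Rmd`) documents the
model, the phantom design, every tunable parameter and the known
limitations.

## Worked example

Simulate one control acquisition, quantify it, then run a full
control-versus-infested experiment:

```r
library(fretleaf)

cfg    <- sceneConfig(condition = "control", seed = 7)
truth  <- generateLeafScene(cfg)      # 40 nuclei, 5 cell types
stack  <- renderStack(truth, cfg)     # 512 x 512 x 40 voxel FretStack
labels <- segmentNuclei(stack)
records <- extractFeatures(labels, stack, rNb = 24)
records <- computeEmissionRatios(records,
                                 estimateBackground(stack, labels))
records <- classifyNuclei(records)
confusionMatrix(records, truth)$accuracy
#> [1] 1

report <- runPipeline(experimentConfig(seed = 7))
report$deltaByClass
#>          cell_type     delta          se n_control n_infested
#> 1    bundle_sheath 0.2081025 0.011979784        35         39
#> 2         pavement 0.1686121 0.009079351        64         64
#> 3 spongy_mesophyll 0.1546741 0.003646525       480        345
#> 4          stomata 0.5355039 0.008367880        80         80
#> 5  vascular_bundle 0.4590127 0.012789901        45         41
```

Reading the output: the biosensor ratio rises in every cell type under
infestation, with the stomatal (+0.54) and vascular (+0.46) nuclei
showing the largest increases — exactly the pattern the generator
encodes. The viability comparison flags the mesophyll loss:

```r
report$countComparison[, c("cell_type", "mean_control", "mean_infested",
                           "q")]
#>          cell_type mean_control mean_infested            q
#> 1          stomata       10.000        10.000 1.000000e+00
#> 2         pavement        8.000         8.000 1.000000e+00
#> 3 spongy_mesophyll       60.000        43.125 8.415459e-06
#> 4    bundle_sheath        4.375         4.875 1.751253e-01
#> 5  vascular_bundle        5.625         5.125 1.751253e-01
#> 6            total       88.000        71.125 8.415459e-06
```

Only spongy mesophyll (and hence the total) drops significantly
(q < 0.05 after BH correction across the six tests): per-image counts
fall from 60 to ~43 nuclei, the 30% feeding-induced dropout the phantom
was configured with.

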