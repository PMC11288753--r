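#' FretStack: a three-channel confocal z-stack
#'
#' Container for one biosensor acquisition: three 3D voxel arrays (DxDm,
#' DxAm, AxAm) sharing dimensions and a physical voxel size in micrometres.
#' Intensities are stored as doubles; [writeStack()] (and
#' [quantizeStack()]) clip to \[0, 65535\] and round, matching 16-bit
#' acquisition.
#'
#' @slot channels named list of three numeric 3D arrays (DxDm, DxAm, AxAm).
#' @slot voxelSize numeric(3), micrometres per voxel along x, y, z.
#' @aliases FretStack
#' @exportClass FretStack
setClass("FretStack",
  representation(channels = "list", voxelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(names(object@channels), fretChannels()))
      msg <- c(msg, "channels must be named DxDm, DxAm, AxAm")
    dims <- lapply(object@channels, dim)
    if (any(vapply(dims, length, 1L) != 3L))
      msg <- c(msg, "each channel must be a 3D array")
    if (length(unique(lapply(dims, as.integer))) > 1L)
      msg <- c(msg, "all channels must share dimensions")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive values (um)")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a FretStack
#'
#' @param DxDm,DxAm,AxAm numeric 3D arrays of identical dimension.
#' @param voxelSize numeric(3), micrometres per voxel (x, y, z).
#' @return A [FretStack-class] object.
#' @examples
#' a <- array(0, c(8, 8, 4))
#' FretStack(a, a, a + 1, voxelSize = c(0.5, 0.5, 2))
#' @export
FretStack <- function(DxDm, DxAm, AxAm, voxelSize) {
  new("FretStack",
      channels = list(DxDm = DxDm, DxAm = DxAm, AxAm = AxAm),
      voxelSize = as.numeric(voxelSize))
}

#' LabelMap: integer nucleus labels over a voxel grid
#'
#' Output of [segmentNuclei()]: 0 marks background, labels 1..N mark
#' segmented nuclei. After size filtering labels are consecutive.
#'
#' @slot labels integer 3D array.
#' @slot voxelSize numeric(3), micrometres per voxel, carried from the stack.
#' @aliases LabelMap
#' @exportClass LabelMap
setClass("LabelMap",
  representation(labels = "array", voxelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3D array")
    if (any(object@labels < 0)) msg <- c(msg, "labels must be non-negative")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive values (um)")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a LabelMap
#' @param labels integer 3D array (0 = background).
#' @param voxelSize numeric(3), micrometres per voxel.
#' @return A [LabelMap-class] object.
#' @export
LabelMap <- function(labels, voxelSize) {
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels, voxelSize = as.numeric(voxelSize))
}

#' SceneConfig: parameters of a synthetic leaf scene
#'
#' Defines a layered leaf phantom: per-class nucleus counts, shape priors,
#' depth ranges, true emission ratios (baseline plus infestation delta),
#' mesophyll dropout under infestation, signal levels and the noise model.
#' See [sceneConfig()] for defaults and units.
#'
#' @slot imageShape integer(3) voxels (x, y, z).
#' @slot voxelSize numeric(3) um/voxel.
#' @slot counts named integer(5), nuclei per cell type.
#' @slot shapePriors data.frame: class, sa, sb, sc (mean semi-axes, um),
#'   sdAxes (per-axis s.d., um), depthMin, depthMax (um below stack top).
#' @slot baselineRatio named numeric(5), true emission ratio under control.
#' @slot infestedDelta named numeric(5), added to the baseline when
#'   condition is "infested".
#' @slot ratioJitterSD numeric(1), per-nucleus s.d. of the true ratio.
#' @slot mesophyllDropout numeric(1) in \[0,1\], probability that a spongy-
#'   mesophyll nucleus is absent under infestation (cell-death emulation).
#' @slot minCenterSeparation numeric(1) um.
#' @slot emissionTotal numeric(1), donor-excited total emission T (counts).
#' @slot acceptorLevel numeric(1), AxAm level A (counts).
#' @slot brightnessJitterSD numeric(1), lognormal s.d. of per-nucleus T and A.
#' @slot backgroundLevel named numeric(3), per-channel background (counts).
#' @slot noiseModel one of "none", "gaussian", "poisson", "poisson_gaussian".
#' @slot gaussianSD numeric(1), read-noise s.d. (counts).
#' @slot poissonScale numeric(1), photons per count for Poisson noise.
#' @slot condition "control" or "infested".
#' @slot seed integer(1).
#' @aliases SceneConfig
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(
    imageShape = "integer", voxelSize = "numeric", counts = "integer",
    shapePriors = "data.frame", baselineRatio = "numeric",
    infestedDelta = "numeric", ratioJitterSD = "numeric",
    mesophyllDropout = "numeric", minCenterSeparation = "numeric",
    emissionTotal = "numeric", acceptorLevel = "numeric",
    brightnessJitterSD = "numeric", backgroundLevel = "numeric",
    noiseModel = "character", gaussianSD = "numeric",
    poissonScale = "numeric", condition = "character", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    ct <- cellTypes()
    if (!identical(sort(names(object@counts)), sort(ct)))
      msg <- c(msg, "counts must be named by the five cell types")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
    if (any(object@baselineRatio <= 0))
      msg <- c(msg, "baseline ratios must be > 0")
    if (any(object@infestedDelta < 0))
      msg <- c(msg, "infested deltas must be >= 0")
    if (object@mesophyllDropout < 0 || object@mesophyllDropout > 1)
      msg <- c(msg, "mesophyllDropout must be in [0, 1]")
    if (!object@condition %in% c("control", "infested"))
      msg <- c(msg, "condition must be 'control' or 'infested'")
    if (!object@noiseModel %in%
          c("none", "gaussian", "poisson", "poisson_gaussian"))
      msg <- c(msg, "unknown noiseModel")
    stackDepth <- object@imageShape[3] * object@voxelSize[3]
    sp <- object@shapePriors
    if (!all(ct %in% sp$class))
      msg <- c(msg, "shapePriors must cover all five cell types")
    if (any(sp$depthMin < 0) || any(sp$depthMax > stackDepth))
      msg <- c(msg, "class depth ranges must lie inside the stack")
    if (any(sp$depthMin >= sp$depthMax))
      msg <- c(msg, "depthMin must be < depthMax")
    # layered leaf: epidermal classes shallowest, vascular deepest
    dmax <- setNames(sp$depthMax, sp$class)
    dmin <- setNames(sp$depthMin, sp$class)
    if (max(dmax[c("stomata", "pavement")]) > dmin["vascular_bundle"] &&
        dmin["vascular_bundle"] > 0) {
      if (dmin["vascular_bundle"] <= dmax["stomata"])
        msg <- c(msg, "vascular depth range must lie below the epidermis")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' SegmentationParams: nucleus segmentation parameters
#'
#' @slot gaussianSigma numeric(1), smoothing sigma in um (converted to
#'   voxels per axis at run time).
#' @slot thresholdMethod "otsu" or "fixed".
#' @slot fixedThreshold numeric(1), used when thresholdMethod = "fixed".
#' @slot connectivity 6 or 26.
#' @slot minVolume,maxVolume numeric(1), component volume bounds (um^3).
#' @aliases SegmentationParams
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(gaussianSigma = "numeric", thresholdMethod = "character",
                 fixedThreshold = "numeric", connectivity = "integer",
                 minVolume = "numeric", maxVolume = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@gaussianSigma < 0) msg <- c(msg, "gaussianSigma must be >= 0")
    if (!object@thresholdMethod %in% c("otsu", "fixed"))
      msg <- c(msg, "thresholdMethod must be 'otsu' or 'fixed'")
    if (!object@connectivity %in% c(6L, 26L))
      msg <- c(msg, "connectivity must be 6 or 26")
    if (object@minVolume >= object@maxVolume)
      msg <- c(msg, "minVolume must be < maxVolume")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct SegmentationParams
#'
#' Defaults: sigma 1 um, Otsu threshold on the smoothed AxAm channel,
#' 26-connectivity, volume bounds \[8, 4000\] um^3. The lower bound sits
#' well below the smallest phantom nucleus even after threshold erosion
#' of small dim nuclei, while still rejecting debris; the upper bound
#' removes merged pairs. Touching nuclei are not split by watershed; the
#' generator guarantees separation and genuine merges are removed by the
#' upper volume bound.
#'
#' @param gaussianSigma smoothing sigma, um.
#' @param thresholdMethod "otsu" or "fixed".
#' @param fixedThreshold absolute intensity threshold for "fixed".
#' @param connectivity 6 or 26.
#' @param minVolume,maxVolume accepted component volume, um^3.
#' @return A [SegmentationParams-class] object.
#' @export
segmentationParams <- function(gaussianSigma = 1.0,
                               thresholdMethod = c("otsu", "fixed"),
                               fixedThreshold = NA_real_,
                               connectivity = 26L,
                               minVolume = 8, maxVolume = 4000) {
  new("SegmentationParams", gaussianSigma = gaussianSigma,
      thresholdMethod = match.arg(thresholdMethod),
      fixedThreshold = as.numeric(fixedThreshold),
      connectivity = as.integer(connectivity),
      minVolume = minVolume, maxVolume = maxVolume)
}

#' RatioParams: emission-ratio computation parameters
#'
#' @slot backgroundMode "none" or "global_median".
#' @slot denominatorFloor minimum background-corrected DxDm mean (counts);
#'   nuclei below it are excluded with qc flag "low_donor_signal".
#' @slot invertRatio logical; swap numerator and denominator bands.
#' @aliases RatioParams
#' @exportClass RatioParams
setClass("RatioParams",
  representation(backgroundMode = "character", denominatorFloor = "numeric",
                 invertRatio = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!object@backgroundMode %in% c("none", "global_median"))
      msg <- c(msg, "backgroundMode must be 'none' or 'global_median'")
    if (object@denominatorFloor <= 0)
      msg <- c(msg, "denominatorFloor must be > 0")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct RatioParams
#'
#' The emission ratio is DxAm/DxDm of background-corrected per-nucleus mean
#' intensities (not the mean of voxelwise ratios, which amplifies noise).
#' Band assignment follows the band physics: DxAm is the donor-excitation
#' acceptor-emission band (525--560 nm); `invertRatio` swaps the bands.
#'
#' @param backgroundMode "none" or "global_median".
#' @param denominatorFloor minimum corrected DxDm mean, counts.
#' @param invertRatio swap numerator/denominator.
#' @return A [RatioParams-class] object.
#' @export
ratioParams <- function(backgroundMode = c("global_median", "none"),
                        denominatorFloor = 1, invertRatio = FALSE) {
  new("RatioParams", backgroundMode = match.arg(backgroundMode),
      denominatorFloor = denominatorFloor, invertRatio = invertRatio)
}

#' ClassifierConfig: rule-based cell-type classifier thresholds
#'
#' @slot epidermisMaxDepth um; at or above this depth a nucleus is epidermal.
#' @slot vascularMinDepth um; minimum depth of the vascular rule.
#' @slot stomataMaxEquivDiam um.
#' @slot pavementMinEquivDiam um.
#' @slot bundleSheathMinElongation dimensionless a/b.
#' @slot vascularMinNeighborDensity count of neighbour centroids within rNb.
#' @slot rNb neighbourhood radius, um.
#' @slot tieBreakOrder class priority for the epidermal size tie zone.
#' @slot depthReference "shallowest_nucleus" or "stack_top".
#' @aliases ClassifierConfig
#' @exportClass ClassifierConfig
setClass("ClassifierConfig",
  representation(epidermisMaxDepth = "numeric", vascularMinDepth = "numeric",
                 stomataMaxEquivDiam = "numeric",
                 pavementMinEquivDiam = "numeric",
                 bundleSheathMinElongation = "numeric",
                 vascularMinNeighborDensity = "numeric", rNb = "numeric",
                 tieBreakOrder = "character", depthReference = "character"),
  validity = function(object) {
    msg <- NULL
    pos <- c(object@epidermisMaxDepth, object@vascularMinDepth,
             object@stomataMaxEquivDiam, object@pavementMinEquivDiam,
             object@bundleSheathMinElongation, object@rNb)
    if (any(pos <= 0)) msg <- c(msg, "thresholds must be positive")
    if (object@epidermisMaxDepth >= object@vascularMinDepth)
      msg <- c(msg, "epidermisMaxDepth must be < vascularMinDepth")
    if (!all(object@tieBreakOrder %in% cellTypes()))
      msg <- c(msg, "tieBreakOrder must contain cell-type labels")
    if (!object@depthReference %in% c("shallowest_nucleus", "stack_top"))
      msg <- c(msg, "unknown depthReference")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct ClassifierConfig
#'
#' Default thresholds sit midway between adjacent generator shape priors
#' (e.g. the 7 um stomata diameter cap lies between the 4--6 um stomata
#' prior and the 10--14 um pavement prior), so class separation holds by
#' construction on the default phantom; all are tunable for real data.
#' Depth is measured from the shallowest segmented nucleus by default, which
#' makes the cascade robust to mounting offset.
#'
#' @param epidermisMaxDepth um.
#' @param vascularMinDepth um.
#' @param stomataMaxEquivDiam um.
#' @param pavementMinEquivDiam um.
#' @param bundleSheathMinElongation a/b threshold.
#' @param vascularMinNeighborDensity neighbours within `rNb`.
#' @param rNb um.
#' @param tieBreakOrder class priority in the epidermal tie zone.
#' @param depthReference "shallowest_nucleus" or "stack_top".
#' @return A [ClassifierConfig-class] object.
#' @export
classifierConfig <- function(epidermisMaxDepth = 15, vascularMinDepth = 55,
                             stomataMaxEquivDiam = 7,
                             pavementMinEquivDiam = 9,
                             bundleSheathMinElongation = 2.0,
                             vascularMinNeighborDensity = 2, rNb = 24,
                             tieBreakOrder = c("stomata", "pavement"),
                             depthReference = c("shallowest_nucleus",
                                                "stack_top")) {
  new("ClassifierConfig", epidermisMaxDepth = epidermisMaxDepth,
      vascularMinDepth = vascularMinDepth,
      stomataMaxEquivDiam = stomataMaxEquivDiam,
      pavementMinEquivDiam = pavementMinEquivDiam,
      bundleSheathMinElongation = bundleSheathMinElongation,
      vascularMinNeighborDensity = vascularMinNeighborDensity, rNb = rNb,
      tieBreakOrder = tieBreakOrder,
      depthReference = match.arg(depthReference))
}

#' StainParams: histochemical stain segmentation parameters
#'
#' Colour rules: trypan blue fires where the blue channel dominates red by
#' `blueMargin`; DAB fires inside a brown hue window with a saturation
#' floor; chlorosis fires inside a yellow hue window. All rules are
#' intersected with the disk (or provided) mask.
#'
#' @slot stain "trypan_blue", "dab" or "chlorosis".
#' @slot pixelSize um per pixel.
#' @slot diskMode "auto_circle" or "provided_mask".
#' @slot blueMargin numeric, trypan-blue B-over-R margin (0--1 scale).
#' @slot hueWindow numeric(2), hue bounds in \[0,1\] for dab/chlorosis.
#' @slot saturationFloor numeric(1).
#' @aliases StainParams
#' @exportClass StainParams
setClass("StainParams",
  representation(stain = "character", pixelSize = "numeric",
                 diskMode = "character", blueMargin = "numeric",
                 hueWindow = "numeric", saturationFloor = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@stain %in% c("trypan_blue", "dab", "chlorosis"))
      msg <- c(msg, "unknown stain")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
    if (!object@diskMode %in% c("auto_circle", "provided_mask"))
      msg <- c(msg, "unknown diskMode")
    if (any(object@hueWindow < 0) || any(object@hueWindow > 1))
      msg <- c(msg, "hueWindow must lie in [0,1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct StainParams
#'
#' @param stain "trypan_blue", "dab" or "chlorosis".
#' @param pixelSize um per pixel.
#' @param diskMode "auto_circle" fits a circle to the non-white region;
#'   "provided_mask" uses a caller-supplied mask.
#' @param blueMargin trypan-blue rule margin.
#' @param hueWindow hue bounds; defaults per stain (brown for DAB, yellow
#'   for chlorosis).
#' @param saturationFloor minimum HSV saturation for hue-window rules.
#' @return A [StainParams-class] object.
#' @export
stainParams <- function(stain = c("trypan_blue", "dab", "chlorosis"),
                        pixelSize = 10, diskMode = c("auto_circle",
                                                     "provided_mask"),
                        blueMargin = 0.15, hueWindow = NULL,
                        saturationFloor = 0.35) {
  stain <- match.arg(stain)
  if (is.null(hueWindow))
    hueWindow <- switch(stain,
      trypan_blue = c(0.5, 0.8),   # unused by the blue-dominance rule
      dab = c(0.02, 0.13),
      chlorosis = c(0.12, 0.20))
  new("StainParams", stain = stain, pixelSize = pixelSize,
      diskMode = match.arg(diskMode), blueMargin = blueMargin,
      hueWindow = hueWindow, saturationFloor = saturationFloor)
}
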