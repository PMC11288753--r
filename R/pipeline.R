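#' Scene configuration for multi-image pipeline experiments
#'
#' A smaller field than the reference phantom, sized for batch runs: a
#' 192 x 192 x 40 voxel stack at 0.7 x 0.7 x 2 um (a 134 x 134 x 80 um
#' field) holding 88 nuclei — 10 stomata, 8 pavement, 60 spongy mesophyll,
#' 5 bundle sheath, 5 vascular. The mesophyll majority mirrors its role as
#' the feeding target, and `mesophyllDropout = 0.3` emulates the viability
#' loss under infestation. All other defaults are inherited from
#' [sceneConfig()].
#'
#' @param condition "control" or "infested".
#' @param seed integer seed.
#' @param ... overrides passed on to [sceneConfig()].
#' @return A [SceneConfig-class].
#' @export
pipelineSceneConfig <- function(condition = c("control", "infested"),
                                seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    imageShape = c(192L, 192L, 40L), voxelSize = c(0.7, 0.7, 2),
    counts = c(stomata = 10L, pavement = 8L, spongy_mesophyll = 60L,
               bundle_sheath = 5L, vascular_bundle = 5L),
    mesophyllDropout = 0.3)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  args$condition <- match.arg(condition)
  args$seed <- seed
  do.call(sceneConfig, args)
}

#' Configure an end-to-end experiment
#'
#' Bundles everything [runPipeline()] needs: the scene template (its
#' condition and seed are overwritten per image), the number of images per
#' condition, stage parameters, and whether the imaging stages are run.
#' With `render = TRUE` every image goes simulate - render - segment -
#' ratio - classify; with `render = FALSE` the per-image tables are taken
#' from generator truth (class labels and true ratios), which exercises the
#' statistical stages alone — used for large calibration studies where the
#' imaging stages would only re-measure what the phantoms already state.
#'
#' @param scene a [SceneConfig-class] template.
#' @param nImagesPerCondition images per condition (>= 2).
#' @param seed master seed; image i of the control arm uses scene seed
#'   `seed * 1000 + i`, of the infested arm `seed * 1000 + 500 + i`.
#' @param render run the imaging stages (see above).
#' @param segParams a [SegmentationParams-class].
#' @param ratioParams a [RatioParams-class].
#' @param classifier a [ClassifierConfig-class].
#' @param alpha significance level used in reporting.
#' @return list of class "fretleafExperiment".
#' @export
experimentConfig <- function(scene = pipelineSceneConfig(),
                             nImagesPerCondition = 8L, seed = 1L,
                             render = TRUE,
                             segParams = segmentationParams(),
                             ratioParams = fretleaf::ratioParams(),
                             classifier = classifierConfig(),
                             alpha = 0.05) {
  stopifnot(nImagesPerCondition >= 2)
  structure(list(scene = scene,
                 nImagesPerCondition = as.integer(nImagesPerCondition),
                 seed = as.integer(seed), render = render,
                 segParams = segParams, ratioParams = ratioParams,
                 classifier = classifier, alpha = alpha),
            class = "fretleafExperiment")
}

# process one image through the imaging stages; errors are annotated with
# the failing stage and image id
.processImage <- function(cfg, segParams, rp, classifier, imageId,
                          condition) {
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed on image '%s': %s", nm, imageId,
                   conditionMessage(e)), call. = FALSE))
  }
  truth <- stage("simulate", generateLeafScene(cfg))
  stack <- stage("render", renderStack(truth, cfg))
  labels <- stage("segment", segmentNuclei(stack, segParams))
  rec <- stage("features",
               extractFeatures(labels, stack, rNb = classifier@rNb))
  bg <- stage("background", estimateBackground(stack, labels))
  rec <- stage("ratio", computeEmissionRatios(rec, bg, rp))
  rec <- stage("classify", classifyNuclei(rec, classifier))
  rec$image <- imageId
  rec$condition <- condition
  truth$image <- imageId
  truth$condition <- condition
  list(records = rec, truth = truth)
}

# truth-level records: the generator's class and ratio stand in for the
# measured ones
.truthRecords <- function(truth, imageId, condition) {
  data.frame(id = truth$id, voxel_count = NA_integer_,
             cx = truth$cx, cy = truth$cy, cz = truth$cz,
             depth_z = truth$cz, equiv_diam = NA_real_,
             elongation = NA_real_, neighbor_density = NA_integer_,
             qc_flags = "", emission_ratio = truth$true_ratio,
             excluded = FALSE, cell_type = truth$class,
             image = imageId, condition = condition,
             stringsAsFactors = FALSE)
}

#' Run the end-to-end pipeline
#'
#' Simulates `nImagesPerCondition` control and infested acquisitions,
#' processes each through segmentation, ratiometry and cell typing (or
#' takes truth-level tables when `render = FALSE`), and assembles the
#' report: per-nucleus records, per-condition-and-class ratio summaries,
#' the per-class ratio increase, the per-class count comparison
#' (viability) and the per-class ratio comparison, plus a reproducibility
#' manifest. Fully deterministic given the experiment seed.
#'
#' @param config from [experimentConfig()].
#' @return list of class "fretleafReport": records, truth, summary,
#'   deltaByClass, countTable, countComparison, ratioComparison, manifest.
#' @seealso [writeReport()]
#' @export
runPipeline <- function(config = experimentConfig()) {
  stopifnot(inherits(config, "fretleafExperiment"))
  base <- (config$seed %% 1000000L) * 1000L
  allRec <- list(); allTruth <- list()
  for (condition in c("control", "infested")) {
    off <- if (condition == "control") 0L else 500L
    for (i in seq_len(config$nImagesPerCondition)) {
      cfg <- config$scene
      cfg@condition <- condition
      cfg@seed <- base + off + i
      imageId <- sprintf("%s_%02d", condition, i)
      if (config$render) {
        out <- .processImage(cfg, config$segParams, config$ratioParams,
                             config$classifier, imageId, condition)
        allRec[[imageId]] <- out$records
        allTruth[[imageId]] <- out$truth
      } else {
        truth <- generateLeafScene(cfg)
        truth$image <- imageId; truth$condition <- condition
        allRec[[imageId]] <- .truthRecords(truth, imageId, condition)
        allTruth[[imageId]] <- truth
      }
    }
  }
  records <- do.call(rbind, allRec)
  rownames(records) <- NULL
  truth <- do.call(rbind, allTruth)
  rownames(truth) <- NULL

  sumCond <- summarizeRatios(records, groupBy = "condition_cell_type")
  sumCtl <- summarizeRatios(records[records$condition == "control", ],
                            groupBy = "cell_type")
  sumInf <- summarizeRatios(records[records$condition == "infested", ],
                            groupBy = "cell_type")
  delta <- ratioIncreaseByClass(sumCtl, sumInf)
  countTab <- nucleusCountTable(records)
  countCmp <- countComparison(countTab)
  ratioCmp <- ratioComparison(records)

  manifest <- list(
    package = "fretleaf",
    version = as.character(packageVersion("fretleaf")),
    seed = config$seed, nImagesPerCondition = config$nImagesPerCondition,
    render = config$render, alpha = config$alpha,
    scene = .s4AsList(config$scene),
    segParams = .s4AsList(config$segParams),
    ratioParams = .s4AsList(config$ratioParams),
    classifier = .s4AsList(config$classifier))

  structure(list(records = records, truth = truth, summary = sumCond,
                 deltaByClass = delta, countTable = countTab,
                 countComparison = countCmp, ratioComparison = ratioCmp,
                 manifest = manifest),
            class = "fretleafReport")
}

# flatten an S4 config into a plain list for YAML/JSON echo
.s4AsList <- function(obj) {
  out <- lapply(methods::slotNames(obj), function(sn) {
    v <- slot(obj, sn)
    if (is.data.frame(v)) as.list(v) else v
  })
  names(out) <- methods::slotNames(obj)
  out
}

#' Write a pipeline report to disk
#'
#' Emits the per-stage CSVs (per-nucleus records — the "Result Table"
#' analog — ratio summaries, per-class deltas, count and ratio
#' comparisons) and the JSON run manifest. Re-running the same experiment
#' configuration reproduces the files byte for byte.
#'
#' @param report from [runPipeline()].
#' @param outDir output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
writeReport <- function(report, outDir) {
  stopifnot(inherits(report, "fretleafReport"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(df, nm) {
    p <- file.path(outDir, nm)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$records, "records.csv")
  wr(report$summary, "ratio_summary.csv")
  wr(report$deltaByClass, "delta_by_class.csv")
  wr(report$countTable, "count_table.csv")
  wr(report$countComparison, "count_comparison.csv")
  wr(report$ratioComparison, "ratio_comparison.csv")
  mp <- file.path(outDir, "manifest.json")
  jsonlite::write_json(report$manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, mp)
  invisible(paths)
}
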