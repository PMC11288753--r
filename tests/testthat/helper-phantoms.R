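# Shared fixtures, all generated in code.

# small scene for fast unit tests: 96 x 96 x 40 voxels at 1 x 1 x 2 um
smallScene <- function(counts = c(stomata = 3L, pavement = 2L,
                                  spongy_mesophyll = 3L,
                                  bundle_sheath = 2L,
                                  vascular_bundle = 3L),
                       seed = 1L, ...) {
  sceneConfig(imageShape = c(96L, 96L, 40L), voxelSize = c(1, 1, 2),
              counts = counts, seed = seed, ...)
}

# single hand-built nucleus in an otherwise empty stack
singleNucleusTruth <- function(sa, sb, sc, ratio = 2, T = 300, A = 400,
                               cx = 48, cy = 48, cz = 40, theta = 0) {
  data.frame(id = 1L, class = "spongy_mesophyll", cx = cx, cy = cy,
             cz = cz, sa = sa, sb = sb, sc = sc, theta = theta,
             true_ratio = ratio, emission_T = T, acceptor_A = A,
             stringsAsFactors = FALSE)
}

emptySceneConfig <- function(...) {
  smallScene(counts = c(stomata = 0L, pavement = 0L,
                        spongy_mesophyll = 0L, bundle_sheath = 0L,
                        vascular_bundle = 0L), ...)
}

# match pipeline records to truth rows by nearest centroid; returns the
# truth row index for each record
matchToTruth <- function(records, truth) {
  P <- as.matrix(records[, c("cx", "cy", "cz")])
  Tm <- as.matrix(truth[, c("cx", "cy", "cz")])
  D <- sqrt(pmax(outer(rowSums(P^2), rowSums(Tm^2), "+") -
                   2 * P %*% t(Tm), 0))
  apply(D, 1, which.min)
}

# run segment + features + ratio + classify on one rendered scene
processScene <- function(cfg, rNb = classifierConfig()@rNb) {
  truth <- generateLeafScene(cfg)
  stk <- renderStack(truth, cfg)
  lab <- segmentNuclei(stk)
  rec <- extractFeatures(lab, stk, rNb = rNb)
  bg <- estimateBackground(stk, lab)
  rec <- computeEmissionRatios(rec, bg)
  rec <- classifyNuclei(rec)
  list(truth = truth, stack = stk, labels = lab, records = rec)
}

# the 20-seed reference phantom suite used by the segmentation and
# cell-typing validation; computed once per session and cached
.suiteCache <- new.env(parent = emptyenv())
referencePhantomSuite <- function(nSeeds = 20L) {
  key <- paste0("suite", nSeeds)
  if (!is.null(.suiteCache[[key]])) return(.suiteCache[[key]])
  out <- lapply(seq_len(nSeeds), function(s) {
    cfg <- sceneConfig(seed = 9000L + s)
    truth <- generateLeafScene(cfg)
    stk <- renderStack(truth, cfg)
    lab <- segmentNuclei(stk)
    L <- labelData(lab)
    vs <- voxelSize(lab)
    ctr <- cbind(round(truth$cx / vs[1] + 0.5),
                 round(truth$cy / vs[2] + 0.5),
                 round(truth$cz / vs[3] + 0.5))
    labAt <- L[ctr]
    rec <- extractFeatures(lab, stk, rNb = classifierConfig()@rNb)
    rec <- computeEmissionRatios(rec, estimateBackground(stk, lab))
    rec <- classifyNuclei(rec)
    cm <- confusionMatrix(rec, truth)
    list(nLabels = nLabels(lab), nTruth = nrow(truth),
         nMatched = sum(labAt > 0),
         nDistinct = length(unique(labAt[labAt > 0])),
         confusion = cm$matrix, accuracy = cm$accuracy,
         unmatchedTruth = cm$unmatchedTruth,
         unmatchedPredicted = cm$unmatchedPredicted)
  })
  .suiteCache[[key]] <- out
  out
}
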