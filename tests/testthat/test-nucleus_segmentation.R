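test_that("separated phantoms segment one label per truth nucleus", {
  cfg <- smallScene(seed = 12, noiseModel = "none",
                    backgroundLevel = c(0, 0, 0))
  truth <- generateLeafScene(cfg)
  stk <- renderStack(truth, cfg)
  lab <- segmentNuclei(stk)
  expect_equal(nLabels(lab), nrow(truth))
  L <- labelData(lab)
  vs <- voxelSize(lab)
  labAt <- L[cbind(round(truth$cx / vs[1] + 0.5),
                   round(truth$cy / vs[2] + 0.5),
                   round(truth$cz / vs[3] + 0.5))]
  expect_true(all(labAt > 0))
  expect_equal(length(unique(labAt)), nrow(truth))
})

test_that("an all-zero AxAm channel yields zero labels", {
  a <- array(0, c(32, 32, 8))
  stk <- FretStack(a, a, a, voxelSize = c(1, 1, 2))
  expect_equal(nLabels(segmentNuclei(stk)), 0)
})

test_that("the volume filter removes sub-minimum nuclei", {
  cfg <- emptySceneConfig(noiseModel = "none", backgroundLevel = c(0, 0, 0))
  # one normal nucleus and one rasterising to a single 2 um^3 voxel,
  # below the 8 um^3 floor (voxel-centred so it is visible at all)
  truth <- rbind(singleNucleusTruth(5, 4, 3, cx = 25, cy = 25),
                 singleNucleusTruth(0.6, 0.6, 1.05, cx = 69.5, cy = 69.5,
                                    cz = 39))
  truth$id <- 1:2
  stk <- renderStack(truth, cfg)
  # unsmoothed fixed threshold so only the volume filter differs
  pDef <- segmentationParams(gaussianSigma = 0, thresholdMethod = "fixed",
                             fixedThreshold = 50)
  expect_equal(nLabels(segmentNuclei(stk, pDef)), 1)
  # with the floor lowered both survive
  pLow <- segmentationParams(gaussianSigma = 0, thresholdMethod = "fixed",
                             fixedThreshold = 50, minVolume = 1)
  expect_equal(nLabels(segmentNuclei(stk, pLow)), 2)
})

test_that("Otsu label count is invariant to monotone intensity rescaling", {
  cfg <- smallScene(seed = 13, noiseModel = "none")
  truth <- generateLeafScene(cfg)
  stk <- renderStack(truth, cfg)
  n1 <- nLabels(segmentNuclei(stk))
  scaled <- FretStack(channel(stk, "DxDm"), channel(stk, "DxAm"),
                      channel(stk, "AxAm") * 7, voxelSize = voxelSize(stk))
  expect_equal(nLabels(segmentNuclei(scaled)), n1)
})

test_that("a fixed threshold above the maximum warns and yields no labels", {
  cfg <- smallScene(seed = 14, noiseModel = "none")
  stk <- renderStack(generateLeafScene(cfg), cfg)
  p <- segmentationParams(thresholdMethod = "fixed", fixedThreshold = 1e6)
  expect_warning(lab <- segmentNuclei(stk, p), "threshold")
  expect_equal(nLabels(lab), 0)
})

test_that("second-moment ellipsoid recovers axis lengths and elongation", {
  # isotropic 1 um grid, no smoothing, fixed threshold: the mask is the
  # exact rasterised ellipsoid, isolating the moment estimator itself
  cfg <- sceneConfig(imageShape = c(96L, 96L, 80L), voxelSize = c(1, 1, 1),
                     counts = c(stomata = 0L, pavement = 0L,
                                spongy_mesophyll = 0L, bundle_sheath = 0L,
                                vascular_bundle = 0L),
                     noiseModel = "none", backgroundLevel = c(0, 0, 0))
  halfMax <- segmentationParams(gaussianSigma = 0,
                                thresholdMethod = "fixed",
                                fixedThreshold = 50)
  truth <- singleNucleusTruth(6, 3, 2, theta = 0)
  stk <- renderStack(truth, cfg)
  rec <- extractFeatures(segmentNuclei(stk, halfMax), stk)
  expect_equal(nrow(rec), 1)
  expect_lt(abs(rec$axis_a - 6) / 6, 0.10)
  expect_lt(abs(rec$axis_b - 3) / 3, 0.10)
  expect_lt(abs(rec$axis_c - 2) / 2, 0.15)
  expect_equal(rec$elongation, 2, tolerance = 0.15)
  # a sphere has unit elongation and flatness
  sph <- singleNucleusTruth(4, 4, 4)
  stk2 <- renderStack(sph, cfg)
  rec2 <- extractFeatures(segmentNuclei(stk2, halfMax), stk2)
  expect_equal(rec2$elongation, 1, tolerance = 0.1)
  expect_equal(rec2$flatness, 1, tolerance = 0.15)
})

test_that("neighbour density counts centroids within the radius", {
  cfg <- emptySceneConfig(noiseModel = "none", backgroundLevel = c(0, 0, 0))
  truth <- rbind(singleNucleusTruth(2, 2, 1.5, cx = 40, cy = 48),
                 singleNucleusTruth(2, 2, 1.5, cx = 45, cy = 48))
  truth$id <- 1:2
  stk <- renderStack(truth, cfg)
  rec <- extractFeatures(segmentNuclei(stk), stk, rNb = 10)
  expect_equal(rec$neighbor_density, c(1L, 1L))
  rec2 <- extractFeatures(segmentNuclei(stk), stk, rNb = 3)
  expect_equal(rec2$neighbor_density, c(0L, 0L))
})

test_that("feature extraction is deterministic", {
  cfg <- smallScene(seed = 15)
  stk <- renderStack(generateLeafScene(cfg), cfg)
  lab <- segmentNuclei(stk)
  expect_identical(extractFeatures(lab, stk, 24),
                   extractFeatures(lab, stk, 24))
})

test_that("background estimation returns the per-channel median", {
  cfg <- smallScene(seed = 16, noiseModel = "none",
                    backgroundLevel = c(5, 7, 9))
  stk <- renderStack(generateLeafScene(cfg), cfg)
  lab <- segmentNuclei(stk)
  expect_equal(estimateBackground(stk, lab),
               c(DxDm = 5, DxAm = 7, AxAm = 9))
  # zero background stays zero
  cfg0 <- smallScene(seed = 16, noiseModel = "none",
                     backgroundLevel = c(0, 0, 0))
  stk0 <- renderStack(generateLeafScene(cfg0), cfg0)
  expect_equal(estimateBackground(stk0, segmentNuclei(stk0)),
               c(DxDm = 0, DxAm = 0, AxAm = 0))
  # gaussian read noise around level 10: median within 0.1
  cfgN <- smallScene(seed = 16, noiseModel = "gaussian", gaussianSD = 2,
                     backgroundLevel = c(10, 10, 10))
  stkN <- renderStack(generateLeafScene(cfgN), cfgN, quantize = FALSE)
  bg <- estimateBackground(stkN, segmentNuclei(stkN))
  expect_true(all(abs(bg - 10) < 0.1))
})

test_that("a fully labelled stack cannot provide a background", {
  a <- array(1, c(8, 8, 4))
  stk <- FretStack(a, a, a, voxelSize = c(1, 1, 1))
  lab <- LabelMap(array(1L, c(8, 8, 4)), c(1, 1, 1))
  expect_error(estimateBackground(stk, lab), "unlabelled")
})

test_that("single-voxel objects are flagged degenerate", {
  a <- array(0, c(16, 16, 6))
  stk <- FretStack(a, a, a + 1, voxelSize = c(1, 1, 2))
  L <- array(0L, c(16, 16, 6))
  L[8, 8, 3] <- 1L
  rec <- extractFeatures(LabelMap(L, c(1, 1, 2)), stk)
  expect_match(rec$qc_flags, "degenerate_shape")
  expect_equal(c(rec$axis_a, rec$axis_b, rec$axis_c), c(2, 1, 1))
})

test_that("the volume-wide Otsu threshold agrees with the EBImage oracle", {
  set.seed(42)
  # bimodal intensity field, continuous values (no bin-edge ties)
  v <- c(rnorm(6000, 30, 6), rnorm(600, 300, 25))
  v <- pmax(v, 0)
  arr <- array(v[1:6400], c(16, 20, 20))
  ours <- fretleaf:::.otsuGlobal(arr)
  hi <- max(arr)
  ref <- EBImage::otsu(matrix(as.numeric(arr) / hi, nrow = 16),
                       range = c(0, 1), levels = 256L) * hi
  # same 256-level histogram maximisation: agree to one bin width
  expect_lt(abs(ours - ref), hi / 256)
})
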