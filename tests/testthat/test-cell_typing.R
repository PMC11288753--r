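# feature rows with direct control over the classifier inputs
featureRow <- function(depth, diam, elong = 1.2, nd = 0L) {
  data.frame(id = 1L, depth_z = depth, equiv_diam = diam,
             elongation = elong, neighbor_density = nd, qc_flags = "",
             excluded = FALSE, cell_type = NA_character_,
             stringsAsFactors = FALSE)
}

# stack_top reference so depth values are taken at face value
cfgAbs <- classifierConfig(depthReference = "stack_top")

test_that("the rule cascade assigns the expected classes", {
  expect_equal(classifyNuclei(featureRow(5, 5), cfgAbs)$cell_type,
               "stomata")
  expect_equal(classifyNuclei(featureRow(5, 12), cfgAbs)$cell_type,
               "pavement")
  expect_equal(classifyNuclei(featureRow(60, 5, elong = 1.2, nd = 4),
                              cfgAbs)$cell_type, "vascular_bundle")
  expect_equal(classifyNuclei(featureRow(40, 8, elong = 2.5),
                              cfgAbs)$cell_type, "bundle_sheath")
  expect_equal(classifyNuclei(featureRow(30, 8, elong = 1.1),
                              cfgAbs)$cell_type, "spongy_mesophyll")
  # epidermal size tie zone resolves by the configured priority
  expect_equal(classifyNuclei(featureRow(5, 8), cfgAbs)$cell_type,
               "stomata")
  cfgPav <- classifierConfig(depthReference = "stack_top",
                             tieBreakOrder = c("pavement", "stomata"))
  expect_equal(classifyNuclei(featureRow(5, 8), cfgPav)$cell_type,
               "pavement")
})

test_that("classification is deterministic and exhaustive", {
  set.seed(77)
  rec <- do.call(rbind, lapply(1:200, function(i)
    featureRow(runif(1, 0, 80), runif(1, 2, 16), runif(1, 1, 4),
               sample(0:6, 1))))
  rec$id <- seq_len(nrow(rec))
  a <- classifyNuclei(rec, cfgAbs)
  b <- classifyNuclei(rec, cfgAbs)
  expect_identical(a$cell_type, b$cell_type)
  expect_true(all(a$cell_type %in% cellTypes()))
  expect_false(anyNA(a$cell_type))
})

test_that("widening the stomata diameter cap never loses stomata labels", {
  set.seed(78)
  rec <- do.call(rbind, lapply(1:150, function(i)
    featureRow(runif(1, 0, 80), runif(1, 2, 16), runif(1, 1, 4),
               sample(0:6, 1))))
  rec$id <- seq_len(nrow(rec))
  caps <- c(5, 6, 7, 8, 9)
  nSto <- vapply(caps, function(cap) {
    cfg <- classifierConfig(depthReference = "stack_top",
                            stomataMaxEquivDiam = cap)
    sum(classifyNuclei(rec, cfg)$cell_type == "stomata")
  }, numeric(1))
  expect_true(all(diff(nSto) >= 0))
})

test_that("missing features and empty inputs are errors", {
  r <- featureRow(5, 5)
  r$elongation <- NA_real_
  expect_error(classifyNuclei(r, cfgAbs), "elongation")
  r2 <- featureRow(5, 5)[, setdiff(names(featureRow(5, 5)),
                                   "neighbor_density")]
  expect_error(classifyNuclei(r2, cfgAbs), "neighbor_density")
  expect_error(classifyNuclei(featureRow(5, 5)[0, ], cfgAbs), "empty")
})

test_that("class counts sum to the number of retained nuclei", {
  cfg <- smallScene(seed = 19)
  out <- processScene(cfg)
  counts <- cellTypeCounts(out$records)
  expect_equal(sum(counts), sum(!out$records$excluded))
})

test_that("an all-mesophyll scene classifies as mesophyll", {
  # absolute depth reference: with a single tissue layer present there is
  # no epidermal anchor to measure relative depth from
  cfg <- smallScene(counts = c(stomata = 0L, pavement = 0L,
                               spongy_mesophyll = 8L, bundle_sheath = 0L,
                               vascular_bundle = 0L), seed = 20)
  truth <- generateLeafScene(cfg)
  stk <- renderStack(truth, cfg)
  rec <- extractFeatures(segmentNuclei(stk), stk, rNb = 24)
  rec <- classifyNuclei(rec, classifierConfig(depthReference = "stack_top"))
  expect_true(all(rec$cell_type == "spongy_mesophyll"))
})

test_that("the confusion matrix is identity-patterned on perfect input", {
  truth <- data.frame(id = 1:4,
                      class = c("stomata", "pavement", "stomata",
                                "vascular_bundle"),
                      cx = c(10, 30, 50, 70), cy = 10, cz = 10)
  rec <- data.frame(cx = truth$cx, cy = truth$cy, cz = truth$cz,
                    cell_type = truth$class)
  cm <- confusionMatrix(rec, truth)
  expect_equal(cm$accuracy, 1.0)
  expect_equal(sum(cm$matrix) - sum(diag(cm$matrix)), 0)
  expect_equal(cm$unmatchedTruth, 0)
  # collapsing all predictions into one class bounds accuracy by its share
  rec2 <- rec; rec2$cell_type <- "spongy_mesophyll"
  cm2 <- confusionMatrix(rec2, truth)
  expect_equal(cm2$accuracy, 0)
  expect_equal(sum(cm2$matrix[, "spongy_mesophyll"]), 4)
})

test_that("unmatched nuclei are reported, not absorbed", {
  truth <- data.frame(id = 1:2, class = c("stomata", "pavement"),
                      cx = c(10, 90), cy = 10, cz = 10)
  rec <- data.frame(cx = 10, cy = 10, cz = 10, cell_type = "stomata")
  cm <- confusionMatrix(rec, truth)
  expect_equal(cm$nMatched, 1)
  expect_equal(cm$unmatchedTruth, 1)
  expect_equal(cm$unmatchedPredicted, 0)
})
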