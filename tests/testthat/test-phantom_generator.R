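test_that("scene truth table has the configured composition", {
  cfg <- sceneConfig(counts = c(stomata = 10, pavement = 10,
                                spongy_mesophyll = 10, bundle_sheath = 5,
                                vascular_bundle = 5),
                     condition = "control", seed = 21)
  truth <- generateLeafScene(cfg)
  expect_equal(nrow(truth), 40)
  expect_equal(sum(truth$class == "stomata"), 10)
  expect_false(any(duplicated(truth$id)))
  expect_true(all(truth$true_ratio > 0))
  # geometry inside the stack
  field <- cfg@imageShape * cfg@voxelSize
  expect_true(all(truth$cz >= 0 & truth$cz <= field[3]))
  expect_true(all(truth$sa >= truth$sb))
})

test_that("mesophyll dropout matches its binomial expectation", {
  # dropout applies only to spongy mesophyll under infestation; a
  # placement-light scene keeps the Monte-Carlo cheap
  counts <- c(stomata = 0L, pavement = 0L, spongy_mesophyll = 10L,
              bundle_sheath = 0L, vascular_bundle = 0L)
  kept <- vapply(1:300, function(s) {
    cfg <- smallScene(counts = counts, condition = "infested",
                      mesophyllDropout = 0.4, seed = 3000L + s)
    nrow(generateLeafScene(cfg))
  }, numeric(1))
  # binomial expectation 10 * 0.6 = 6.0; se of the mean ~ 0.09
  expect_equal(mean(kept), 6.0, tolerance = 0.08)
})

test_that("zero dropout gives condition-invariant class counts", {
  for (s in c(5, 6)) {
    tc <- generateLeafScene(smallScene(seed = s, condition = "control",
                                       mesophyllDropout = 0))
    ti <- generateLeafScene(smallScene(seed = s, condition = "infested",
                                       mesophyllDropout = 0))
    expect_equal(table(tc$class), table(ti$class))
  }
})

test_that("generation and rendering are deterministic given the seed", {
  cfg <- smallScene(seed = 17, condition = "infested",
                    mesophyllDropout = 0.3)
  t1 <- generateLeafScene(cfg)
  t2 <- generateLeafScene(cfg)
  expect_identical(t1, t2)
  s1 <- renderStack(t1, cfg)
  s2 <- renderStack(t2, cfg)
  expect_identical(s1@channels, s2@channels)
  r1 <- renderStack(t1, cfg, quantize = FALSE)
  r2 <- renderStack(t2, cfg, quantize = FALSE)
  expect_identical(r1@channels, r2@channels)
})

test_that("the ratiometric partition recovers R exactly without noise", {
  cfg <- emptySceneConfig(noiseModel = "none", backgroundLevel = c(0, 0, 0))
  truth <- singleNucleusTruth(sa = 5, sb = 4, sc = 3, ratio = 2.0, T = 300)
  stk <- renderStack(truth, cfg, quantize = FALSE)
  inside <- channel(stk, "AxAm") > 0
  expect_true(any(inside))
  expect_true(all(channel(stk, "DxDm")[inside] == 100))
  expect_true(all(channel(stk, "DxAm")[inside] == 200))
  # R = 1 makes the two donor-excitation channels identical
  t1 <- singleNucleusTruth(sa = 5, sb = 4, sc = 3, ratio = 1.0)
  s1 <- renderStack(t1, cfg, quantize = FALSE)
  in1 <- channel(s1, "AxAm") > 0
  expect_equal(channel(s1, "DxAm")[in1], channel(s1, "DxDm")[in1])
})

test_that("DxDm + DxAm conserves T voxelwise inside nuclei", {
  cfg <- smallScene(seed = 9, noiseModel = "none",
                    backgroundLevel = c(0, 0, 0))
  truth <- generateLeafScene(cfg)
  stk <- renderStack(truth, cfg, quantize = FALSE)
  inside <- channel(stk, "AxAm") > 0
  total <- channel(stk, "DxDm")[inside] + channel(stk, "DxAm")[inside]
  expect_true(all(total > 0))
  # every inside voxel's sum equals one of the per-nucleus T values
  expect_true(all(vapply(unique(round(total, 6)), function(v)
    any(abs(truth$emission_T - v) < 1e-6), logical(1))))
})

test_that("increasing a class delta strictly increases its mean ratio", {
  lowCfg <- smallScene(seed = 31, condition = "infested",
                       mesophyllDropout = 0,
                       infestedDelta = c(stomata = 0.1, pavement = 0.1,
                                         spongy_mesophyll = 0.1,
                                         bundle_sheath = 0.1,
                                         vascular_bundle = 0.1))
  hiCfg <- smallScene(seed = 31, condition = "infested",
                      mesophyllDropout = 0,
                      infestedDelta = c(stomata = 0.6, pavement = 0.1,
                                        spongy_mesophyll = 0.1,
                                        bundle_sheath = 0.1,
                                        vascular_bundle = 0.1))
  lo <- generateLeafScene(lowCfg)
  hi <- generateLeafScene(hiCfg)
  mlo <- mean(lo$true_ratio[lo$class == "stomata"])
  mhi <- mean(hi$true_ratio[hi$class == "stomata"])
  expect_gt(mhi, mlo)
})

test_that("overlapping nuclei abort rendering", {
  cfg <- emptySceneConfig(noiseModel = "none")
  truth <- rbind(singleNucleusTruth(5, 4, 3),
                 singleNucleusTruth(5, 4, 3, cx = 50))
  truth$id <- 1:2
  expect_error(renderStack(truth, cfg), "overlap")
})

test_that("impression truth matches the requested pore field", {
  imp <- generateImpression(nPores = 30, seed = 8)
  expect_equal(nrow(imp$truth), 30)
  expect_equal(imp$fieldAreaMm2, 0.5)
  expect_equal(nrow(imp$truth) / imp$fieldAreaMm2, 60)  # pores per mm^2
  expect_true(all(imp$truth$width <= imp$truth$length))
  # unit aperture range yields circles
  circ <- generateImpression(nPores = 5, apertureRatioRange = c(1, 1),
                             seed = 3)
  expect_true(all(circ$truth$aperture_ratio == 1))
  # determinism: identical image on regeneration
  i1 <- generateImpression(nPores = 12, seed = 44)
  i2 <- generateImpression(nPores = 12, seed = 44)
  expect_identical(i1$image, i2$image)
})

test_that("stained disks hit the requested fraction with exact truth", {
  d0 <- generateStainedDisk(diskRadiusPx = 80, stainedFraction = 0,
                            seed = 2)
  expect_equal(d0$stainedPx, 0)
  d <- generateStainedDisk(diskRadiusPx = 200, stainedFraction = 0.25,
                           seed = 2)
  expect_equal(d$stainedPx, sum(d$mask))
  expect_lt(abs(d$fraction - 0.25), 0.01)
  expect_lt(abs(d$stainedPx - 0.25 * pi * 200^2) / (0.25 * pi * 200^2),
            0.02)
  # same geometry seed, different stain: identical mask, different colour
  a <- generateStainedDisk(100, 0.2, stain = "trypan_blue", seed = 7)
  b <- generateStainedDisk(100, 0.2, stain = "dab", seed = 7)
  expect_identical(a$mask, b$mask)
  expect_false(identical(a$image, b$image))
  expect_error(generateStainedDisk(100, 0.9, seed = 1), "packing")
})
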