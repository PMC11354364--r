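# small disc sizes keep these tests fast; the published presets are exercised
# in the acceptance suite

test_that("presets carry the published disc size and threshold", {
  p <- cellLinePreset("tov21g")
  expect_identical(p@discSize, 20L)
  expect_identical(p@threshold, 92L)
  s <- cellLinePreset("skov3")
  expect_identical(s@discSize, 50L)
  expect_identical(s@threshold, 92L)
  over <- cellLinePreset("tov21g", threshold = 120L)
  expect_identical(over@threshold, 120L)
  expect_identical(over@discSize, 20L)
})

test_that("a constant image segments as one full-frame wound", {
  img <- grayImage(matrix(128L, 64, 64))
  m <- suppressWarnings(segmentWound(img, segmentationParams(discSize = 8)))
  expect_equal(areaFraction(m), 1)
  expect_identical(m@nComponentsKept, 1L)
})

test_that("confluent textured fields yield near-zero wound area", {
  for (seed in 1:3) {
    sim <- simulateScratchImage(width = 300, height = 72, woundFrac = 0,
                                seed = seed)
    m <- segmentWound(sim$image, segmentationParams(discSize = 8))
    expect_lte(areaFraction(m), 0.01)
  }
})

test_that("synthetic scratches are recovered at small wound fractions", {
  # band width = 5 x disc size; the regime where the fixed-threshold edge
  # offset is small relative to the frame
  for (seed in 1:5) {
    sim <- simulateScratchImage(width = 400, height = 72, woundFrac = 0.1,
                                seed = seed)
    m <- segmentWound(sim$image, segmentationParams(discSize = 8))
    expect_lt(abs(areaFraction(m) - areaFraction(sim$truth)), 0.03)
  }
})

test_that("the wound candidate grows monotonically with the threshold", {
  for (seed in 1:5) {
    sim <- simulateScratchImage(width = 200, height = 60, woundFrac = 0.25,
                                seed = seed, edgeRoughness = 2)
    resc <- pixels(rescaleEntropy(localEntropy(sim$image, 8)))
    lower <- resc < 60L
    upper <- resc < 140L
    expect_true(all(upper[lower]))  # candidate at 60 is a subset of at 140
  }
})

test_that("segmentation commutes with frame flips", {
  for (seed in c(2, 4)) {
    sim <- simulateScratchImage(width = 220, height = 64, woundFrac = 0.3,
                                seed = seed)
    p <- segmentationParams(discSize = 8)
    m <- pixels(segmentWound(sim$image, p))
    mh <- pixels(segmentWound(grayImage(flipH(pixels(sim$image))), p))
    mv <- pixels(segmentWound(grayImage(flipV(pixels(sim$image))), p))
    expect_identical(mh, flipH(m))
    expect_identical(mv, flipV(m))
  }
})

test_that("simulated closure yields non-increasing estimated area", {
  sim <- simulateScratchSeries(width = 500, height = 72, woundFrac = 0.4,
                               closureFracs = seq(1, 0.25, length.out = 6),
                               times = 0:5 * 8, seed = 6)
  est <- vapply(sim$images, function(im)
    areaFraction(segmentWound(im, segmentationParams(discSize = 8))),
    numeric(1))
  expect_true(all(diff(est) <= 0.02))
})

test_that("manual overrides replace, intersect or union and set the flag", {
  sim <- simulateScratchImage(width = 160, height = 48, woundFrac = 0.3,
                              seed = 1)
  m <- segmentWound(sim$image, segmentationParams(discSize = 8))
  same <- applyOverride(m, pixels(m))
  expect_identical(pixels(same), pixels(m))  # idempotent
  expect_true(same@overridden)
  none <- applyOverride(m, matrix(FALSE, 48, 160))
  expect_identical(woundArea(none), 0L)
  full <- applyOverride(m, matrix(TRUE, 48, 160))
  expect_equal(areaFraction(full), 1)
  inter <- applyOverride(m, matrix(TRUE, 48, 160), mode = "intersect")
  expect_identical(pixels(inter), pixels(m))
  expect_error(applyOverride(m, matrix(TRUE, 3, 3)), "dimensions")
})

test_that("polygon ROIs rasterize to the enclosed pixels", {
  m <- new("WoundMask", pixels = matrix(FALSE, 20, 30),
           nComponentsKept = 0L, overridden = FALSE)
  # axis-aligned rectangle spanning rows 5..10, cols 8..20
  poly <- cbind(c(4.5, 4.5, 10.5, 10.5), c(7.5, 20.5, 20.5, 7.5))
  out <- applyOverride(m, poly)
  ref <- matrix(FALSE, 20, 30)
  ref[5:10, 8:20] <- TRUE
  expect_identical(pixels(out), ref)
  expect_error(applyOverride(m, cbind(c(1, 25, 10), c(1, 2, 3))), "bounds")
})
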