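test_that("sampled weights respect the breed's gender-conditional ranges", {
  pm <- pureMysoreBreed()
  withr::with_seed(11L, {
    wm <- sampleWeight(pm, "male", 500)
    wf <- sampleWeight(pm, 0, 500)
  })
  expect_true(all(wm >= 0.8 & wm <= 1.1))
  expect_true(all(wf >= 1.2 & wf <= 1.4))
  # Pure Mysore supports are disjoint: weight alone separates the genders
  expect_lt(max(wm), min(wf))
  # quantized to the 0.01 g load-sensor resolution
  expect_true(all(abs(wm / 0.01 - round(wm / 0.01)) < 1e-9))
})

test_that("degenerate weight range collapses to a single value", {
  sp <- breedSpec("deg", c(1.0, 1.0), c(1.5, 1.5))
  withr::with_seed(1L, w <- sampleWeight(sp, "female", 20))
  expect_true(all(w == 1.5))
})

test_that("uniform weight sampler matches its stated support and mean", {
  csr2 <- csr2Breed()
  withr::with_seed(42L, w <- sampleWeight(csr2, "female", 10000))
  expect_gte(min(w), 1.5)
  expect_lte(max(w), 2.0)
  expect_equal(mean(w), 1.75, tolerance = 0.01)
})

test_that("invalid gender is rejected with a labelled error", {
  expect_error(sampleWeight(csr2Breed(), 2), "gender")
  expect_error(sampleWeight(csr2Breed(), "hermaphrodite"), "gender")
})

test_that("breed spec validity enforces the bulkier-female invariant", {
  expect_error(breedSpec("bad", c(1.0, 0.9), c(1.2, 1.4)), "lo <= hi")
  expect_error(breedSpec("bad", c(0.8, 1.1), c(1.2, 1.4),
                         maleSizeScale = 17, femaleSizeScale = 16),
               "bulkier")
})

test_that("noiseless fiber-free render has exactly two intensity levels", {
  img <- withr::with_seed(1L, renderSilhouette(16, waist = 0,
                                               fiberDensity = 0, noiseSd = 0))
  expect_identical(sort(unique(as.vector(img))), c(25L, 230L))
})

test_that("rendered foreground area matches the closed-form superellipse area", {
  for (scale in c(20, 30, 45)) {
    img <- withr::with_seed(2L, renderSilhouette(scale, waist = 0,
                                                 fiberDensity = 0, noiseSd = 0,
                                                 imageSize = 2 * scale + 12))
    fg <- sum(img < 128)
    analytic <- 4 * scale * (scale / 1.7) * gamma(1 + 1 / 2.5)^2 / gamma(1 + 2 / 2.5)
    expect_equal(fg, analytic, tolerance = 0.02)
  }
})

test_that("rendering is bit-identical under a fixed seed", {
  a <- withr::with_seed(7L, renderSilhouette(16.6))
  b <- withr::with_seed(7L, renderSilhouette(16.6))
  expect_identical(a, b)
})

test_that("shapes exceeding the frame are rejected", {
  expect_error(renderSilhouette(40, imageSize = 64), "frame")
})

test_that("generated batches have the requested composition and determinism", {
  b <- generateBatch(csr2Breed(), 47, 44, seed = 1)
  expect_equal(nCocoons(b), 91)
  expect_equal(sum(cocoonLabels(b) == 1), 47)
  expect_equal(sum(cocoonLabels(b) == 0), 44)
  expect_false(anyDuplicated(cocoonInfo(b)$index) > 0)
  b2 <- generateBatch(csr2Breed(), 47, 44, seed = 1)
  expect_identical(cocoonImages(b), cocoonImages(b2))
  expect_identical(cocoonInfo(b), cocoonInfo(b2))
  b3 <- generateBatch(pureMysoreBreed(), 35, 41, seed = 7)
  expect_equal(nCocoons(b3), 76)
})

test_that("an empty batch writes a valid empty ground-truth CSV", {
  b <- generateBatch(csr2Breed(), 0, 0, seed = 1)
  expect_equal(nCocoons(b), 0)
  dir <- withr::local_tempdir()
  writeBatch(b, dir)
  truth <- readTruthCSV(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), 0)
  expect_named(truth, c("index", "breed", "weight_g", "label"))
})

test_that("batch export round-trips images and truth losslessly", {
  b <- generateBatch(pureMysoreBreed(), 2, 2, seed = 3)
  dir <- withr::local_tempdir()
  writeBatch(b, dir)
  truth <- readTruthCSV(file.path(dir, "truth.csv"))
  expect_equal(truth$weight_g, cocoonWeights(b))
  img1 <- readCocoonImage(file.path(dir, "1.png"))
  expect_identical(img1, cocoonImages(b)[[1]])
})

test_that("multi-cocoon images violate the gate and keep shells separate", {
  img <- generateMultiCocoonImage(csr2Breed(), k = 2, seed = 5)
  seg <- segmentImage(img, areaBounds = c(500, 550))
  expect_equal(length(seg$components), 2L)
  expect_gt(seg$gate@totalArea, 550)
  expect_equal(verdict(seg$gate), "reject_multiple")
  img3 <- generateMultiCocoonImage(csr2Breed(), k = 3, seed = 5)
  expect_equal(verdict(segmentImage(img3, c(500, 550))$gate), "reject_multiple")
  expect_error(generateMultiCocoonImage(csr2Breed(), k = 1, seed = 1), "k")
})

test_that("female silhouettes are larger and heavier than male ones on average", {
  b <- generateBatch(csr2Breed(), 15, 15, seed = 9)
  info <- cocoonInfo(b)
  areas <- vapply(cocoonImages(b), function(im) {
    seg <- segmentImage(im, areaBounds = c(1, 1e9))
    seg$gate@totalArea
  }, numeric(1))
  expect_gt(mean(areas[info$label == 0]), mean(areas[info$label == 1]))
  expect_gt(mean(info$weight_g[info$label == 0]),
            mean(info$weight_g[info$label == 1]))
})
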