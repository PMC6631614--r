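test_that("area and perimeter of canonical shapes are exact", {
  sq <- regionFromMask(rectMask(10, 10))
  expect_equal(regionArea(sq), 100)
  expect_equal(regionPerimeter(sq), 36)   # 4*10 minus 4 corner double-counts
  line <- regionFromMask(rectMask(7, 1))
  expect_equal(regionArea(line), 7)
  expect_equal(regionPerimeter(line), 7)  # every pixel of a 1xN line is boundary
  single <- extractComponents(rectMask(1, 1), minSpeck = 1)[[1]]
  expect_equal(regionArea(single), 1)
})

test_that("pixel-count perimeter matches the brute-force scan oracle", {
  withr::with_seed(41L, {
    for (i in 1:6) {
      img <- renderSilhouette(12 + 2 * i, waist = 0.05 * (i %% 3),
                              fiberDensity = 0, noiseSd = 0,
                              imageSize = 24 + 4 * i + 12)
      mask <- binarizeImage(img, otsuThreshold(img))
      reg <- regionFromMask(mask)
      expect_equal(regionPerimeter(reg), perimeterOracle(mask))
    }
  })
})

test_that("rendered superellipse area matches the closed form through the region path", {
  img <- withr::with_seed(5L, renderSilhouette(30, waist = 0, fiberDensity = 0,
                                               noiseSd = 0, imageSize = 72))
  reg <- regionFromMask(binarizeImage(img, otsuThreshold(img)))
  analytic <- 4 * 30 * (30 / 1.7) * gamma(1.4)^2 / gamma(1.8)
  expect_equal(regionArea(reg), analytic, tolerance = 0.02)
})

test_that("moment-ellipse axes have their closed-form values on rectangles and discs", {
  # a x b uniform rectangle: axis ratio is exactly a/b with the 1/12 correction
  r <- regionFromMask(rectMask(30, 12))
  lam <- momentEllipse(r)
  expect_equal(unname(lam["lambda1"] / lam["lambda2"]), 30 / 12, tolerance = 1e-12)
  expect_equal(unname(lam["lambda1"]), 30 * 2 / sqrt(3), tolerance = 1e-9)
  # disc of radius r: both axes approach the diameter
  d <- regionFromMask(discMask(25))
  lamd <- momentEllipse(d)
  expect_equal(unname(lamd["lambda1"]), 50, tolerance = 0.02)
  expect_equal(unname(lamd["lambda2"]), 50, tolerance = 0.02)
})

test_that("moment ellipse is invariant under 90-degree rotation", {
  m <- rotRectMask(24, 9, 28)
  lam1 <- momentEllipse(regionFromMask(m))
  lam2 <- momentEllipse(regionFromMask(t(m)))   # transpose = 90-deg rotation
  expect_equal(lam1, lam2, tolerance = 1e-9)
})

test_that("minimum bounding rectangle is exact axis-aligned and tight rotated", {
  mbr <- minBoundingRect(regionFromMask(rectMask(18, 7)))
  expect_equal(unname(mbr["Lb"]), 18)
  expect_equal(unname(mbr["Wb"]), 7)
  expect_equal(unname(mbr["Ar"]), 126)
  # rotated 45 degrees: recovered dimensions within 3% of the originals
  reg45 <- regionFromMask(rotRectMask(60, 40, 45))
  mbr45 <- minBoundingRect(reg45)
  expect_equal(unname(mbr45["Lb"]), 60, tolerance = 0.03)
  expect_equal(unname(mbr45["Wb"]), 40, tolerance = 0.03)
  # minimality: never larger than the axis-aligned bounding box
  p <- reg45$pixels
  aabb <- (diff(range(p[, 1])) + 1) * (diff(range(p[, 2])) + 1)
  expect_lte(mbr45[["Ar"]], aabb + 1e-9)
})

test_that("convex hull geometry matches the gift-wrapping oracle", {
  withr::with_seed(43L, {
    img <- renderSilhouette(20, waist = 0.15, fiberDensity = 0, noiseSd = 0,
                            imageSize = 52)
    reg <- regionFromMask(binarizeImage(img, otsuThreshold(img)))
    got <- convexHullGeometry(reg)
    oracleHull <- giftWrapHull(reg$pixels)
    edges <- rbind(oracleHull[-1, , drop = FALSE], oracleHull[1, ]) - oracleHull
    expect_equal(unname(got["P_hull"]), sum(sqrt(rowSums(edges^2))),
                 tolerance = 1e-9)
    expect_equal(unname(got["H"]), latticeCountOracle(oracleHull, reg$pixels))
  })
})

test_that("hull area: exact on convex input, strictly larger on a dumbbell", {
  r <- regionFromMask(rectMask(14, 9))
  hg <- convexHullGeometry(r)
  expect_equal(unname(hg["H"]), 126)   # convex image of a rectangle is itself
  # dumbbell: two blobs joined by a thin bar is far from convex
  m <- matrix(FALSE, 14, 30)
  m[3:12, 2:8] <- TRUE
  m[3:12, 23:29] <- TRUE
  m[7, 9:22] <- TRUE
  db <- regionFromMask(m)
  expect_gt(convexHullGeometry(db)[["H"]], regionArea(db))
})

test_that("assembled feature vector honours the defining ratios and bounds", {
  img <- withr::with_seed(47L, renderSilhouette(16.6))
  seg <- segmentImage(img, areaBounds = c(400, 650))
  expect_equal(verdict(seg$gate), "accept")
  sf <- computeShapeFeatures(seg$components[[1]])
  expect_named(sf, c("A", "P", "lambda1", "lambda2", "axis_ratio",
                     "E", "C", "R", "S", "AC"))
  expect_equal(unname(sf["C"]), unname(sf["A"] / sf["P"]^2))
  expect_gte(unname(sf["axis_ratio"]), 1)
  expect_gte(unname(sf["E"]), 1)
  expect_true(sf["R"] > 0 && sf["R"] <= 1)
  expect_true(sf["S"] > 0 && sf["S"] <= 1)
})

test_that("solidity of convex shapes stays in [0.98, 1]", {
  for (reg in list(regionFromMask(discMask(20)),
                   regionFromMask(discMask(35)),
                   regionFromMask(rectMask(20, 11)),
                   regionFromMask(rotRectMask(26, 13, 30)))) {
    s <- regionArea(reg) / convexHullGeometry(reg)[["H"]]
    expect_gte(s, 0.98)
    expect_lte(s, 1.0)
  }
})

test_that("rectangularity of a filled rectangle approaches 1", {
  expect_equal(computeShapeFeatures(regionFromMask(rectMask(25, 10)))[["R"]], 1,
               tolerance = 1e-9)
})

test_that("circularity of a disc approaches its continuum limit under the weighted perimeter", {
  # the pixel-count perimeter of a digital disc is ~0.89 * 2*pi*r, so the
  # default C plateaus near 0.100; the chain-code weighted perimeter
  # converges to 2*pi*r and recovers C -> 1/(4*pi)
  reg <- regionFromMask(discMask(40))
  cWeighted <- computeShapeFeatures(reg, perimeterMethod = "weighted")[["C"]]
  expect_equal(cWeighted, 1 / (4 * pi), tolerance = 0.1)
  cPixel <- computeShapeFeatures(reg)[["C"]]
  expect_equal(cPixel, regionArea(reg) / perimeterOracle(discMask(40))^2,
               tolerance = 1e-9)
})

test_that("geometry invariants hold across rendered silhouettes", {
  withr::with_seed(53L, {
    for (i in 1:6) {
      img <- renderSilhouette(14 + 3 * i, waist = 0.12, imageSize = 28 + 6 * i + 14)
      seg <- segmentImage(img, areaBounds = c(1, 1e9))
      reg <- seg$components[[1]]
      A <- regionArea(reg)
      H <- convexHullGeometry(reg)[["H"]]
      Ar <- minBoundingRect(reg)[["Ar"]]
      expect_lte(A, H + 1e-9)
      expect_lte(H, Ar + 1e-9)
    }
  })
})

test_that("dimensionless features are scale-robust and all invariant to translation", {
  mk <- function(scale, center, sz) {
    img <- renderSilhouette(scale, waist = 0.25, fiberDensity = 0, noiseSd = 0,
                            imageSize = sz, center = center)
    computeShapeFeatures(regionFromMask(binarizeImage(img, otsuThreshold(img))))
  }
  f1 <- mk(20, NULL, 52)
  f2 <- mk(40, NULL, 94)            # 2x scale
  for (nm in c("E", "C", "R", "S", "AC", "axis_ratio"))
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 0.05)
  fShift <- mk(18, c(22, 24), 48)   # same shape, different position
  expect_equal(unname(fShift), unname(mk(18, c(24, 22), 48)), tolerance = 1e-12)
})
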