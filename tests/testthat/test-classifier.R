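test_that("stratified hold-out reproduces the printed protocol cell counts", {
  # CSR2: 47 males, 44 females
  y <- c(rep(1, 47), rep(0, 44))
  sp <- stratifiedHoldoutSplit(y, seed = 1)
  expect_equal(sum(y[sp$train] == 1), 28)
  expect_equal(sum(y[sp$train] == 0), 26)
  expect_equal(sum(y[sp$test] == 1), 19)
  expect_equal(sum(y[sp$test] == 0), 18)
  # Pure Mysore: 35 males, 41 females
  y2 <- c(rep(1, 35), rep(0, 41))
  sp2 <- stratifiedHoldoutSplit(y2, seed = 2)
  expect_equal(sum(y2[sp2$train] == 1), 21)
  expect_equal(sum(y2[sp2$train] == 0), 24)
  expect_equal(sum(y2[sp2$test] == 1), 14)
  expect_equal(sum(y2[sp2$test] == 0), 17)
  # disjoint and covering
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  # 10 records of one gender at 0.6 -> 6 train, 4 test
  y3 <- c(rep(1, 10), rep(0, 5))
  sp3 <- stratifiedHoldoutSplit(y3, seed = 3)
  expect_equal(sum(y3[sp3$train] == 1), 6)
})

test_that("splits are deterministic in the seed and reject unlabelled records", {
  y <- c(rep(1, 20), rep(0, 20))
  expect_identical(stratifiedHoldoutSplit(y, seed = 9),
                   stratifiedHoldoutSplit(y, seed = 9))
  expect_error(stratifiedHoldoutSplit(c(1, 0, NA), seed = 1), "label")
})

test_that("the symmetric two-point problem yields the mid-plane", {
  X <- rbind(c(1, 0.3), c(-1, -0.3))
  colnames(X) <- c("a", "b")
  m <- trainLinearSVM(X, c(1, 0), cReg = 1e4)
  # perpendicular bisector: the two points score +/- s, the midpoint 0
  s <- decisionValue(m, X)
  expect_equal(s[1], -s[2], tolerance = 1e-6)
  expect_equal(predict(m, X), c(1L, 0L))
  mid <- (X[1, ] + X[2, ]) / 2
  expect_equal(decisionValue(m, mid), 0, tolerance = 1e-9)
})

test_that("margin matches the direction-search oracle on tiny separable sets", {
  withr::with_seed(71L, {
    for (i in 1:4) {
      n1 <- sample(2:4, 1); n0 <- sample(2:4, 1)
      X <- rbind(matrix(rnorm(2 * n1, 3), n1, 2),
                 matrix(rnorm(2 * n0, -3), n0, 2))
      y <- c(rep(1, n1), rep(0, n0))
      np <- fitNormalizer(X)
      Z <- applyZscore(X, np)
      m <- trainLinearSVM(X, y, cReg = 1e6)
      margin <- min(abs(Z %*% m@w + m@b)) / sqrt(sum(m@w^2))
      expect_equal(margin, maxMarginOracle2d(Z, y), tolerance = 0.01)
      expect_equal(predict(m, X), y)   # separable: zero training error
    }
  })
})

test_that("weights separable by cocoon mass alone train error-free", {
  withr::with_seed(72L, {
    b <- generateBatch(pureMysoreBreed(), 20, 20, seed = 101, fiberDensity = 0)
    info <- cocoonInfo(b)
    # weight + filler features: separation must come through W
    X <- cbind(W = info$weight_g, noise = rnorm(40))
    m <- trainLinearSVM(X, info$label, cReg = 1e4)
    expect_equal(predict(m, X), info$label)
  })
})

test_that("tie at score zero maps to female and sign agrees with predict", {
  X <- rbind(c(2, 1), c(-2, -1), c(1, 2), c(-1, -2))
  colnames(X) <- c("a", "b")
  m <- trainLinearSVM(X, c(1, 0, 1, 0), cReg = 100)
  # a point exactly on the hyperplane (score 0) is labelled 0
  np <- m@normParams
  xOnPlane <- np@mu - np@sigma * m@b * m@w / sum(m@w^2)
  expect_equal(decisionValue(m, xOnPlane), 0, tolerance = 1e-9)
  expect_equal(predict(m, xOnPlane), 0L)
  withr::with_seed(73L, R <- matrix(rnorm(2000), 1000, 2))
  expect_equal(predict(m, R), as.integer(decisionValue(m, R) > 0))
  # monotone along +w (in raw space: shift by sigma-scaled w)
  x0 <- np@mu
  x1 <- x0 + np@sigma * m@w
  expect_gt(decisionValue(m, x1), decisionValue(m, x0))
})

test_that("single-class input and length mismatches are rejected", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(trainLinearSVM(X, rep(1, 5)), "both classes")
  m <- trainLinearSVM(rbind(c(1, 0), c(-1, 0), c(2, 1), c(-2, -1)),
                      c(1, 0, 1, 0), cReg = 10)
  expect_error(predict(m, c(1, 2, 3)), "length mismatch")
})

test_that("the trained direction recovers a known separating direction", {
  # two Gaussians separated by 4 sd along a known direction, n = 200
  withr::with_seed(74L, {
    dTrue <- c(1, rep(0, 8))
    X <- matrix(rnorm(200 * 9), 200, 9)
    y <- rep(c(1, 0), each = 100)
    X[y == 1, 1] <- X[y == 1, 1] + 4
    colnames(X) <- ifvFeatureNames()
    m <- trainLinearSVM(X, y, cReg = 1)
    cosine <- sum(m@w * dTrue) / sqrt(sum(m@w^2))
    expect_gt(cosine, 0.95)
  })
})

test_that("identical data and seed give identical models", {
  withr::with_seed(75L, {
    X <- matrix(rnorm(60 * 4), 60, 4)
    y <- rep(c(1, 0), 30)
    X[y == 1, 2] <- X[y == 1, 2] + 2
  })
  m1 <- trainLinearSVM(X, y, cReg = 1)
  m2 <- trainLinearSVM(X, y, cReg = 1)
  expect_identical(m1@w, m2@w)
  expect_identical(m1@b, m2@b)
})

test_that("model JSON round-trips byte-identically and scores identically", {
  X <- rbind(c(1.2, 500), c(0.9, 480), c(1.6, 560), c(1.5, 555))
  colnames(X) <- c("W", "A")
  m <- trainLinearSVM(X, c(0, 0, 1, 1), cReg = 5)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  saveModelJSON(m, f1)
  m2 <- readModelJSON(f1)
  saveModelJSON(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(decisionValue(m2, X), decisionValue(m, X))
  # malformed file is rejected with the missing field named
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(w = 1:2, b = 0), f3, auto_unbox = TRUE)
  expect_error(readModelJSON(f3), "C_reg")
})
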