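# Synthetic cocoon specimens: backlit silhouette images plus gender- and
# breed-conditional weights, emulating the multi-sensor acquisition rig so
# the whole pipeline is testable without real data.

#' Construct a breed specification
#'
#' @param breedName character breed label.
#' @param maleWeightRange,femaleWeightRange numeric \code{c(lo, hi)} in grams.
#' @param maleSizeScale,femaleSizeScale silhouette semi-major axis (px) at the
#'   reference camera geometry (18 cm standoff, where a single cocoon covers
#'   roughly 500--550 px).
#' @param sizeNoiseSd relative sd of the per-cocoon size scale.
#' @param weightDistribution "uniform" (default) or "truncnorm" (truncated
#'   normal centred on the range midpoint with sd = range/4), for overlap
#'   experiments.
#' @return a [BreedSpec-class]
#' @export
breedSpec <- function(breedName,
                      maleWeightRange, femaleWeightRange,
                      maleSizeScale = 16.6, femaleSizeScale = 17.2,
                      sizeNoiseSd = 0.01,
                      weightDistribution = c("uniform", "truncnorm")) {
  new("BreedSpec", breedName = breedName,
      maleWeightRange = as.numeric(maleWeightRange),
      femaleWeightRange = as.numeric(femaleWeightRange),
      maleSizeScale = maleSizeScale, femaleSizeScale = femaleSizeScale,
      sizeNoiseSd = sizeNoiseSd,
      weightDistribution = match.arg(weightDistribution))
}

#' @rdname breedSpec
#' @export
csr2Breed <- function() {
  breedSpec("CSR2", maleWeightRange = c(0.7, 1.4),
            femaleWeightRange = c(1.5, 2.0))
}

#' @rdname breedSpec
#' @export
pureMysoreBreed <- function() {
  breedSpec("PureMysore", maleWeightRange = c(0.8, 1.1),
            femaleWeightRange = c(1.2, 1.4))
}

#' Sample cocoon weights for one gender of a breed
#'
#' Draws from the gender's configured weight support and quantizes to the
#' 0.01 g resolution of the load sensor.  Uniform over the range by default;
#' a truncated normal (midpoint mean, sd = range/4) is available through the
#' breed's \code{weightDistribution} for overlap experiments.  Uses the
#' current R random stream; seed at the caller (e.g. [generateBatch()]).
#'
#' @param spec a [BreedSpec-class]
#' @param gender 1/"male" or 0/"female"
#' @param n number of draws
#' @return numeric vector of weights in grams, multiples of 0.01
#' @export
sampleWeight <- function(spec, gender, n = 1L) {
  stopifnot(is(spec, "BreedSpec"))
  validObject(spec)
  r <- weightRange(spec, gender)
  w <- if (spec@weightDistribution == "uniform") {
    stats::runif(n, r[1], r[2])
  } else {
    mu <- mean(r); sd <- max(diff(r) / 4, 1e-9)
    x <- stats::rnorm(n, mu, sd)
    while (any(bad <- x < r[1] | x > r[2]))     # rejection sampling
      x[bad] <- stats::rnorm(sum(bad), mu, sd)
    x
  }
  round(w * 100) / 100
}

# Closed-form area of the superellipse |x/a|^p + |y/b|^p <= 1.
superellipseArea <- function(a, b, exponent = 2.5) {
  4 * a * b * gamma(1 + 1 / exponent)^2 / gamma(1 + 2 / exponent)
}

# Foreground membership of the (optionally waist-pinched) superellipse, on
# pixel centers.  The pinch narrows the half-height by a cosine factor that is
# strongest at the shape's centre, giving the peanut profile of a cocoon.
.shellMask <- function(imageSize, center, scale, elongation, exponent, waist,
                       angle = 0, pinchWidth = 0.5) {
  a <- scale; b <- scale / elongation
  x0 <- matrix(rep(seq_len(imageSize[2]), each = imageSize[1]) - center[2],
               imageSize[1], imageSize[2])
  y0 <- matrix(rep(seq_len(imageSize[1]), times = imageSize[2]) - center[1],
               imageSize[1], imageSize[2])
  x <- cos(angle) * x0 + sin(angle) * y0
  y <- -sin(angle) * x0 + cos(angle) * y0
  # cosine waist pinch confined to a window of half-width pinchWidth * a, so
  # the dip survives the flat top of the superellipse (peanut profile)
  pinch <- 1 - waist * pmax(cos(pi * x / (2 * pinchWidth * a)), 0) *
    (abs(x) < pinchWidth * a)
  (abs(x / a))^exponent + (abs(y / (b * pinch)))^exponent <= 1
}

#' Render one backlit cocoon silhouette
#'
#' Produces an 8-bit grayscale image with a bright background (the LED
#' backlight), a dark ovoid shell (a superellipse, optionally pinched at the
#' waist into the peanut profile typical of cocoons), thin fibrous strands at
#' an intermediate intensity, and additive Gaussian pixel noise.  The strand
#' intensity lies strictly between shell and background and is biased toward
#' the backlight so that a correct bimodal threshold assigns the floss to the
#' background, which is exactly what backlit acquisition achieves on real
#' cocoons.
#'
#' Uses the current R random stream (strands and noise); seed at the caller.
#'
#' @param scale semi-major axis of the shell in pixels.
#' @param elongation ratio of major to minor semi-axis (> 1 for an ovoid).
#' @param waist waist-pinch depth in \[0, 1); 0 gives a pure superellipse
#'   whose area has the closed form used as a test oracle.
#' @param exponent superellipse exponent (2 = ellipse).
#' @param fiberDensity number of fibrous strands to draw.
#' @param noiseSd sd of additive Gaussian pixel noise (intensity units).
#' @param imageSize scalar or \code{c(rows, cols)} image size in pixels.
#' @param center shell centre \code{c(row, col)}; defaults to the image centre.
#' @param angle in-plane orientation of the major axis in radians (cocoons
#'   land on the flip plate at arbitrary orientation).
#' @param shellIntensity,backgroundIntensity,fiberIntensity 8-bit levels;
#'   must satisfy shell < fiber < background.
#' @return integer matrix (rows x cols) with values in 0..255
#' @export
renderSilhouette <- function(scale, elongation = 1.7, waist = 0.25,
                             exponent = 2.5, fiberDensity = 8, noiseSd = 6,
                             imageSize = 64L, center = NULL, angle = 0,
                             shellIntensity = 25L, backgroundIntensity = 230L,
                             fiberIntensity = 150L) {
  if (length(imageSize) == 1L) imageSize <- c(imageSize, imageSize)
  imageSize <- as.integer(imageSize)
  if (is.null(center)) center <- (imageSize + 1) / 2
  stopifnot(scale > 0, elongation >= 1, waist >= 0, waist < 1,
            shellIntensity < fiberIntensity,
            fiberIntensity < backgroundIntensity)
  margin <- 2
  # conservative half-extents: a rotated shell fits in a disc of radius a
  halfC <- scale
  halfR <- if (abs(sin(angle)) < 1e-12) scale / elongation else scale
  if (center[2] - halfC < margin || center[2] + halfC > imageSize[2] - margin ||
      center[1] - halfR < margin || center[1] + halfR > imageSize[1] - margin)
    stop("shape exceeds the frame: increase imageSize or reduce scale")

  img <- matrix(as.numeric(backgroundIntensity), imageSize[1], imageSize[2])
  shell <- .shellMask(imageSize, center, scale, elongation, exponent, waist,
                      angle)
  img[shell] <- shellIntensity

  if (fiberDensity > 0) {
    # each strand: a short random walk starting just outside the shell rim,
    # one pixel thick; drawn with min() so strands never darken the shell
    for (k in seq_len(fiberDensity)) {
      ang <- stats::runif(1, 0, 2 * pi)
      r0 <- scale * stats::runif(1, 0.95, 1.15)
      pos <- center + c(sin(ang) * r0 / elongation, cos(ang) * r0)
      dir <- stats::runif(1, 0, 2 * pi)
      for (s in seq_len(round(scale * 1.5))) {
        dir <- dir + stats::rnorm(1, 0, 0.45)
        pos <- pos + c(sin(dir), cos(dir))
        rr <- round(pos[1]); cc <- round(pos[2])
        if (rr < 1 || rr > imageSize[1] || cc < 1 || cc > imageSize[2]) break
        img[rr, cc] <- min(img[rr, cc], fiberIntensity)
      }
    }
  }
  if (noiseSd > 0)
    img <- img + stats::rnorm(length(img), 0, noiseSd)
  storage.mode(img) <- "double"
  img <- round(img)
  img[img < 0] <- 0; img[img > 255] <- 255
  storage.mode(img) <- "integer"
  img
}

#' Generate a labelled batch of synthetic cocoons
#'
#' Each record gets a unique index, a weight drawn by [sampleWeight()] from
#' the gender's configured range, and a backlit silhouette whose size scale is
#' drawn from the gender's size distribution (females render larger, matching
#' their larger circumference).  All randomness flows from \code{seed};
#' identical seeds give bit-identical batches.
#'
#' @param spec a [BreedSpec-class]
#' @param nMale,nFemale non-negative specimen counts.
#' @param seed integer seed.
#' @param imageSize image size in pixels (scalar or \code{c(rows, cols)}).
#' @param waist,fiberDensity,noiseSd passed to [renderSilhouette()].
#' @param dir optional directory; when given, images are written as
#'   \code{<index>.png} and ground truth as \code{truth.csv}.
#' @return a [CocoonBatch-class]
#' @export
generateBatch <- function(spec, nMale, nFemale, seed, imageSize = 64L,
                          waist = 0.25, fiberDensity = 8, noiseSd = 6,
                          dir = NULL) {
  stopifnot(is(spec, "BreedSpec"), nMale >= 0, nFemale >= 0)
  validObject(spec)
  n <- nMale + nFemale
  genders <- c(rep(1L, nMale), rep(0L, nFemale))
  withr::with_seed(as.integer(seed), {
    images <- vector("list", n)
    weights <- numeric(n)
    for (i in seq_len(n)) {
      g <- genders[i]
      weights[i] <- sampleWeight(spec, g, 1L)
      sc <- sizeScale(spec, g) * (1 + stats::rnorm(1, 0, spec@sizeNoiseSd))
      images[[i]] <- renderSilhouette(sc, waist = waist,
                                      fiberDensity = fiberDensity,
                                      noiseSd = noiseSd,
                                      imageSize = imageSize,
                                      angle = stats::runif(1, 0, pi))
    }
  })
  info <- data.frame(index = seq_len(n),
                     breed = rep(breedName(spec), n),
                     weight_g = weights,
                     label = genders,
                     stringsAsFactors = FALSE)
  if (n == 0L)
    info <- data.frame(index = integer(), breed = character(),
                       weight_g = numeric(), label = integer(),
                       stringsAsFactors = FALSE)
  batch <- new("CocoonBatch", images = images, info = info)
  if (!is.null(dir)) writeBatch(batch, dir)
  batch
}

#' Render an image containing several cocoons
#'
#' Places \code{k >= 2} non-touching silhouettes on one frame, used to test
#' the single-cocoon area gate (more than one cocoon on the flip plate must be
#' rejected and ejected).  Shell centres are laid out on a grid with spacing
#' larger than two shell diameters, so segmentation is guaranteed to find
#' \code{k} separate components.
#'
#' @param spec a [BreedSpec-class]
#' @param k number of cocoons, at least 2.
#' @param seed integer seed.
#' @param fiberDensity,noiseSd passed to [renderSilhouette()].
#' @return integer matrix, 8-bit grayscale
#' @export
generateMultiCocoonImage <- function(spec, k, seed, fiberDensity = 0,
                                     noiseSd = 0) {
  stopifnot(is(spec, "BreedSpec"))
  if (k < 2) stop("k must be >= 2 for a multi-cocoon image")
  validObject(spec)
  amax <- spec@femaleSizeScale * 1.1
  cellSz <- ceiling(2 * amax + 8)
  ncol <- ceiling(sqrt(k))
  nrowg <- ceiling(k / ncol)
  sz <- c(nrowg, ncol) * cellSz
  withr::with_seed(as.integer(seed), {
    img <- matrix(230L, sz[1], sz[2])
    for (i in seq_len(k)) {
      gr <- (i - 1) %/% ncol
      gc <- (i - 1) %% ncol
      ctr <- c(gr * cellSz + cellSz / 2, gc * cellSz + cellSz / 2)
      g <- stats::rbinom(1, 1, 0.5)
      sc <- sizeScale(spec, g) * (1 + stats::rnorm(1, 0, spec@sizeNoiseSd))
      sub <- renderSilhouette(sc, fiberDensity = fiberDensity,
                              noiseSd = 0, imageSize = cellSz,
                              center = c(cellSz / 2, cellSz / 2),
                              angle = stats::runif(1, 0, pi))
      img[(gr * cellSz + 1):((gr + 1) * cellSz),
          (gc * cellSz + 1):((gc + 1) * cellSz)] <- sub
    }
    if (noiseSd > 0) {
      img <- round(img + stats::rnorm(length(img), 0, noiseSd))
      img[img < 0] <- 0L; img[img > 255] <- 255L
      storage.mode(img) <- "integer"
    }
  })
  img
}
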