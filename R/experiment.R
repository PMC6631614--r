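# End-to-end orchestration of the acquisition-and-classification protocol:
# generate (or load) a batch, segment and gate every image, fuse features,
# split, train, evaluate, and measure repeated-trial repeatability.

# Segment every image of a batch and compute IFVs for accepted records.
# gateBounds = NULL auto-calibrates the gate from the batch's own singleton
# areas (mean +/- 3 sd), the reference-batch calibration used when the camera
# geometry differs from the fixed 500-550 px default.
.processBatch <- function(batch, gateBounds = NULL, minSpeck = 10L) {
  imgs <- cocoonImages(batch)
  info <- cocoonInfo(batch)
  n <- length(imgs)
  segs <- lapply(imgs, function(im) {
    t <- otsuThreshold(im)
    mask <- binarizeImage(im, t)
    comps <- extractComponents(mask, minSpeck = minSpeck)
    list(threshold = t, components = comps,
         area = sum(vapply(comps, `[[`, numeric(1), "area")))
  })
  areas <- vapply(segs, `[[`, numeric(1), "area")
  if (is.null(gateBounds)) gateBounds <- calibrateGateBounds(areas)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- singleCocoonGate(segs[[i]]$components, gateBounds)
    if (verdict(g) == "accept") {
      sf <- computeShapeFeatures(segs[[i]]$components[[1L]])
      ifv <- buildIFV(info$weight_g[i], sf)
      rows[[i]] <- list(verdict = "accept", ifv = ifv, area = g@totalArea)
    } else {
      rows[[i]] <- list(verdict = verdict(g), ifv = NULL, area = g@totalArea)
    }
  }
  list(rows = rows, gateBounds = gateBounds, areas = areas)
}

.cmReport <- function(cm) {
  met <- computeMetrics(cm)
  list(cm = as.list(cmCounts(cm)),
       metrics = met[c("accuracy", "TMR", "TFR", "MPV", "FPV", "F1")])
}

#' Run the full classification experiment on a synthetic batch
#'
#' Mirrors the acquisition-to-evaluation protocol end to end: generate a
#' labelled batch, segment and gate every silhouette, build integrated
#' feature vectors, perform the stratified 60/40 hold-out split, fit the
#' normalizer and the linear SVM on the training split, and report confusion
#' matrices and metric suites for both splits.  With \code{trials > 0} the
#' pipeline from segmentation onward is re-run \code{trials} times on the
#' same images and the repeatability statistic (fraction of records correct
#' in every trial) is reported.
#'
#' @param spec a [BreedSpec-class]
#' @param nMale,nFemale specimen counts
#' @param seed integer seed driving all randomness
#' @param cReg soft-margin penalty
#' @param trainFrac training fraction, default 0.6
#' @param trials number of repeatability trials (0 = skip)
#' @param gateBounds \code{c(lo, hi)} or NULL to auto-calibrate from the
#'   batch's singleton areas (mean +/- 3 sd)
#' @param imageSize,waist,fiberDensity,noiseSd passed to [generateBatch()]
#' @return report list with elements \code{split}, \code{gate},
#'   \code{train}, \code{test}, and optionally \code{repeatability}
#' @export
runExperiment <- function(spec, nMale, nFemale, seed, cReg = 1,
                          trainFrac = 0.6, trials = 0L, gateBounds = NULL,
                          imageSize = 64L, waist = 0.25, fiberDensity = 8,
                          noiseSd = 6) {
  batch <- generateBatch(spec, nMale, nFemale, seed, imageSize = imageSize,
                         waist = waist, fiberDensity = fiberDensity,
                         noiseSd = noiseSd)
  proc <- .processBatch(batch, gateBounds)
  accepted <- which(vapply(proc$rows, `[[`, character(1), "verdict") == "accept")
  if (length(accepted) < 4L)
    stop("too few accepted cocoons (", length(accepted), ") to run a split")
  X <- do.call(rbind, lapply(proc$rows[accepted], `[[`, "ifv"))
  y <- cocoonLabels(batch)[accepted]

  sp <- stratifiedHoldoutSplit(y, trainFrac = trainFrac, seed = seed + 1L)
  model <- trainLinearSVM(X[sp$train, , drop = FALSE], y[sp$train], cReg = cReg)
  predTrain <- predict(model, X[sp$train, , drop = FALSE])
  predTest <- predict(model, X[sp$test, , drop = FALSE])

  report <- list(
    config = list(breed = breedName(spec), n_male = nMale, n_female = nFemale,
                  seed = seed, C_reg = cReg, train_frac = trainFrac,
                  trials = trials),
    gate = list(bounds = proc$gateBounds,
                accepted = length(accepted),
                rejected = nCocoons(batch) - length(accepted)),
    split = list(train_male = sum(y[sp$train] == 1),
                 train_female = sum(y[sp$train] == 0),
                 test_male = sum(y[sp$test] == 1),
                 test_female = sum(y[sp$test] == 0)),
    train = .cmReport(confusionMatrix(y[sp$train], predTrain)),
    test = .cmReport(confusionMatrix(y[sp$test], predTest))
  )

  if (trials > 0L) {
    testIdxAll <- accepted[sp$test]
    correct <- matrix(NA, length(testIdxAll), trials)
    for (tr in seq_len(trials)) {
      # re-run segmentation onward on the same physical images; the pipeline
      # is deterministic, so trials agree unless the inputs change
      proc2 <- .processBatch(batch, proc$gateBounds)
      ok <- logical(length(testIdxAll))
      for (j in seq_along(testIdxAll)) {
        row <- proc2$rows[[testIdxAll[j]]]
        ok[j] <- row$verdict == "accept" &&
          predict(model, row$ifv) == cocoonLabels(batch)[testIdxAll[j]]
      }
      correct[, tr] <- ok
    }
    report$repeatability <- list(k = trials, n = nrow(correct),
                                 value = repeatability(correct))
  }
  report
}

#' Classify a batch of images with weights through the gate and model
#'
#' For every row of the weight table, reads \code{<index>.png} from
#' \code{imageDir}, applies Otsu segmentation and the single-cocoon gate,
#' and, for accepted records, predicts the gender and assigns the output
#' bin ("male_tray" / "female_tray", the two blower targets).  Records whose
#' image is missing or whose weight is absent produce an error row and the
#' batch continues.
#'
#' @param imageDir directory of \code{<index>.png} images
#' @param weights data.frame with columns \code{index}, \code{weight_g}, or a
#'   path to such a CSV
#' @param model a trained [CocoonSVM-class]
#' @param gateBounds area gate bounds \code{c(lo, hi)} in pixels
#' @param minSpeck passed to [extractComponents()]
#' @return data.frame with columns \code{index, verdict, area, weight_g,
#'   score, label, bin, error}
#' @export
classifyBatch <- function(imageDir, weights, model,
                          gateBounds = c(500, 550), minSpeck = 10L) {
  stopifnot(is(model, "CocoonSVM"))
  if (is.character(weights)) {
    weights <- utils::read.csv(weights, stringsAsFactors = FALSE)
  }
  if (!all(c("index", "weight_g") %in% names(weights)))
    stop("weights must have columns index, weight_g")
  if (anyDuplicated(weights$index))
    stop("duplicate cocoon indices in the weight table")
  out <- lapply(seq_len(nrow(weights)), function(i) {
    idx <- weights$index[i]
    w <- weights$weight_g[i]
    base <- data.frame(index = idx, verdict = NA_character_,
                       area = NA_real_, weight_g = w, score = NA_real_,
                       label = NA_integer_, bin = NA_character_,
                       error = NA_character_, stringsAsFactors = FALSE)
    path <- file.path(imageDir, paste0(idx, ".png"))
    if (!file.exists(path)) {
      base$error <- "image not found"
      return(base)
    }
    if (is.na(w) || !is.finite(w) || w <= 0) {
      base$error <- "missing or invalid weight"
      return(base)
    }
    seg <- segmentImage(readCocoonImage(path), areaBounds = gateBounds,
                        minSpeck = minSpeck)
    base$verdict <- verdict(seg$gate)
    base$area <- seg$gate@totalArea
    if (base$verdict == "accept") {
      ifv <- buildIFV(w, computeShapeFeatures(seg$components[[1L]]))
      base$score <- decisionValue(model, ifv)
      base$label <- predict(model, ifv)
      base$bin <- if (base$label == 1L) "male_tray" else "female_tray"
    }
    base
  })
  if (!length(out))
    return(data.frame(index = integer(), verdict = character(),
                      area = numeric(), weight_g = numeric(),
                      score = numeric(), label = integer(),
                      bin = character(), error = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
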