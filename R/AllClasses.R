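#' @import methods
NULL

#' BreedSpec: breed- and gender-conditional cocoon population parameters
#'
#' Describes one silkworm breed for the synthetic generator: the
#' gender-conditional cocoon weight supports (grams) and the gender-conditional
#' silhouette size scales (semi-major axis of the rendered shell, in pixels).
#' Female cocoons are bulkier and heavier than males, so the female weight
#' range and size scale must dominate the male ones.
#'
#' Default constructors [csr2Breed()] and [pureMysoreBreed()] carry the
#' industrial-practice weight ranges for the two breeds studied:
#' Pure Mysore male 0.8--1.1 g, female 1.2--1.4 g (disjoint supports);
#' CSR2 male 0.7--1.4 g, female 1.5--2.0 g.
#'
#' @slot breedName character, one of "CSR2", "PureMysore" (free-form names
#'   are allowed for configured variants).
#' @slot maleWeightRange,femaleWeightRange numeric length-2 \code{c(lo, hi)},
#'   grams, \code{lo <= hi}.
#' @slot maleSizeScale,femaleSizeScale positive numeric, silhouette semi-major
#'   axis in pixels at the reference camera geometry; female > male.
#' @slot sizeNoiseSd non-negative numeric, relative (dimensionless) standard
#'   deviation of the per-cocoon size scale.
#' @slot weightDistribution character, "uniform" (default) or "truncnorm".
#' @export
setClass("BreedSpec",
  representation(
    breedName = "character",
    maleWeightRange = "numeric",
    femaleWeightRange = "numeric",
    maleSizeScale = "numeric",
    femaleSizeScale = "numeric",
    sizeNoiseSd = "numeric",
    weightDistribution = "character"
  )
)

setValidity("BreedSpec", function(object) {
  msg <- character()
  for (nm in c("maleWeightRange", "femaleWeightRange")) {
    r <- slot(object, nm)
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] <= 0)
      msg <- c(msg, sprintf("%s must be finite positive c(lo, hi) with lo <= hi", nm))
  }
  if (length(object@maleSizeScale) != 1L || length(object@femaleSizeScale) != 1L ||
      object@maleSizeScale <= 0 || object@femaleSizeScale <= 0)
    msg <- c(msg, "size scales must be positive scalars")
  else if (object@femaleSizeScale <= object@maleSizeScale)
    msg <- c(msg, "femaleSizeScale must exceed maleSizeScale (females are bulkier)")
  if (length(object@sizeNoiseSd) != 1L || object@sizeNoiseSd < 0)
    msg <- c(msg, "sizeNoiseSd must be a non-negative scalar")
  if (!object@weightDistribution %in% c("uniform", "truncnorm"))
    msg <- c(msg, "weightDistribution must be 'uniform' or 'truncnorm'")
  if (length(msg)) msg else TRUE
})

#' CocoonBatch: a labelled batch of synthetic cocoon specimens
#'
#' Holds the rendered backlit silhouette images (8-bit integer matrices,
#' 0 = black, 255 = white) together with the per-cocoon ground-truth table
#' (index, breed, weight in grams quantized to 0.01 g, gender label with
#' 1 = male, 0 = female).
#'
#' @slot images list of integer matrices, one 8-bit grayscale image per cocoon.
#' @slot info data.frame with columns \code{index}, \code{breed},
#'   \code{weight_g}, \code{label}.
#' @export
setClass("CocoonBatch",
  representation(images = "list", info = "data.frame")
)

setValidity("CocoonBatch", function(object) {
  msg <- character()
  info <- object@info
  need <- c("index", "breed", "weight_g", "label")
  if (!all(need %in% names(info)))
    return(paste("info must have columns", paste(need, collapse = ", ")))
  if (length(object@images) != nrow(info))
    msg <- c(msg, "one image per info row required")
  if (anyDuplicated(info$index))
    msg <- c(msg, "cocoon indices must be unique within a batch")
  if (nrow(info)) {
    if (any(info$weight_g <= 0) ||
        any(abs(info$weight_g / 0.01 - round(info$weight_g / 0.01)) > 1e-8))
      msg <- c(msg, "weights must be positive multiples of 0.01 g")
    lab <- info$label
    if (!all(is.na(lab) | lab %in% c(0, 1)))
      msg <- c(msg, "labels must be 1 (male), 0 (female) or NA")
    bad <- !vapply(object@images, function(im)
      is.matrix(im) && min(im) >= 0 && max(im) <= 255, logical(1))
    if (any(bad)) msg <- c(msg, "images must be matrices with values in [0, 255]")
  }
  if (length(msg)) msg else TRUE
})

#' GateVerdict: outcome of the single-cocoon area gate
#'
#' @slot verdict character, one of "accept", "reject_multiple", "reject_empty".
#' @slot totalArea numeric, total foreground area in pixels.
#' @slot componentCount integer, number of connected components considered.
#' @export
setClass("GateVerdict",
  representation(verdict = "character", totalArea = "numeric",
                 componentCount = "integer")
)

setValidity("GateVerdict", function(object) {
  if (!object@verdict %in% c("accept", "reject_multiple", "reject_empty"))
    return("verdict must be accept / reject_multiple / reject_empty")
  TRUE
})

#' NormalizationParams: per-feature z-score parameters
#'
#' Mean and standard deviation of every integrated-feature-vector component,
#' fitted on the training split only and frozen for later scoring.
#'
#' @slot mu,sigma numeric vectors of equal length; all \code{sigma > 0}.
#' @slot featureNames character vector naming the components.
#' @slot sdType character, "population" (denominator n, default) or "sample".
#' @export
setClass("NormalizationParams",
  representation(mu = "numeric", sigma = "numeric",
                 featureNames = "character", sdType = "character")
)

setValidity("NormalizationParams", function(object) {
  msg <- character()
  L <- length(object@mu)
  if (length(object@sigma) != L || length(object@featureNames) != L)
    msg <- c(msg, "mu, sigma and featureNames must have equal length")
  if (any(!is.finite(object@mu)) || any(!is.finite(object@sigma)))
    msg <- c(msg, "mu and sigma must be finite")
  else if (any(object@sigma <= 0))
    msg <- c(msg, "all sigma must be strictly positive")
  if (!object@sdType %in% c("population", "sample"))
    msg <- c(msg, "sdType must be 'population' or 'sample'")
  if (length(msg)) msg else TRUE
})

#' CocoonSVM: trained linear maximum-margin classifier
#'
#' A linear soft-margin SVM in normalized feature space, with the z-score
#' parameters embedded so that scoring raw integrated feature vectors is
#' self-contained.  The decision rule is \code{label = 1 (male)} iff
#' \code{w . z + b > 0} with \code{z} the z-scored feature vector; a score of
#' exactly zero maps to female (0).
#'
#' @slot w numeric weight vector in normalized-feature space.
#' @slot b numeric bias.
#' @slot cReg positive numeric, soft-margin penalty.
#' @slot normParams [NormalizationParams-class] fitted on the training split.
#' @slot featureNames character, order of expected raw features.
#' @slot labelMap named numeric, \code{c(male = 1, female = 0)}.
#' @export
setClass("CocoonSVM",
  representation(w = "numeric", b = "numeric", cReg = "numeric",
                 normParams = "NormalizationParams",
                 featureNames = "character", labelMap = "numeric")
)

setValidity("CocoonSVM", function(object) {
  msg <- character()
  if (length(object@w) != length(object@featureNames))
    msg <- c(msg, "w must have one entry per feature")
  if (sqrt(sum(object@w^2)) <= 0)
    msg <- c(msg, "||w|| must be positive after training")
  if (length(object@b) != 1L || !is.finite(object@b))
    msg <- c(msg, "b must be a finite scalar")
  if (length(object@cReg) != 1L || object@cReg <= 0)
    msg <- c(msg, "cReg must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: male/female binary confusion counts
#'
#' Counts follow the male-positive convention: TM (true male), TF (true
#' female), FM (false male: a true female predicted male), FF (false female:
#' a true male predicted female).
#'
#' @slot TM,TF,FM,FF non-negative integers.
#' @export
setClass("ConfusionMatrix",
  representation(TM = "integer", TF = "integer", FM = "integer", FF = "integer")
)

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@TM, object@TF, object@FM, object@FF)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0))
    return("TM, TF, FM, FF must be non-negative integer counts")
  TRUE
})
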