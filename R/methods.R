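# Accessors and show methods for the S4 surface.

.asGender <- function(gender) {
  if (length(gender) != 1L) stop("invalid gender: must be a single value")
  if (is.character(gender)) {
    g <- match(tolower(gender), c("female", "male")) - 1L
    if (is.na(g)) stop("invalid gender: ", gender)
    return(g)
  }
  if (is.numeric(gender) && gender %in% c(0, 1)) return(as.integer(gender))
  stop("invalid gender: must be 1/'male' or 0/'female'")
}

#' @rdname BreedSpec-class
setMethod("breedName", "BreedSpec", function(object) object@breedName)

#' @rdname BreedSpec-class
setMethod("weightRange", "BreedSpec", function(object, gender) {
  if (.asGender(gender) == 1L) object@maleWeightRange else object@femaleWeightRange
})

#' @rdname BreedSpec-class
setMethod("sizeScale", "BreedSpec", function(object, gender) {
  if (.asGender(gender) == 1L) object@maleSizeScale else object@femaleSizeScale
})

setMethod("show", "BreedSpec", function(object) {
  cat("BreedSpec:", object@breedName, "\n")
  cat(sprintf("  male   weight %.2f-%.2f g, size scale %.1f px\n",
              object@maleWeightRange[1], object@maleWeightRange[2],
              object@maleSizeScale))
  cat(sprintf("  female weight %.2f-%.2f g, size scale %.1f px\n",
              object@femaleWeightRange[1], object@femaleWeightRange[2],
              object@femaleSizeScale))
  cat(sprintf("  size noise sd %.3f, weight distribution %s\n",
              object@sizeNoiseSd, object@weightDistribution))
})

#' @rdname CocoonBatch-class
setMethod("cocoonImages", "CocoonBatch", function(object) object@images)

#' @rdname CocoonBatch-class
setMethod("cocoonInfo", "CocoonBatch", function(object) object@info)

#' @rdname CocoonBatch-class
setMethod("cocoonWeights", "CocoonBatch", function(object) object@info$weight_g)

#' @rdname CocoonBatch-class
setMethod("cocoonLabels", "CocoonBatch", function(object) object@info$label)

#' @rdname CocoonBatch-class
setMethod("nCocoons", "CocoonBatch", function(object) nrow(object@info))

setMethod("show", "CocoonBatch", function(object) {
  n <- nCocoons(object)
  cat("CocoonBatch with", n, "cocoons")
  if (n) {
    lab <- object@info$label
    cat(sprintf(" (%d male, %d female, %d unlabelled)",
                sum(lab == 1, na.rm = TRUE), sum(lab == 0, na.rm = TRUE),
                sum(is.na(lab))))
    cat("\n  breed:", paste(unique(object@info$breed), collapse = ", "))
    cat(sprintf("\n  weight: %.2f-%.2f g", min(object@info$weight_g),
                max(object@info$weight_g)))
  }
  cat("\n")
})

#' @rdname GateVerdict-class
setMethod("verdict", "GateVerdict", function(object) object@verdict)

setMethod("show", "GateVerdict", function(object) {
  cat(sprintf("GateVerdict: %s (total area %g px, %d component%s)\n",
              object@verdict, object@totalArea, object@componentCount,
              if (object@componentCount == 1L) "" else "s"))
})

setMethod("show", "NormalizationParams", function(object) {
  cat("NormalizationParams (", object@sdType, " sd) for ",
      length(object@mu), " features\n", sep = "")
  print(data.frame(feature = object@featureNames, mu = object@mu,
                   sigma = object@sigma), row.names = FALSE)
})

#' @rdname CocoonSVM-class
setMethod("modelWeights", "CocoonSVM", function(object) object@w)

#' @rdname CocoonSVM-class
setMethod("modelBias", "CocoonSVM", function(object) object@b)

#' @rdname CocoonSVM-class
setMethod("normParams", "CocoonSVM", function(object) object@normParams)

setMethod("show", "CocoonSVM", function(object) {
  cat("CocoonSVM linear classifier (C =", object@cReg, ")\n")
  cat("  features:", paste(object@featureNames, collapse = ", "), "\n")
  cat("  ||w|| =", format(sqrt(sum(object@w^2))), " b =", format(object@b), "\n")
  cat("  labels: 1 = male, 0 = female; score 0 maps to female\n")
})

#' @rdname ConfusionMatrix-class
setMethod("cmCounts", "ConfusionMatrix", function(object)
  c(TM = object@TM, TF = object@TF, FM = object@FM, FF = object@FF))

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@TM, object@FM, object@FF, object@TF), 2, 2,
              dimnames = list(c("true male", "true female"),
                              c("pred male", "pred female")))
  cat("ConfusionMatrix (n =", object@TM + object@TF + object@FM + object@FF, ")\n")
  print(m)
})
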