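#' @rdname BreedSpec-class
#' @param object a \code{BreedSpec}
#' @export
setGeneric("breedName", function(object) standardGeneric("breedName"))

#' @rdname BreedSpec-class
#' @param gender 1/"male" or 0/"female"
#' @export
setGeneric("weightRange", function(object, gender) standardGeneric("weightRange"))

#' @rdname BreedSpec-class
#' @export
setGeneric("sizeScale", function(object, gender) standardGeneric("sizeScale"))

#' @rdname CocoonBatch-class
#' @param object a \code{CocoonBatch}
#' @export
setGeneric("cocoonImages", function(object) standardGeneric("cocoonImages"))

#' @rdname CocoonBatch-class
#' @export
setGeneric("cocoonInfo", function(object) standardGeneric("cocoonInfo"))

#' @rdname CocoonBatch-class
#' @export
setGeneric("cocoonWeights", function(object) standardGeneric("cocoonWeights"))

#' @rdname CocoonBatch-class
#' @export
setGeneric("cocoonLabels", function(object) standardGeneric("cocoonLabels"))

#' @rdname CocoonBatch-class
#' @export
setGeneric("nCocoons", function(object) standardGeneric("nCocoons"))

#' @rdname GateVerdict-class
#' @param object a \code{GateVerdict}
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))

#' @rdname CocoonSVM-class
#' @param object a \code{CocoonSVM}
#' @export
setGeneric("modelWeights", function(object) standardGeneric("modelWeights"))

#' @rdname CocoonSVM-class
#' @export
setGeneric("modelBias", function(object) standardGeneric("modelBias"))

#' @rdname CocoonSVM-class
#' @export
setGeneric("normParams", function(object) standardGeneric("normParams"))

#' Signed decision score of a linear cocoon classifier
#'
#' Returns \code{w . z + b} for each supplied raw integrated feature vector,
#' where \code{z} is the embedded z-score transform of the input.  The
#' predicted label is 1 (male) exactly when the score is strictly positive.
#'
#' @param object a trained [CocoonSVM-class]
#' @param x numeric vector (one IFV) or matrix (rows = IFVs)
#' @return numeric vector of signed scores
#' @export
setGeneric("decisionValue", function(object, x) standardGeneric("decisionValue"))

#' @rdname ConfusionMatrix-class
#' @param object a \code{ConfusionMatrix}
#' @export
setGeneric("cmCounts", function(object) standardGeneric("cmCounts"))
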