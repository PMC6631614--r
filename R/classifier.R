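# Linear maximum-margin classification: stratified hold-out split, soft-margin
# SVM training in normalized feature space, and deterministic scoring with the
# male-positive label convention (1 = male, 0 = female; a score of exactly
# zero maps to female).

#' Stratified hold-out split
#'
#' Per gender, exactly \code{floor(trainFrac * n_gender)} records go to
#' training and the remainder to testing; membership within a gender is
#' randomized by \code{seed}.  Floor rounding per class reproduces the
#' standard 60/40 protocol cell counts (e.g. 47/44 males/females ->
#' 28+26 train, 19+18 test).
#'
#' @param labels vector of 0/1 gender labels, no NA
#' @param trainFrac training fraction in (0, 1), default 0.6
#' @param seed integer seed
#' @return list with sorted integer index vectors \code{train} and \code{test}
#' @export
stratifiedHoldoutSplit <- function(labels, trainFrac = 0.6, seed) {
  if (any(is.na(labels)) || !all(labels %in% c(0, 1)))
    stop("every record must carry a 0/1 label for a stratified split")
  stopifnot(trainFrac > 0, trainFrac < 1)
  train <- integer()
  withr::with_seed(as.integer(seed), {
    for (g in c(1, 0)) {
      idx <- which(labels == g)
      nTrain <- floor(trainFrac * length(idx))
      train <- c(train, sort(sample(idx, nTrain)))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Train the linear soft-margin SVM cocoon classifier
#'
#' Fits z-score normalization on the training rows, then minimizes the
#' soft-margin hinge objective \code{0.5 ||w||^2 + C sum(hinge)} with a linear
#' kernel (solved by libsvm via \pkg{e1071} at tolerance 1e-6).  The returned
#' model embeds \code{(w, b)} and the normalization parameters, so raw
#' integrated feature vectors can be scored directly.
#'
#' @param X numeric matrix of raw IFVs, one row per cocoon
#' @param y 0/1 labels (1 = male), both classes present
#' @param cReg soft-margin penalty C, default 1
#' @param sdType passed to [fitNormalizer()]
#' @return a [CocoonSVM-class]
#' @export
trainLinearSVM <- function(X, y, cReg = 1, sdType = "population") {
  X <- as.matrix(X)
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("labels must be 0/1 with no NA")
  if (length(unique(y)) < 2L)
    stop("both classes must be present to train a binary classifier")
  if (length(y) != nrow(X)) stop("length mismatch between X and y")
  np <- fitNormalizer(X, sdType = sdType)
  Z <- applyZscore(X, np)
  yf <- factor(y, levels = c(1, 0))
  fit <- e1071::svm(Z, yf, type = "C-classification", kernel = "linear",
                    cost = cReg, scale = FALSE, tolerance = 1e-6)
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # pin the sign convention: positive score = male (label 1)
  pred <- predict(fit, Z)
  scorePred <- as.numeric(Z %*% w + b > 0)
  if (mean(scorePred == (pred == "1")) < 0.5) { w <- -w; b <- -b }
  new("CocoonSVM", w = w, b = b, cReg = cReg, normParams = np,
      featureNames = np@featureNames, labelMap = c(male = 1, female = 0))
}

#' @rdname decisionValue
setMethod("decisionValue", "CocoonSVM", function(object, x) {
  z <- applyZscore(if (is.matrix(x)) x else matrix(x, nrow = 1L),
                   object@normParams)
  as.vector(z %*% object@w + object@b)
})

#' Predict gender labels from raw integrated feature vectors
#'
#' Applies the embedded normalization and the linear decision rule:
#' label 1 (male) iff \code{w . z + b > 0}; a score of exactly 0 maps to
#' female (0), the pinned tie rule.
#'
#' @param object a trained [CocoonSVM-class]
#' @param newdata numeric vector (one IFV) or matrix (rows = IFVs)
#' @return integer vector of 0/1 labels
#' @export
setMethod("predict", "CocoonSVM", function(object, newdata) {
  as.integer(decisionValue(object, newdata) > 0)
})

#' Save / load a trained model as JSON
#'
#' The model file is self-contained: weights, bias, penalty, normalization
#' parameters, feature order and label map, serialized at full precision.
#' \code{saveModelJSON(readModelJSON(f), f2)} reproduces \code{f} byte for
#' byte.
#'
#' @param model a [CocoonSVM-class]
#' @param path file path
#' @return \code{readModelJSON} returns a [CocoonSVM-class]
#' @export
saveModelJSON <- function(model, path) {
  stopifnot(is(model, "CocoonSVM"))
  obj <- list(w = model@w, b = model@b, C_reg = model@cReg,
              mu = model@normParams@mu, sigma = model@normParams@sigma,
              sd_type = model@normParams@sdType,
              feature_order = model@featureNames,
              label_map = as.list(model@labelMap))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname saveModelJSON
#' @export
readModelJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("w", "b", "C_reg", "mu", "sigma", "feature_order")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop("malformed model file, missing field(s): ",
                         paste(miss, collapse = ", "))
  np <- new("NormalizationParams", mu = as.numeric(obj$mu),
            sigma = as.numeric(obj$sigma),
            featureNames = as.character(obj$feature_order),
            sdType = if (is.null(obj$sd_type)) "population" else obj$sd_type)
  new("CocoonSVM", w = as.numeric(obj$w), b = as.numeric(obj$b),
      cReg = as.numeric(obj$C_reg), normParams = np,
      featureNames = np@featureNames,
      labelMap = c(male = 1, female = 0))
}
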