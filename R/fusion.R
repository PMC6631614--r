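# Feature fusion: the ordered nine-component integrated feature vector (IFV)
# combining cocoon weight with the shape descriptors, and z-score
# normalization with parameters learned on training data only.

#' Canonical order of the integrated feature vector
#' @export
ifvFeatureNames <- function() {
  c("W", "A", "P", "axis_ratio", "E", "C", "R", "S", "AC")
}

#' Build the integrated feature vector
#'
#' Fuses the measured weight with the shape descriptors into the fixed
#' nine-component order \code{(W, A, P, lambda1/lambda2, E, C, R, S, AC)}.
#' No rescaling is applied here; see [fitNormalizer()].
#'
#' By default the two moment-ellipse axis lengths enter as their ratio
#' (a dimensionless aspect measure consistent with the other shape ratios);
#' \code{lambdaMode = "pair"} keeps them as two separate entries instead,
#' giving a ten-component vector.
#'
#' @param weight cocoon weight in grams, positive and finite
#' @param sf named shape feature vector from [computeShapeFeatures()]
#' @param lambdaMode "ratio" (default) or "pair"
#' @return named numeric vector of length 9 (or 10 for "pair")
#' @export
buildIFV <- function(weight, sf, lambdaMode = c("ratio", "pair")) {
  lambdaMode <- match.arg(lambdaMode)
  if (length(weight) != 1L || !is.finite(weight) || weight <= 0)
    stop("weight must be a single positive finite value in grams")
  need <- c("A", "P", "axis_ratio", "E", "C", "R", "S", "AC",
            if (lambdaMode == "pair") c("lambda1", "lambda2"))
  if (!all(need %in% names(sf)))
    stop("shape features missing: ", paste(setdiff(need, names(sf)), collapse = ", "))
  if (any(!is.finite(sf[need]))) stop("non-finite shape feature values")
  if (lambdaMode == "ratio") {
    out <- c(W = weight, sf[c("A", "P", "axis_ratio", "E", "C", "R", "S", "AC")])
    names(out) <- ifvFeatureNames()
  } else {
    out <- c(W = weight,
             sf[c("A", "P", "lambda1", "lambda2", "E", "C", "R", "S", "AC")])
    names(out) <- c("W", "A", "P", "lambda1", "lambda2", "E", "C", "R", "S", "AC")
  }
  out
}

#' Fit z-score normalization parameters on training vectors
#'
#' Per-feature mean and standard deviation over the training set only; the
#' returned parameters are frozen and later applied unchanged to test or
#' production vectors, so no information leaks from evaluation data.
#' Population sd (denominator n) by default.
#'
#' @param X numeric matrix, one row per training IFV
#' @param sdType "population" (default) or "sample"
#' @return a [NormalizationParams-class]
#' @export
fitNormalizer <- function(X, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training vectors")
  mu <- colMeans(X)
  dev2 <- colMeans(sweep(X, 2L, mu)^2)
  sigma <- if (sdType == "population") sqrt(dev2)
           else sqrt(dev2 * nrow(X) / (nrow(X) - 1))
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("f", seq_along(mu))
  if (any(sigma <= 0))
    stop("zero-variance feature(s): ", paste(nm[sigma <= 0], collapse = ", "))
  new("NormalizationParams", mu = unname(mu), sigma = unname(sigma),
      featureNames = nm, sdType = sdType)
}

#' Apply z-score normalization
#'
#' Entry-wise \code{(x - mu) / sigma} with frozen parameters; values outside
#' the training range are transformed like any others (no clipping).
#'
#' @param x numeric vector (one IFV) or matrix (rows = IFVs)
#' @param params a [NormalizationParams-class]
#' @return normalized vector or matrix, same shape as \code{x}
#' @export
applyZscore <- function(x, params) {
  stopifnot(is(params, "NormalizationParams"))
  validObject(params)
  L <- length(params@mu)
  if (is.matrix(x)) {
    if (ncol(x) != L) stop("length mismatch: expected ", L, " features")
    sweep(sweep(x, 2L, params@mu), 2L, params@sigma, "/")
  } else {
    if (length(x) != L) stop("length mismatch: expected ", L, " features")
    (x - params@mu) / params@sigma
  }
}
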