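# Evaluation: male/female confusion matrix, the derived metric suite
# (accuracy, class recalls, class precisions, F1), and the repeated-trial
# repeatability statistic.

#' Build a male/female confusion matrix
#'
#' @param truth,pred equal-length vectors of 0/1 labels (1 = male)
#' @return a [ConfusionMatrix-class]
#' @export
confusionMatrix <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length")
  if (!all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1)))
    stop("labels must be 0 or 1")
  new("ConfusionMatrix",
      TM = sum(truth == 1 & pred == 1),
      TF = sum(truth == 0 & pred == 0),
      FM = sum(truth == 0 & pred == 1),
      FF = sum(truth == 1 & pred == 0))
}

#' Confusion-matrix metric suite
#'
#' Computes accuracy, true male rate (male recall), true female rate (female
#' recall), male predictive value (male precision), female predictive value
#' (female precision) and the F1 score of the male class:
#' \deqn{TMR = TM/(TM+FF),\ TFR = TF/(TF+FM),\ MPV = TM/(TM+FM),}
#' \deqn{FPV = TF/(TF+FF),\ F1 = 2 \cdot MPV \cdot TMR/(MPV+TMR).}
#' A ratio with zero denominator is reported as \code{NaN} and named in the
#' \code{undefined} element rather than silently set to 0.
#'
#' @param cm a [ConfusionMatrix-class]
#' @param f1 "male" (default: F1 of the male class) or "macro" (mean of the
#'   male-class and female-class F1 scores)
#' @return list with elements \code{accuracy, TMR, TFR, MPV, FPV, F1,
#'   undefined} (character vector of flagged undefined metrics)
#' @export
computeMetrics <- function(cm, f1 = c("male", "macro")) {
  stopifnot(is(cm, "ConfusionMatrix"))
  f1 <- match.arg(f1)
  TM <- cm@TM; TF <- cm@TF; FM <- cm@FM; FF <- cm@FF
  n <- TM + TF + FM + FF
  if (n == 0) stop("empty confusion matrix")
  safe <- function(num, den) if (den > 0) num / den else NaN
  out <- list(accuracy = (TM + TF) / n,
              TMR = safe(TM, TM + FF),
              TFR = safe(TF, TF + FM),
              MPV = safe(TM, TM + FM),
              FPV = safe(TF, TF + FF))
  f1m <- if (is.nan(out$MPV) || is.nan(out$TMR) || out$MPV + out$TMR == 0) NaN
         else 2 * out$MPV * out$TMR / (out$MPV + out$TMR)
  if (f1 == "male") {
    out$F1 <- f1m
  } else {
    f1f <- if (is.nan(out$FPV) || is.nan(out$TFR) || out$FPV + out$TFR == 0) NaN
           else 2 * out$FPV * out$TFR / (out$FPV + out$TFR)
    out$F1 <- mean(c(f1m, f1f))
  }
  out$undefined <- names(out)[vapply(out, function(v)
    is.numeric(v) && length(v) == 1 && is.nan(v), logical(1))]
  out
}

#' Reconstruct integer confusion counts from class sizes and printed rates
#'
#' Given the number of true males and females evaluated and the reported
#' true-male and true-female rates (typically printed to 4 decimals), finds
#' the integer counts \code{TM in 0..nMale} and \code{TF in 0..nFemale}
#' closest to those rates, and returns the implied confusion matrix.  Errors
#' if no integer count reproduces a rate to within one unit of its printed
#' precision (covering both rounding and truncation of the last digit).
#'
#' @param nMale,nFemale evaluated class sizes
#' @param tmr,tfr reported true male / true female rates
#' @param digits printed precision of the rates (default 4)
#' @return a [ConfusionMatrix-class]
#' @export
reconstructConfusion <- function(nMale, nFemale, tmr, tfr, digits = 4) {
  tol <- 10^(-digits)
  pick <- function(nn, rate, what) {
    k <- 0:nn
    err <- abs(k / nn - rate)
    if (min(err) > tol)
      stop("no integer ", what, " count matches the printed rate ", rate)
    k[which.min(err)]
  }
  TM <- pick(nMale, tmr, "true-male")
  TF <- pick(nFemale, tfr, "true-female")
  new("ConfusionMatrix", TM = as.integer(TM), TF = as.integer(TF),
      FM = as.integer(nFemale - TF), FF = as.integer(nMale - TM))
}

#' Repeated-trial repeatability statistic
#'
#' Fraction of specimens classified correctly in EVERY one of the repeated
#' full-pipeline trials: the number of records whose prediction is correct in
#' all trials over the total number of tested records.
#'
#' @param trialMatrix logical matrix, records x trials; TRUE = correctly
#'   classified in that trial
#' @return fraction in \[0, 1\]
#' @export
repeatability <- function(trialMatrix) {
  if (is.data.frame(trialMatrix)) trialMatrix <- as.matrix(trialMatrix)
  if (!is.matrix(trialMatrix) || !is.logical(trialMatrix))
    stop("trialMatrix must be a logical records x trials matrix")
  if (nrow(trialMatrix) < 1L || ncol(trialMatrix) < 1L)
    stop("need at least one record and one trial")
  if (anyNA(trialMatrix)) stop("trialMatrix must not contain NA")
  mean(rowSums(trialMatrix) == ncol(trialMatrix))
}
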