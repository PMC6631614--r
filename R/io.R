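# Artifact I/O: 8-bit grayscale PNG images, feature / ground-truth CSV files,
# report JSON, and batch export.  All round trips are lossless at the stated
# resolutions (images 8-bit, weights 0.01 g, features full precision).

#' Read / write an 8-bit grayscale cocoon image
#'
#' PNG only; multi-channel input is collapsed to its first channel.
#'
#' @param path file path
#' @param img integer matrix with values in 0..255
#' @return \code{readCocoonImage} returns an integer matrix
#' @export
readCocoonImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  m <- round(a * 255)
  storage.mode(m) <- "integer"
  m
}

#' @rdname readCocoonImage
#' @export
writeCocoonImage <- function(img, path) {
  stopifnot(is.matrix(img), min(img) >= 0, max(img) <= 255)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Write a batch to disk
#'
#' Images as \code{<index>.png} and ground truth as \code{truth.csv} with
#' header \code{index,breed,weight_g,label}.
#'
#' @param batch a [CocoonBatch-class]
#' @param dir output directory (created if absent)
#' @return the directory, invisibly
#' @export
writeBatch <- function(batch, dir) {
  stopifnot(is(batch, "CocoonBatch"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  info <- cocoonInfo(batch)
  imgs <- cocoonImages(batch)
  for (i in seq_len(nrow(info)))
    writeCocoonImage(imgs[[i]], file.path(dir, paste0(info$index[i], ".png")))
  writeTruthCSV(info, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read / write the ground-truth CSV
#'
#' Fixed header \code{index,breed,weight_g,label}; labels must be 0, 1 or
#' empty, indices unique.
#'
#' @param df data.frame with the truth columns
#' @param path file path
#' @return \code{readTruthCSV} returns a validated data.frame
#' @export
writeTruthCSV <- function(df, path) {
  need <- c("index", "breed", "weight_g", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("truth table missing column(s): ",
                         paste(miss, collapse = ", "))
  utils::write.csv(df[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTruthCSV
#' @export
readTruthCSV <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "breed", "weight_g", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("truth file ", path, " missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$index)) stop("duplicate cocoon indices in ", path)
  bad <- !(is.na(df$label) | df$label %in% c(0, 1))
  if (any(bad)) stop("invalid label value(s) in ", path, ": ",
                     paste(unique(df$label[bad]), collapse = ", "))
  df
}

#' Read / write the shape-feature CSV
#'
#' Fixed header \code{index,A,P,lambda1,lambda2,axis_ratio,E,C,R,S,AC}
#' (plus \code{weight_g} when present); numeric fields at full precision.
#'
#' @param df data.frame of per-cocoon features
#' @param path file path
#' @return \code{readFeatureCSV} returns a validated data.frame
#' @export
writeFeatureCSV <- function(df, path) {
  need <- c("index", "A", "P", "lambda1", "lambda2", "axis_ratio",
            "E", "C", "R", "S", "AC")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature table missing column(s): ",
                         paste(miss, collapse = ", "))
  cols <- c(need, intersect("weight_g", names(df)))
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(df[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "A", "P", "lambda1", "lambda2", "axis_ratio",
            "E", "C", "R", "S", "AC")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature file ", path, " missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Write an evaluation report as JSON
#'
#' @param report list as produced by [runExperiment()]
#' @param path file path
#' @export
writeReportJSON <- function(report, path) {
  jsonlite::write_json(report, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
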