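# Backlit-image segmentation: Otsu binarization, 8-connected components with
# traced boundaries, and the single-cocoon area gate.

#' Otsu threshold of an 8-bit grayscale image
#'
#' Returns the intensity level \code{t} in 0..255 that maximizes the
#' between-class variance of the histogram split \code{<= t} vs \code{> t}.
#' Ties are broken toward the smaller threshold, so the result is
#' deterministic.
#'
#' @param img integer/numeric matrix with values in 0..255
#' @return integer threshold level
#' @export
otsuThreshold <- function(img) {
  stopifnot(is.matrix(img), length(img) > 0)
  v <- as.integer(round(img))
  if (min(v) < 0 || max(v) > 255) stop("image values must lie in [0, 255]")
  if (min(v) == max(v))
    stop("constant image: no valid threshold splits a single intensity level")
  h <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  lev <- 0:255
  cw <- cumsum(h)                  # pixels with intensity <= t
  cs <- cumsum(h * lev)            # intensity sum up to t
  total <- cs[256]
  w0 <- cw[1:255] / n
  w1 <- 1 - w0
  valid <- cw[1:255] > 0 & cw[1:255] < n
  mu0 <- cs[1:255] / cw[1:255]
  mu1 <- (total - cs[1:255]) / (n - cw[1:255])
  sigmaB <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  # which.max returns the first (smallest t) maximum
  as.integer(which.max(sigmaB) - 1L)
}

#' Binarize an image at a threshold
#'
#' Foreground is the dark side of the split (\code{intensity <= t}): under
#' backlighting the cocoon shell is dark on a bright field.
#'
#' @param img integer/numeric matrix with values in 0..255
#' @param t threshold level
#' @return logical matrix, TRUE = foreground
#' @export
binarizeImage <- function(img, t) {
  stopifnot(is.matrix(img))
  img <= t
}

# 4-exterior boundary criterion: region pixels with at least one 4-neighbour
# outside the region (or outside the frame).
.boundaryMask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  up <- pad[1:nr, 2:(nc + 1)]; dn <- pad[3:(nr + 2), 2:(nc + 1)]
  lf <- pad[2:(nr + 1), 1:nc]; rt <- pad[2:(nr + 1), 3:(nc + 2)]
  core & !(up & dn & lf & rt)
}

# Moore-neighbour contour tracing (8-neighbour following) of one component's
# outer boundary, clockwise, with Jacob's stopping criterion.  Returns an
# ordered matrix of (row, col).  Works on a logical mask of the component.
.traceBoundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 1L)
    return(cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L))
  # start: topmost of the leftmost column containing the region
  cols <- (idx - 1L) %/% nr + 1L
  c0 <- min(cols)
  r0 <- min((idx[cols == c0] - 1L) %% nr + 1L)
  # clockwise Moore neighbourhood, 0-based: W, NW, N, NE, E, SE, S, SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  cap <- 4L * length(idx) + 8L
  path <- matrix(0L, cap, 2L)
  np <- 0L
  cur <- c(r0, c0)
  searchFrom <- 0L   # West is outside by construction of the start pixel
  start <- cur; firstMove <- NA_integer_
  repeat {
    np <- np + 1L
    path[np, ] <- cur
    moved <- NA_integer_
    for (k in 0:7) {
      d <- (searchFrom + k) %% 8L
      r <- cur[1] + dr[d + 1L]; c <- cur[2] + dc[d + 1L]
      if (inside(r, c)) { moved <- d; cur <- c(r, c); break }
    }
    if (is.na(moved)) break                     # single pixel / no neighbour
    if (np == 1L) firstMove <- moved
    # stop when the start pixel is re-entered by the same move (Jacob)
    if (np > 1L && cur[1] == start[1] && cur[2] == start[2] &&
        moved == firstMove) break
    searchFrom <- (moved + 6L) %% 8L            # backtrack, then clockwise
    if (np >= cap - 1L) break
  }
  # cyclic chain: the step from the last pixel back to the first closes it
  path[seq_len(np), , drop = FALSE]
}

#' Extract 8-connected components from a binary mask
#'
#' Components are found under 8-connectivity (diagonal neighbours connect, so
#' thin silhouette necks are not split), sorted by area descending, and
#' components smaller than \code{minSpeck} pixels (residual fiber fragments)
#' are dropped.  Each component carries its filled pixel set, its boundary
#' pixel set (region pixels with a 4-neighbour outside), and an ordered outer
#' contour traced by 8-neighbour following.
#'
#' @param mask logical matrix, TRUE = foreground
#' @param minSpeck minimum component area in pixels (default 10)
#' @return list of regions; each region is a list with elements
#'   \code{pixels} (n x 2 matrix of row, col), \code{area},
#'   \code{boundary} (m x 2 matrix), \code{contour} (ordered k x 2 matrix)
#' @export
extractComponents <- function(mask, minSpeck = 10L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nextLab <- 0L
  queue <- integer(sum(mask))
  offR <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  offC <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    nextLab <- nextLab + 1L
    labels[start] <- nextLab
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      pr <- (p - 1L) %% nr + 1L
      pc <- (p - 1L) %/% nr + 1L
      for (k in 1:8) {
        r <- pr + offR[k]; c <- pc + offC[k]
        if (r >= 1L && r <= nr && c >= 1L && c <= nc) {
          q <- (c - 1L) * nr + r
          if (mask[q] && labels[q] == 0L) {
            labels[q] <- nextLab
            tail <- tail + 1L
            queue[tail] <- q
          }
        }
      }
    }
  }
  if (nextLab == 0L) return(list())
  bmask <- .boundaryMask(mask)
  comps <- vector("list", nextLab)
  areas <- tabulate(labels[labels > 0L], nextLab)
  for (lab in seq_len(nextLab)) {
    if (areas[lab] < minSpeck) next
    idx <- which(labels == lab)
    px <- cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
    bidx <- idx[bmask[idx]]
    bd <- cbind(row = (bidx - 1L) %% nr + 1L, col = (bidx - 1L) %/% nr + 1L)
    sub <- matrix(FALSE, nr, nc); sub[idx] <- TRUE
    comps[[lab]] <- list(pixels = px, area = length(idx), boundary = bd,
                         contour = .traceBoundary(sub))
  }
  comps <- comps[!vapply(comps, is.null, logical(1))]
  comps[order(vapply(comps, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

#' Single-cocoon area gate
#'
#' Decides whether exactly one cocoon is present from the total foreground
#' area: above the upper bound means more than one cocoon entered the imaging
#' module (reject and eject), below the lower bound means no cocoon.  The
#' default bounds are the 500--550 px single-cocoon range observed at the
#' reference camera geometry; recalibrate with [calibrateGateBounds()] for
#' other setups.
#'
#' @param components list of regions from [extractComponents()]
#' @param areaBounds numeric \code{c(lo, hi)} in pixels, \code{lo < hi}
#' @param mode "total" (default) gates on total foreground area;
#'   "largest" gates on the largest component only
#' @return a [GateVerdict-class]
#' @export
singleCocoonGate <- function(components, areaBounds = c(500, 550),
                             mode = c("total", "largest")) {
  mode <- match.arg(mode)
  stopifnot(length(areaBounds) == 2L, areaBounds[1] < areaBounds[2])
  areas <- vapply(components, `[[`, numeric(1), "area")
  total <- if (length(areas) == 0) 0 else if (mode == "total") sum(areas) else max(areas)
  v <- if (total > areaBounds[2]) "reject_multiple"
       else if (total < areaBounds[1]) "reject_empty"
       else "accept"
  new("GateVerdict", verdict = v, totalArea = total,
      componentCount = length(components))
}

#' Calibrate single-cocoon gate bounds from a reference batch
#'
#' Returns \code{mean(areas) +/- 3 sd(areas)}, the empirical singleton band
#' for a batch of known single-cocoon foreground areas.
#'
#' @param areas numeric vector of singleton foreground areas (px)
#' @return numeric \code{c(lo, hi)}
#' @export
calibrateGateBounds <- function(areas) {
  stopifnot(length(areas) >= 2)
  m <- mean(areas); s <- stats::sd(areas)
  c(m - 3 * s, m + 3 * s)
}

#' Segment one backlit image into gated cocoon components
#'
#' Convenience wrapper: Otsu threshold, dark-side binarization, component
#' extraction, area gate.
#'
#' @inheritParams otsuThreshold
#' @inheritParams singleCocoonGate
#' @param minSpeck passed to [extractComponents()]
#' @return list with \code{threshold}, \code{mask}, \code{components},
#'   \code{gate} (a [GateVerdict-class])
#' @export
segmentImage <- function(img, areaBounds = c(500, 550), minSpeck = 10L,
                         mode = c("total", "largest")) {
  t <- otsuThreshold(img)
  mask <- binarizeImage(img, t)
  comps <- extractComponents(mask, minSpeck = minSpeck)
  list(threshold = t, mask = mask, components = comps,
       gate = singleCocoonGate(comps, areaBounds, mode = match.arg(mode)))
}
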