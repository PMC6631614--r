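# Shape descriptors of one segmented cocoon region: area, boundary-pixel
# perimeter, moment-ellipse axes, minimum-area bounding rectangle, convex hull
# geometry, and the derived dimensionless ratios.
#
# Pixel geometry: pixel (r, c) occupies the unit square
# [r-0.5, r+0.5] x [c-0.5, c+0.5].  The minimum bounding rectangle is
# computed over boundary-pixel CORNERS (an axis-aligned a x b pixel rectangle
# measures exactly a x b, and rectangularity never exceeds 1); the convex
# hull area is the convex-image pixel count over the center hull (solidity of
# a convex shape is exactly 1).

.checkRegion <- function(region, minPixels = 1L) {
  if (!is.list(region) || is.null(region$pixels))
    stop("region must be a component list from extractComponents()")
  if (nrow(region$pixels) < minPixels)
    stop("region has fewer than ", minPixels, " pixels")
  invisible(region)
}

#' Region area
#'
#' Number of pixels in the region.
#'
#' @param region a component from [extractComponents()]
#' @return integer pixel count
#' @export
regionArea <- function(region) {
  .checkRegion(region)
  nrow(region$pixels)
}

#' Region perimeter
#'
#' Default ("pixel") is the number of pixels in the boundary of the shape:
#' region pixels with at least one 4-neighbour outside the region.  The
#' "weighted" alternative is the chain-code length of the traced outer
#' contour (1 per axial step, sqrt(2) per diagonal step), which converges to
#' the true continuum perimeter and is exposed for sensitivity checks.
#'
#' @param region a component from [extractComponents()]
#' @param method "pixel" (boundary pixel count, default) or "weighted"
#' @return numeric perimeter
#' @export
regionPerimeter <- function(region, method = c("pixel", "weighted")) {
  .checkRegion(region)
  method <- match.arg(method)
  if (method == "pixel") return(nrow(region$boundary))
  ch <- region$contour
  if (nrow(ch) < 2L) return(as.numeric(nrow(ch)))
  nxt <- rbind(ch[-1L, , drop = FALSE], ch[1L, , drop = FALSE])
  step <- abs(nxt - ch)
  sum(ifelse(step[, 1] + step[, 2] == 2L, sqrt(2), 1)[step[, 1] + step[, 2] > 0])
}

#' Moment-ellipse axis lengths
#'
#' Major and minor axis lengths (pixels) of the ellipse with the same
#' normalized second central moments as the region:
#' \code{lambda = 4 * sqrt(eigenvalue)} of the 2x2 central second-moment
#' matrix of the pixel centers, with a +1/12 per-pixel correction (the
#' variance of the uniform distribution over a unit pixel) so a single row or
#' column of pixels still has nonzero extent.
#'
#' @param region a component from [extractComponents()]
#' @return named numeric \code{c(lambda1, lambda2)}, \code{lambda1 >= lambda2}
#' @export
momentEllipse <- function(region) {
  .checkRegion(region, minPixels = 2L)
  p <- region$pixels
  mr <- mean(p[, 1]); mc <- mean(p[, 2])
  dr <- p[, 1] - mr; dc <- p[, 2] - mc
  n <- nrow(p)
  m <- matrix(c(mean(dr^2) + 1 / 12, mean(dr * dc),
                mean(dr * dc), mean(dc^2) + 1 / 12), 2, 2)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("degenerate region: zero spatial variance")
  c(lambda1 = 4 * sqrt(ev[1]), lambda2 = 4 * sqrt(ev[2]))
}

# Corner points (unit-square convention) of the boundary pixels, the only
# candidates for convex-hull vertices.
.cornerPoints <- function(region) {
  b <- region$boundary
  if (nrow(b) == 0L) b <- region$pixels
  rbind(cbind(b[, 1] - 0.5, b[, 2] - 0.5),
        cbind(b[, 1] - 0.5, b[, 2] + 0.5),
        cbind(b[, 1] + 0.5, b[, 2] - 0.5),
        cbind(b[, 1] + 0.5, b[, 2] + 0.5))
}

#' Convex hull area and perimeter of a region
#'
#' The hull polygon is taken over the region's pixel centers.  \code{H} is
#' the convex-image area: the number of pixels whose center lies inside or on
#' that polygon.  Because every lattice point inside the hull of a digitally
#' convex region belongs to the region, the solidity \code{A/H} of a convex
#' shape is exactly 1, matching the defining property of the descriptor.
#' \code{P_hull} is the Euclidean perimeter of the hull polygon.
#'
#' @param region a component from [extractComponents()]
#' @return named numeric \code{c(H, P_hull)}
#' @export
convexHullGeometry <- function(region) {
  .checkRegion(region)
  p <- region$pixels
  hull <- p[grDevices::chull(p[, 2], p[, 1]), , drop = FALSE]
  if (nrow(hull) < 3L) {
    # collinear region: the hull degenerates to a segment
    d <- 0
    if (nrow(p) > 1L) d <- max(stats::dist(p))
    return(c(H = nrow(p), P_hull = 2 * d))
  }
  edges <- rbind(hull[-1L, , drop = FALSE], hull[1L, , drop = FALSE]) - hull
  Phull <- sum(sqrt(rowSums(edges^2)))
  # convex image: lattice points of the bounding box inside/on the polygon
  rows <- seq(min(p[, 1]), max(p[, 1]))
  cols <- seq(min(p[, 2]), max(p[, 2]))
  gy <- rep(rows, times = length(cols))
  gx <- rep(cols, each = length(rows))
  # orient counterclockwise in (x = col, y = row) coordinates
  x <- hull[, 2]; y <- hull[, 1]
  if (sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) < 0) {
    x <- rev(x); y <- rev(y)
  }
  inside <- rep(TRUE, length(gx))
  nv <- length(x)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cross <- (x[j] - x[i]) * (gy - y[i]) - (y[j] - y[i]) * (gx - x[i])
    inside <- inside & cross >= -1e-9
  }
  c(H = sum(inside), P_hull = Phull)
}

#' Minimum-area bounding rectangle
#'
#' Rotating-calipers minimum over the convex hull of the region's
#' boundary-pixel corners: for every hull edge orientation the axis-aligned
#' extent in that frame is measured, and the orientation with the smallest
#' area wins.  \code{Lb >= Wb}, \code{Ar = Lb * Wb}.
#'
#' @param region a component from [extractComponents()]
#' @return named numeric \code{c(Lb, Wb, Ar)}
#' @export
minBoundingRect <- function(region) {
  .checkRegion(region)
  pts <- .cornerPoints(region)
  hull <- pts[grDevices::chull(pts[, 2], pts[, 1]), , drop = FALSE]
  if (nrow(hull) < 3L) stop("degenerate region: hull has fewer than 3 vertices")
  x <- hull[, 2]; y <- hull[, 1]
  ex <- c(x[-1], x[1]) - x
  ey <- c(y[-1], y[1]) - y
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 0
  ux <- ex[keep] / len[keep]; uy <- ey[keep] / len[keep]
  best <- c(Lb = Inf, Wb = Inf, Ar = Inf)
  for (i in seq_along(ux)) {
    pr1 <- x * ux[i] + y * uy[i]       # along the edge
    pr2 <- -x * uy[i] + y * ux[i]      # perpendicular
    d1 <- diff(range(pr1)); d2 <- diff(range(pr2))
    ar <- d1 * d2
    if (ar < best["Ar"])
      best <- c(Lb = max(d1, d2), Wb = min(d1, d2), Ar = ar)
  }
  best
}

#' Compute the full shape feature vector of a region
#'
#' Assembles the descriptor suite of a single accepted cocoon silhouette:
#' \describe{
#'   \item{A}{area: number of region pixels}
#'   \item{P}{perimeter: number of boundary pixels (see [regionPerimeter()])}
#'   \item{lambda1, lambda2}{moment-ellipse major/minor axis lengths (px)}
#'   \item{axis_ratio}{lambda1 / lambda2}
#'   \item{E}{eccentricity Lb / Wb of the minimum bounding rectangle (>= 1;
#'     an aspect ratio, not the classical ellipse eccentricity)}
#'   \item{C}{circularity A / P^2}
#'   \item{R}{rectangularity A / Ar}
#'   \item{S}{solidity A / H (1 for convex shapes)}
#'   \item{AC}{convexity: hull perimeter / region perimeter}
#' }
#'
#' @param region a component from [extractComponents()]
#' @param perimeterMethod passed to [regionPerimeter()]
#' @return named numeric vector with elements
#'   \code{A, P, lambda1, lambda2, axis_ratio, E, C, R, S, AC}
#' @export
computeShapeFeatures <- function(region, perimeterMethod = c("pixel", "weighted")) {
  .checkRegion(region, minPixels = 2L)
  A <- regionArea(region)
  P <- regionPerimeter(region, method = match.arg(perimeterMethod))
  lam <- momentEllipse(region)
  mbr <- minBoundingRect(region)
  hull <- convexHullGeometry(region)
  c(A = A, P = P,
    lambda1 = unname(lam["lambda1"]), lambda2 = unname(lam["lambda2"]),
    axis_ratio = unname(lam["lambda1"] / lam["lambda2"]),
    E = unname(mbr["Lb"] / mbr["Wb"]),
    C = A / P^2,
    R = unname(A / mbr["Ar"]),
    S = unname(A / hull["H"]),
    AC = unname(hull["P_hull"] / P))
}
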