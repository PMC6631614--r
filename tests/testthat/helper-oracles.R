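# Independent oracles and fixture builders shared across the suite.
# Each oracle deliberately uses a different algorithm (or package) than the
# implementation it checks.

# Exhaustive Otsu: literal search over all 256 candidate thresholds, means
# computed directly from the split histograms.
otsuOracle <- function(img) {
  v <- as.integer(round(img))
  best <- -Inf; bt <- NA_integer_
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best) { best <- s; bt <- t }   # strict > keeps the smaller t
  }
  bt
}

# Component count under 8-connectivity via igraph on the pixel adjacency
# graph (independent of the package's BFS labelling).
componentCountOracle <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
  key <- paste(r, c)
  edges <- character(0)
  off <- cbind(dr = c(-1, -1, -1, 0), dc = c(-1, 0, 1, -1))
  for (k in 1:4) {
    r2 <- r + off[k, 1]; c2 <- c + off[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(mask)
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok)) edges <- c(edges, rbind(key[ok], paste(r2[ok], c2[ok])))
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges)) data.frame(from = edges[c(TRUE, FALSE)],
                                  to = edges[c(FALSE, TRUE)])
    else data.frame(from = character(), to = character()),
    directed = FALSE, vertices = data.frame(name = key))
  igraph::components(g)$no
}

# Brute-force boundary-pixel count: pad and scan for region pixels with an
# exterior 4-neighbour, written with explicit loops.
perimeterOracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  cnt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    nb <- c(if (i > 1) mask[i - 1, j] else FALSE,
            if (i < nr) mask[i + 1, j] else FALSE,
            if (j > 1) mask[i, j - 1] else FALSE,
            if (j < nc) mask[i, j + 1] else FALSE)
    if (!all(nb)) cnt <- cnt + 1L
  }
  cnt
}

# Gift-wrapping (Jarvis march) convex hull over a point set, returning hull
# vertices in order; independent of grDevices::chull.
giftWrapHull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1L) 2L else 1L
    for (k in seq_len(n)) {
      if (k == cur || k == cand) next
      cross <- (pts[cand, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
               (pts[cand, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      d2c <- sum((pts[cand, ] - pts[cur, ])^2)
      d2k <- sum((pts[k, ] - pts[cur, ])^2)
      if (cross < 0 || (abs(cross) < 1e-12 && d2k > d2c)) cand <- k
    }
    cur <- cand
    if (cur == start) break
    if (length(hull) > n) break
  }
  pts[hull, , drop = FALSE]
}

# Count lattice points (pixel centers) inside or on a convex polygon: for
# every edge, a point must lie on the same side as the polygon centroid.
latticeCountOracle <- function(hull, pixels) {
  rows <- seq(min(pixels[, 1]), max(pixels[, 1]))
  cols <- seq(min(pixels[, 2]), max(pixels[, 2]))
  ctr <- colMeans(hull)
  cnt <- 0L
  for (r in rows) for (c in cols) {
    ok <- TRUE
    for (i in seq_len(nrow(hull))) {
      j <- if (i == nrow(hull)) 1L else i + 1L
      e <- hull[j, ] - hull[i, ]
      cq <- e[1] * (c - hull[i, 2]) - e[2] * (r - hull[i, 1])
      cc <- e[1] * (ctr[2] - hull[i, 2]) - e[2] * (ctr[1] - hull[i, 1])
      if (abs(cq) > 1e-9 && sign(cq) != sign(cc)) { ok <- FALSE; break }
    }
    if (ok) cnt <- cnt + 1L
  }
  cnt
}

shoelaceOracle <- function(pts) {
  x <- pts[, 2]; y <- pts[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Maximum-margin direction search for separable 2-D point sets: scan
# orientations on a fine grid; for each direction the best margin is half the
# gap between the classes' projections.
maxMarginOracle2d <- function(X, y, nAngles = 20000L) {
  best <- -Inf
  for (th in seq(0, pi, length.out = nAngles)) {
    u <- c(cos(th), sin(th))
    p1 <- X[y == 1, , drop = FALSE] %*% u
    p0 <- X[y == 0, , drop = FALSE] %*% u
    gap <- max(min(p1) - max(p0), min(p0) - max(p1))
    if (gap / 2 > best) best <- gap / 2
  }
  best
}

# Build a region (as extractComponents returns it) from a logical mask that
# must contain exactly one component.
regionFromMask <- function(mask, minSpeck = 1L) {
  comps <- extractComponents(mask, minSpeck = minSpeck)
  stopifnot(length(comps) == 1L)
  comps[[1L]]
}

discMask <- function(r, pad = 3L) {
  n <- 2L * r + 2L * pad
  ctr <- r + pad + 0.5
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  (row - ctr)^2 + (col - ctr)^2 <= r^2
}

rectMask <- function(a, b, pad = 2L) {
  m <- matrix(FALSE, b + 2L * pad, a + 2L * pad)
  m[(pad + 1):(pad + b), (pad + 1):(pad + a)] <- TRUE
  m
}

# Filled rectangle a x b rotated by angle (degrees) about its centre,
# rasterized on pixel centers.
rotRectMask <- function(a, b, angleDeg, pad = 4L) {
  th <- angleDeg * pi / 180
  n <- ceiling(sqrt(a^2 + b^2)) + 2L * pad
  ctr <- (n + 1) / 2
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  xr <- (col - ctr) * cos(th) + (row - ctr) * sin(th)
  yr <- -(col - ctr) * sin(th) + (row - ctr) * cos(th)
  abs(xr) <= a / 2 & abs(yr) <= b / 2
}
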