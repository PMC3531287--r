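#' Construct a spore point pattern
#'
#' @param points n x 2 matrix (or data.frame) of spore coordinates, um.
#' @param center analysis disc centre `(x, y)`, um.
#' @param radius analysis disc radius, um (default 50).
#' @return a [SporePattern-class] object.
#' @export
sporePattern <- function(points, center = c(0, 0), radius = 50) {
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(0), 0, 2)
  dimnames(points) <- NULL
  new("SporePattern",
    points = points, center = as.numeric(center),
    radius = radius
  )
}

#' Count spores on a regular grid
#'
#' Divides a square analysis window (default: a square of side 1.2 times
#' the disc diameter centred on the disc) into an `n x n` grid and counts
#' the points falling in each cell; points outside the window are ignored.
#'
#' @param pattern a [SporePattern-class] object.
#' @param window window as `c(xmin, xmax, ymin, ymax)` um, or `NULL` for
#'   the default centred square.
#' @param n grid cells per side (default 100).
#' @return a [DensityField-class] holding the counts (total equals the
#'   number of in-window points).
#' @export
concentrationGrid <- function(pattern, window = NULL, n = 100) {
  stopifnot(is(pattern, "SporePattern"))
  n <- .asCount(n, "n")
  if (is.null(window)) {
    half <- 1.2 * pattern@radius
    window <- c(
      pattern@center[1] - half, pattern@center[1] + half,
      pattern@center[2] - half, pattern@center[2] + half
    )
  }
  if (window[2] <= window[1] || window[4] <= window[3]) {
    stop("degenerate window", call. = FALSE)
  }
  cs <- (window[2] - window[1]) / n
  csY <- (window[4] - window[3]) / n
  if (abs(cs - csY) > 1e-9) stop("window must be square", call. = FALSE)
  counts <- matrix(0, n, n)
  p <- pattern@points
  if (nrow(p)) {
    ix <- floor((p[, 1] - window[1]) / cs) + 1
    iy <- floor((p[, 2] - window[3]) / cs) + 1
    ix[p[, 1] == window[2]] <- n # closed upper edge
    iy[p[, 2] == window[4]] <- n
    keep <- ix >= 1 & ix <= n & iy >= 1 & iy <= n
    if (any(keep)) {
      tab <- table(factor(ix[keep], levels = 1:n), factor(iy[keep], levels = 1:n))
      counts <- matrix(as.numeric(tab), n, n)
    }
  }
  new("DensityField",
    values = counts, origin = c(window[1], window[3]),
    cellSize = cs
  )
}

#' Gaussian-smoothed local density field
#'
#' Convolves a concentration grid with a unit-mass discrete Gaussian
#' kernel, emulating the weighted averaging performed by an OCT beam of
#' finite footprint. Edges are handled by renormalized truncation (each
#' node is divided by the kernel mass actually falling inside the grid), so
#' total mass is conserved away from the window edges.
#'
#' @param grid a [DensityField-class] of counts, from
#'   [concentrationGrid()].
#' @param sigma kernel standard deviation in grid cells (default 2).
#' @return a [DensityField-class] of smoothed densities.
#' @export
localDensityField <- function(grid, sigma = 2) {
  stopifnot(is(grid, "DensityField"))
  .assertScalar(sigma, "sigma", lower = 1e-12)
  R <- ceiling(3 * sigma)
  off <- -R:R
  k1 <- exp(-off^2 / (2 * sigma^2))
  K <- outer(k1, k1)
  K <- K / sum(K)
  v <- grid@values
  n1 <- nrow(v)
  n2 <- ncol(v)
  out <- matrix(0, n1, n2)
  wsum <- matrix(0, n1, n2)
  for (a in seq_along(off)) {
    for (b in seq_along(off)) {
      dx <- off[a]
      dy <- off[b]
      sx <- max(1, 1 - dx):min(n1, n1 - dx)
      sy <- max(1, 1 - dy):min(n2, n2 - dy)
      out[sx + dx, sy + dy] <- out[sx + dx, sy + dy] + K[a, b] * v[sx, sy]
      wsum[sx, sy] <- wsum[sx, sy] + K[a, b]
    }
  }
  out <- out / wsum
  new("DensityField",
    values = out, origin = grid@origin,
    cellSize = grid@cellSize
  )
}

#' Radial distribution of a density field
#'
#' Averages the field over all grid nodes at a fixed radius from the
#' centre, in bins one grid cell wide, out to the disc radius.
#'
#' @param field a [DensityField-class] object.
#' @param center `(x, y)` um; must lie inside the grid.
#' @param maxRadius outermost radius, um (default: the largest radius fully
#'   inside the window).
#' @return a data.frame with `bin`, `rInner`, `rMid`, `mean`, `count`; the
#'   curve has `floor(maxRadius / cellSize)` bins.
#' @export
radialDensityOfField <- function(field, center, maxRadius = NULL) {
  stopifnot(is(field, "DensityField"))
  n1 <- nrow(field@values)
  n2 <- ncol(field@values)
  cs <- field@cellSize
  xs <- field@origin[1] + (seq_len(n1) - 0.5) * cs
  ys <- field@origin[2] + (seq_len(n2) - 0.5) * cs
  if (center[1] < min(xs) || center[1] > max(xs) ||
    center[2] < min(ys) || center[2] > max(ys)) {
    stop("center must lie inside the grid", call. = FALSE)
  }
  if (is.null(maxRadius)) {
    maxRadius <- min(
      center[1] - field@origin[1],
      field@origin[1] + n1 * cs - center[1],
      center[2] - field@origin[2],
      field@origin[2] + n2 * cs - center[2]
    )
  }
  nb <- floor(maxRadius / cs)
  r <- sqrt(outer(xs - center[1], rep(1, n2))^2 +
    outer(rep(1, n1), ys - center[2])^2)
  bin <- floor(r / cs) + 1
  keep <- bin >= 1 & bin <= nb
  vals <- split(field@values[keep], factor(bin[keep], levels = seq_len(nb)))
  data.frame(
    bin = seq_len(nb),
    rInner = (seq_len(nb) - 1) * cs, rMid = (seq_len(nb) - 0.5) * cs,
    mean = vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
      numeric(1)
    ),
    count = lengths(vals)
  )
}

#' Angular distribution of spores in a disc
#'
#' Counts spores per pie-slice sector about the disc centre, by default
#' directly from the raw point coordinates (exact); alternatively from the
#' nodes of a concentration grid, summing grid counts by the sector of the
#' node centre.
#'
#' @param pattern a [SporePattern-class] object.
#' @param sectorWidth sector width, degrees; must divide 360 (default 3,
#'   giving 120 sectors).
#' @param grid optional [DensityField-class] of counts; when supplied the
#'   counts are accumulated from grid nodes inside the disc instead of raw
#'   points.
#' @return a data.frame with `sector`, `angleStart`, `angleMid`, `count`;
#'   counts sum to the number of in-disc points (or in-disc grid counts).
#' @export
angularSporeCounts <- function(pattern, sectorWidth = 3, grid = NULL) {
  stopifnot(is(pattern, "SporePattern"))
  if (360 %% sectorWidth != 0) {
    stop("sectorWidth must divide 360", call. = FALSE)
  }
  nS <- as.integer(360 / sectorWidth)
  cx <- pattern@center[1]
  cy <- pattern@center[2]
  if (is.null(grid)) {
    p <- pattern@points
    w <- rep(1, nrow(p))
    px <- p[, 1]
    py <- p[, 2]
  } else {
    stopifnot(is(grid, "DensityField"))
    n1 <- nrow(grid@values)
    n2 <- ncol(grid@values)
    px <- rep(grid@origin[1] + (seq_len(n1) - 0.5) * grid@cellSize, n2)
    py <- rep(grid@origin[2] + (seq_len(n2) - 0.5) * grid@cellSize,
      each = n1
    )
    w <- as.vector(grid@values)
  }
  r <- sqrt((px - cx)^2 + (py - cy)^2)
  keep <- r <= pattern@radius
  ang <- (atan2(py - cy, px - cx) * 180 / pi + 360) %% 360
  sector <- pmin(floor(ang / sectorWidth), nS - 1) + 1
  counts <- vapply(seq_len(nS), function(s) {
    sum(w[keep & sector == s])
  }, numeric(1))
  data.frame(
    sector = seq_len(nS),
    angleStart = (seq_len(nS) - 1) * sectorWidth,
    angleMid = (seq_len(nS) - 0.5) * sectorWidth,
    count = counts
  )
}

#' Nearest-neighbour distances of a point set
#'
#' Convenience metric for comparing spore clustering against shuffled
#' controls.
#'
#' @param points n x 2 coordinate matrix.
#' @return numeric vector of each point's distance to its nearest
#'   neighbour (length 0 when fewer than 2 points).
#' @export
nearestNeighbourDistances <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) {
    return(numeric(0))
  }
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}
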