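#' Construct an intensity volume
#'
#' @param data 3D numeric array indexed `[row (y), col (x), z]` with values
#'   in \[0, 255\]; `z = 1` is the base slice.
#' @param pxUm in-plane pixel spacing, um/pixel (default 3.3).
#' @param sliceUm slice spacing, um.
#' @return an [IntensityVolume-class] object.
#' @export
intensityVolume <- function(data, pxUm = 3.3, sliceUm = pxUm) {
  new("IntensityVolume", data = data, pxUm = pxUm, sliceUm = sliceUm)
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Uses the ITU-R 601 luminance weights `0.299 R + 0.587 G + 0.114 B`,
#' rounded to the nearest integer and clipped to \[0, 255\]. A matrix input
#' (already grayscale) is returned unchanged.
#'
#' @param img an `h x w x 3` array with channel values in \[0, 255\], or an
#'   `h x w` matrix.
#' @return an `h x w` matrix of grayscale intensities.
#' @export
toGrayscale <- function(img) {
  if (is.matrix(img)) {
    return(img)
  }
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) {
    stop("expected an h x w x 3 RGB array (or a grayscale matrix); got dims ",
      paste(d, collapse = " x "),
      call. = FALSE
    )
  }
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(pmin(pmax(round(g), 0), 255), d[1], d[2])
}

#' Extract an in-plane cross-section
#'
#' Fixes the z index and returns the xy-plane slice (parallel to the agar
#' surface) without resampling. `z = 1` is the base of the mound; the slice
#' at height `h` um is `z = h / sliceSpacing(volume) + 1`.
#'
#' @param volume an [IntensityVolume-class] object.
#' @param z slice index (1-based).
#' @return the slice as a matrix `[row (y), col (x)]`.
#' @export
extractPlane <- function(volume, z) {
  stopifnot(is(volume, "IntensityVolume"))
  nz <- dim(volume@data)[3]
  if (length(z) != 1 || is.na(z) || z < 1 || z > nz) {
    stop("z must lie in [1, ", nz, "]", call. = FALSE)
  }
  volume@data[, , z]
}

#' Intensity-weighted image moments
#'
#' Raw moments `m_pq = sum_x sum_y x^p y^q I(x, y)` and central second
#' moments about the intensity centroid, with `x` the column index and `y`
#' the row index (1-based pixel coordinates). The image is used as weights,
#' not binarized.
#'
#' @param I an image matrix.
#' @return a list with `m00`, `m10`, `m01`, `centroid` (`(x, y)`), `mu20`,
#'   `mu11`, `mu02`.
#' @export
imageMoments <- function(I) {
  m00 <- sum(I)
  if (!is.finite(m00) || m00 <= 0) {
    stop("undefined centroid: image has no intensity mass", call. = FALSE)
  }
  x <- col(I)
  y <- row(I)
  m10 <- sum(x * I)
  m01 <- sum(y * I)
  xc <- m10 / m00
  yc <- m01 / m00
  list(
    m00 = m00, m10 = m10, m01 = m01, centroid = c(xc, yc),
    mu20 = sum((x - xc)^2 * I), mu11 = sum((x - xc) * (y - yc) * I),
    mu02 = sum((y - yc)^2 * I)
  )
}

#' Fit an equivalent ellipse to a cross-section
#'
#' Builds the covariance matrix from normalized central moments
#' (`mu20/m00` etc.), takes its eigen-decomposition and reports semi-axes
#' `2 * sqrt(lambda)` (exact for a uniform-intensity ellipse, whose variance
#' along an axis is `a^2 / 4`), the principal-axis orientation in degrees
#' counter-clockwise from +x mapped to (-90, 90], and the eccentricity from
#' the axis ratio. Nearly isotropic or degenerate (collinear-mass) images
#' yield a flagged fit whose orientation is unconstrained.
#'
#' @param I an image matrix with positive total intensity.
#' @return an [EllipseFit-class] object.
#' @export
ellipseFit <- function(I) {
  mom <- imageMoments(I)
  C <- matrix(
    c(mom$mu20, mom$mu11, mom$mu11, mom$mu02) / mom$m00, 2, 2
  )
  ev <- eigen(C, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  flagged <- FALSE
  if (lam[1] <= 0) {
    stop("degenerate covariance: all mass at a single pixel", call. = FALSE)
  }
  if (lam[2] / lam[1] < 1e-12) flagged <- TRUE # collinear mass
  a <- 2 * sqrt(lam[1])
  b <- 2 * sqrt(lam[2])
  # collinear mass gives b -> 0; keep the eccentricity inside [0, 1)
  ecc <- min(sqrt(max(0, 1 - (b / a)^2)), 1 - 1e-12)
  if (ecc < 0.05) flagged <- TRUE # near-circular: orientation unconstrained
  v <- ev$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  new("EllipseFit",
    centroid = mom$centroid, orientation = ang,
    eccentricity = ecc, semiMajor = a, semiMinor = max(b, 1e-12),
    m00 = mom$m00, flagged = flagged
  )
}

# normalized elliptical radius of every pixel under a fit
.ellipticalRadius <- function(I, fit) {
  th <- fit@orientation * pi / 180
  dx <- col(I) - fit@centroid[1]
  dy <- row(I) - fit@centroid[2]
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  sqrt((u / fit@semiMajor)^2 + (v / fit@semiMinor)^2)
}

#' Elliptical-annulus radial intensity profile
#'
#' Bins pixels by their normalized elliptical radius (the affine-invariant
#' coordinate induced by the fit, 1 at the fitted ellipse boundary) into
#' annuli of equal radial width and reports per-annulus mean intensity,
#' standard deviation and pixel count. The per-annulus standard deviation
#' measures the density variation within a ring.
#'
#' @param I an image matrix.
#' @param fit an [EllipseFit-class] for the cross-section (default: fitted
#'   from `I`).
#' @param nRings number of annuli (default 20).
#' @param maxRadius outermost normalized radius analyzed (default 1.5).
#' @return a data.frame with `ring`, `rInner`, `rOuter`, `mean`, `sd`,
#'   `count`; counts sum to the number of pixels inside the outermost
#'   ellipse.
#' @export
radialProfile <- function(I, fit = ellipseFit(I), nRings = 20,
                          maxRadius = 1.5) {
  nRings <- .asCount(nRings, "nRings")
  r <- .ellipticalRadius(I, fit)
  width <- maxRadius / nRings
  bin <- pmin(floor(r / width), nRings - 1) + 1
  keep <- r <= maxRadius
  vals <- split(I[keep], bin[keep])
  ring <- as.integer(names(vals))
  out <- data.frame(
    ring = ring,
    rInner = (ring - 1) * width, rOuter = ring * width,
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, function(v) if (length(v) > 1) sd(v) else 0, numeric(1)),
    count = lengths(vals)
  )
  rownames(out) <- NULL
  out[order(out$ring), ]
}

#' Angular sector intensity profile
#'
#' Divides the masked domain into pie-slice sectors about a centre and
#' averages the intensity within each sector. Sectors are indexed
#' counter-clockwise from the +x axis.
#'
#' @param I an image matrix.
#' @param center sector centre `(x, y)` in pixel coordinates (default: the
#'   intensity centroid).
#' @param sectorWidth sector width in degrees; must divide 360 (default 10).
#' @param isovalue pixels at or above this intensity form the default
#'   domain mask (default 10, the outer-shell isovalue).
#' @param mask optional logical matrix overriding the isovalue mask.
#' @return a data.frame with `sector`, `angleStart`, `angleMid`, `mean`,
#'   `sd`, `count`; counts sum to the mask size.
#' @export
angularProfile <- function(I, center = imageMoments(I)$centroid,
                           sectorWidth = 10, isovalue = 10, mask = NULL) {
  if (360 %% sectorWidth != 0) {
    stop("sectorWidth must divide 360", call. = FALSE)
  }
  if (is.null(mask)) mask <- I >= isovalue
  nS <- as.integer(360 / sectorWidth)
  ang <- atan2(row(I) - center[2], col(I) - center[1]) * 180 / pi
  ang <- (ang + 360) %% 360
  sector <- pmin(floor(ang / sectorWidth), nS - 1) + 1
  vals <- split(I[mask], factor(sector[mask], levels = seq_len(nS)))
  out <- data.frame(
    sector = seq_len(nS),
    angleStart = (seq_len(nS) - 1) * sectorWidth,
    angleMid = (seq_len(nS) - 0.5) * sectorWidth,
    mean = vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
      numeric(1)
    ),
    sd = vapply(vals, function(v) if (length(v) > 1) sd(v) else 0, numeric(1)),
    count = lengths(vals)
  )
  rownames(out) <- NULL
  out
}

# mass-preserving centered moving average over histogram bins: each bin's
# mass is spread uniformly over its (edge-truncated) window
.smoothMassPreserving <- function(h, window) {
  k <- (window - 1) %/% 2
  n <- length(h)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - k)
    hi <- min(n, i + k)
    out[lo:hi] <- out[lo:hi] + h[i] / (hi - lo + 1)
  }
  out
}

#' Per-plane intensity distributions
#'
#' For every slice in `zRange`: the raw intensity histogram over the masked
#' cross-sectional disc, the same histogram normalized by the disc area
#' (total masked pixels), and a smoothed version (mass-preserving centered
#' moving average, default window 5 intensity bins).
#'
#' @param volume an [IntensityVolume-class] object.
#' @param zRange slice indices to analyze (default: all).
#' @param isovalue mask threshold defining the cross-sectional disc
#'   (default 10).
#' @param window smoothing window in intensity bins (odd; default 5).
#' @return a long data.frame with `z`, `heightUm`, `intensity` (0-255),
#'   `count`, `norm`, `smooth`. Slices with an empty mask are omitted.
#' @export
planeIntensityDistributions <- function(volume, zRange = NULL, isovalue = 10,
                                        window = 5) {
  stopifnot(is(volume, "IntensityVolume"))
  nz <- dim(volume@data)[3]
  if (is.null(zRange)) zRange <- seq_len(nz)
  stopifnot(all(zRange >= 1 & zRange <= nz))
  out <- lapply(zRange, function(z) {
    I <- volume@data[, , z]
    vals <- I[I >= isovalue]
    if (!length(vals)) {
      return(NULL)
    }
    counts <- tabulate(pmin(pmax(floor(vals), 0), 255) + 1, nbins = 256)
    nrm <- counts / sum(counts)
    data.frame(
      z = z, heightUm = (z - 1) * volume@sliceUm, intensity = 0:255,
      count = counts, norm = nrm,
      smooth = .smoothMassPreserving(nrm, window)
    )
  })
  do.call(rbind, out)
}

#' Cross-sectional semi-axes as a function of height
#'
#' Fits the moment ellipse to every slice restricted to pixels at or above
#' the surface isovalue, converts the semi-axes to micrometres, and
#' regresses each semi-axis on height. A linear decrease of both axes with
#' height is the signature of a cone-like mound.
#'
#' @param volume an [IntensityVolume-class] object.
#' @param isovalue surface threshold (default 10).
#' @param minPixels slices with fewer masked pixels are skipped
#'   (default 20; suppresses pixelation noise at the apex).
#' @return a list with `table` (per-slice `z`, `heightUm`, `semiMajorUm`,
#'   `semiMinorUm`, `orientation`, `eccentricity`, `maskPixels`),
#'   `majorSlope`, `majorR2`, `minorSlope`, `minorR2` (slopes in um/um).
#'   Errors when fewer than 3 slices carry mass.
#' @export
axesVsHeight <- function(volume, isovalue = 10, minPixels = 20) {
  stopifnot(is(volume, "IntensityVolume"))
  nz <- dim(volume@data)[3]
  rows <- list()
  for (z in seq_len(nz)) {
    I <- volume@data[, , z]
    Iw <- I * (I >= isovalue)
    npx <- sum(I >= isovalue)
    if (npx < minPixels || sum(Iw) <= 0) next
    fit <- ellipseFit(Iw)
    rows[[length(rows) + 1]] <- data.frame(
      z = z, heightUm = (z - 1) * volume@sliceUm,
      semiMajorUm = fit@semiMajor * volume@pxUm,
      semiMinorUm = fit@semiMinor * volume@pxUm,
      orientation = fit@orientation, eccentricity = fit@eccentricity,
      maskPixels = npx
    )
  }
  if (length(rows) < 3) {
    stop("need at least 3 slices with mass above the isovalue", call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  fitA <- lm(semiMajorUm ~ heightUm, data = tab)
  fitB <- lm(semiMinorUm ~ heightUm, data = tab)
  list(
    table = tab,
    majorSlope = unname(coef(fitA)[2]),
    majorR2 = summary(fitA)$r.squared,
    minorSlope = unname(coef(fitB)[2]),
    minorR2 = summary(fitB)$r.squared
  )
}

#' Extract high-density pockets as 3D connected components
#'
#' Thresholds the volume at an isovalue and labels the 26-connected
#' components of the resulting 3D mask.
#'
#' @param volume an [IntensityVolume-class] object.
#' @param isovalue threshold in (0, 255).
#' @param minVoxels drop components smaller than this many voxels (default 1,
#'   i.e. keep everything; a few voxels' worth suppresses speckle islands in
#'   noisy volumes).
#' @return a data.frame, one row per component, sorted by size: `label`,
#'   `voxels`, `volumeUm3`, `eqDiameterUm` (diameter of the
#'   equal-volume sphere), `xUm`, `yUm`, `zUm` (centroid). Empty when
#'   nothing exceeds the isovalue.
#' @export
isovolumePockets <- function(volume, isovalue, minVoxels = 1) {
  stopifnot(is(volume, "IntensityVolume"))
  .assertScalar(isovalue, "isovalue", 1e-9, 255 - 1e-9)
  mask <- volume@data >= isovalue
  empty <- data.frame(
    label = integer(), voxels = integer(), volumeUm3 = numeric(),
    eqDiameterUm = numeric(), xUm = numeric(), yUm = numeric(),
    zUm = numeric()
  )
  if (!any(mask)) {
    return(empty)
  }
  labels <- .label_components_26(mask, dim(mask))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  vxVol <- volume@pxUm^2 * volume@sliceUm
  n <- tabulate(lab)
  out <- data.frame(
    label = seq_along(n), voxels = n, volumeUm3 = n * vxVol,
    eqDiameterUm = (6 * n * vxVol / pi)^(1 / 3),
    xUm = vapply(
      seq_along(n),
      function(l) mean(idx[lab == l, 2] - 1) * volume@pxUm, numeric(1)
    ),
    yUm = vapply(
      seq_along(n),
      function(l) mean(idx[lab == l, 1] - 1) * volume@pxUm, numeric(1)
    ),
    zUm = vapply(
      seq_along(n),
      function(l) mean(idx[lab == l, 3] - 1) * volume@sliceUm, numeric(1)
    )
  )
  out <- out[out$voxels >= minVoxels, ]
  out[order(-out$voxels), ]
}
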