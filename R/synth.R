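#' Ground truth describing a synthetic mound volume
#'
#' Defaults emulate the gross structure of a scanned fruiting-body mound: a
#' linearly tapering elliptical cone with base semi-axes 60 x 40 um and apex
#' at 90 um, a roughly uniform interior intensity of 130 (the middle of the
#' observed 120-140 interior band) with Gaussian noise of sd 8, a dim
#' background below the surface isovalue, and optional embedded spherical
#' pockets of elevated intensity no larger than 25 um across.
#'
#' @param baseAxes base semi-axes `(a, b)`, um.
#' @param apexHeight apex height, um.
#' @param baseIntensity interior intensity in (0, 255).
#' @param noiseSd additive Gaussian noise sd (intensity units).
#' @param background exterior intensity.
#' @param pockets data.frame with columns `x`, `y`, `z`, `diameter`,
#'   `boost` (see [placePockets()]).
#' @return a [MoundTruth-class] object.
#' @export
moundTruth <- function(baseAxes = c(60, 40), apexHeight = 90,
                       baseIntensity = 130, noiseSd = 8, background = 2,
                       pockets = data.frame(
                         x = numeric(), y = numeric(), z = numeric(),
                         diameter = numeric(), boost = numeric()
                       )) {
  new("MoundTruth",
    baseAxes = as.numeric(baseAxes), apexHeight = apexHeight,
    baseIntensity = baseIntensity, noiseSd = noiseSd,
    background = background, pockets = pockets
  )
}

#' Plant high-density pockets in a mound truth
#'
#' Draws pocket centres by rejection sampling inside the cone with a
#' minimum centre separation of one pocket diameter (the larger of the
#' pair), preventing unintended merges of planted components.
#'
#' @param truth a [MoundTruth-class] object.
#' @param k number of pockets.
#' @param diamRange pocket diameter range, um (default 12-25).
#' @param boost added intensity inside a pocket (default 40).
#' @param seed RNG seed.
#' @param maxTries rejection-sampling budget per pocket.
#' @return the truth with `k` pockets added.
#' @export
placePockets <- function(truth, k, diamRange = c(12, 25), boost = 40,
                         seed = 1L, maxTries = 2000) {
  stopifnot(is(truth, "MoundTruth"))
  set.seed(seed)
  a0 <- truth@baseAxes[1]
  b0 <- truth@baseAxes[2]
  H <- truth@apexHeight
  p <- truth@pockets
  for (i in seq_len(k)) {
    d <- runif(1, diamRange[1], diamRange[2])
    r <- d / 2
    placed <- FALSE
    for (t in seq_len(maxTries)) {
      z <- runif(1, r, 0.8 * H)
      s <- 1 - z / H
      ae <- a0 * s - r
      be <- b0 * s - r
      if (ae <= 0 || be <= 0) next
      u <- runif(1)
      phi <- runif(1, 0, 2 * pi)
      x <- sqrt(u) * ae * cos(phi)
      y <- sqrt(u) * be * sin(phi)
      cand <- data.frame(x = x, y = y, z = z, diameter = d, boost = boost)
      tmp <- truth
      tmp@pockets <- cand
      if (!all(.pocketsInsideCone(tmp))) next
      if (nrow(p)) {
        sep <- sqrt((p$x - x)^2 + (p$y - y)^2 + (p$z - z)^2)
        if (any(sep < pmax(p$diameter, d))) next
      }
      p <- rbind(p, cand)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place pocket ", i, " within the rejection budget",
        call. = FALSE
      )
    }
  }
  truth@pockets <- p
  validObject(truth)
  truth
}

#' Generate a uniform-intensity ellipse phantom
#'
#' A filled ellipse of constant intensity (plus optional additive Gaussian
#' noise), used as a moment-fitting oracle: its intensity-weighted
#' covariance has eigenvalues `a^2/4` and `b^2/4`, so [ellipseFit()] should
#' recover the parameters exactly up to pixelation.
#'
#' @param a,b semi-axes in pixels (`a >= b > 0`).
#' @param angle orientation, degrees counter-clockwise from +x.
#' @param intensity fill intensity (default 200).
#' @param size image side length in pixels (default: fits the ellipse with
#'   a margin).
#' @param noiseSd additive Gaussian noise sd (default 0).
#' @param seed RNG seed (used only when `noiseSd > 0`).
#' @return a list with `image` (matrix) and `truth` (list of `a`, `b`,
#'   `angle`, `centroid`, `intensity`, `eccentricity`).
#' @export
synthEllipseImage <- function(a, b, angle = 0, intensity = 200,
                              size = 2 * ceiling(a) + 21, noiseSd = 0,
                              seed = 1L) {
  stopifnot(a >= b, b > 0)
  if (2 * a + 2 > size) stop("ellipse exceeds the frame", call. = FALSE)
  cx <- (size + 1) / 2
  cy <- (size + 1) / 2
  th <- angle * pi / 180
  # boundary pixels carry fractional coverage (4x4 subsampling) so the
  # discrete moments track the continuous uniform ellipse closely
  os <- 4
  sub <- (seq_len(os) - 0.5) / os - 0.5
  cover <- matrix(0, size, size)
  for (sx in sub) {
    for (sy in sub) {
      x <- col(cover) + sx - cx
      y <- row(cover) + sy - cy
      u <- cos(th) * x + sin(th) * y
      v <- -sin(th) * x + cos(th) * y
      cover <- cover + ((u / a)^2 + (v / b)^2 <= 1)
    }
  }
  img <- intensity * cover / os^2
  if (noiseSd > 0) {
    set.seed(seed)
    img <- pmin(pmax(img + rnorm(length(img), 0, noiseSd), 0), 255)
    dim(img) <- c(size, size)
  }
  list(
    image = img,
    truth = list(
      a = a, b = b, angle = angle, centroid = c(cx, cy),
      intensity = intensity,
      eccentricity = sqrt(1 - (b / a)^2)
    )
  )
}

#' Generate a synthetic cone-shaped mound volume
#'
#' Voxels inside the linearly tapering elliptical cone receive the base
#' intensity plus Gaussian noise; planted pocket spheres add their boost;
#' everything outside is background. Values are clipped to \[0, 255\], and
#' generation is deterministic under the seed.
#'
#' @param truth a [MoundTruth-class] object.
#' @param pxUm in-plane spacing, um/pixel (default 3.3).
#' @param sliceUm slice spacing, um (default 3.3).
#' @param marginUm background margin around the base ellipse, um.
#' @param seed RNG seed.
#' @return a list with `volume` (an [IntensityVolume-class]) and `truth`.
#' @export
synthMoundVolume <- function(truth = moundTruth(), pxUm = 3.3,
                             sliceUm = 3.3, marginUm = 15, seed = 1L) {
  stopifnot(is(truth, "MoundTruth"))
  validObject(truth)
  set.seed(seed)
  a0 <- truth@baseAxes[1]
  b0 <- truth@baseAxes[2]
  H <- truth@apexHeight
  nx <- 2 * ceiling((a0 + marginUm) / pxUm) + 1
  ny <- 2 * ceiling((b0 + marginUm) / pxUm) + 1
  nz <- ceiling(H / sliceUm)
  cxUm <- (floor(nx / 2)) * pxUm # cone axis, um from pixel (1,1)
  cyUm <- (floor(ny / 2)) * pxUm
  xs <- (seq_len(nx) - 1) * pxUm - cxUm
  ys <- (seq_len(ny) - 1) * pxUm - cyUm
  vol <- array(truth@background, dim = c(ny, nx, nz))
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  for (k in seq_len(nz)) {
    h <- (k - 1) * sliceUm
    s <- 1 - h / H
    if (s <= 0) next
    inside <- (X / (a0 * s))^2 + (Y / (b0 * s))^2 <= 1
    plane <- vol[, , k]
    n_in <- sum(inside)
    if (n_in > 0) {
      val <- truth@baseIntensity +
        if (truth@noiseSd > 0) rnorm(n_in, 0, truth@noiseSd) else 0
      plane[inside] <- val
    }
    p <- truth@pockets
    if (nrow(p)) {
      for (q in seq_len(nrow(p))) {
        r <- p$diameter[q] / 2
        dz <- h - p$z[q]
        if (abs(dz) > r) next
        rr <- sqrt(r^2 - dz^2)
        hit <- inside & ((X - p$x[q])^2 + (Y - p$y[q])^2 <= rr^2)
        plane[hit] <- plane[hit] + p$boost[q]
      }
    }
    vol[, , k] <- plane
  }
  vol <- pmin(pmax(vol, 0), 255)
  dim(vol) <- c(ny, nx, nz)
  list(
    volume = intensityVolume(vol, pxUm = pxUm, sliceUm = sliceUm),
    truth = truth,
    centerPx = c(x = floor(nx / 2) + 1, y = floor(ny / 2) + 1)
  )
}

#' Generate a clustered spore point pattern
#'
#' Cluster centres are uniform in the analysis disc; each cluster receives
#' a Poisson number of offspring (at least one) placed with isotropic
#' Gaussian scatter about its centre. The returned truth lists the centres
#' and the cluster membership of every point.
#'
#' @param nClusters number of clusters.
#' @param meanPerCluster mean points per cluster (Poisson).
#' @param sdUm Gaussian scatter sd, um.
#' @param center disc centre `(x, y)`, um.
#' @param radius disc radius, um; must exceed `sdUm`.
#' @param seed RNG seed.
#' @return a list with `pattern` (a [SporePattern-class]) and `truth`
#'   (list of `centers` and `membership`).
#' @export
synthClusteredSpores <- function(nClusters = 6, meanPerCluster = 30,
                                 sdUm = 3, center = c(0, 0), radius = 50,
                                 seed = 1L) {
  stopifnot(radius > sdUm)
  set.seed(seed)
  nClusters <- .asCount(nClusters, "nClusters")
  u <- runif(nClusters)
  phi <- runif(nClusters, 0, 2 * pi)
  ctr <- cbind(
    center[1] + radius * sqrt(u) * cos(phi),
    center[2] + radius * sqrt(u) * sin(phi)
  )
  sizes <- pmax(1L, rpois(nClusters, meanPerCluster))
  pts <- do.call(rbind, lapply(seq_len(nClusters), function(i) {
    cbind(
      rnorm(sizes[i], ctr[i, 1], sdUm),
      rnorm(sizes[i], ctr[i, 2], sdUm)
    )
  }))
  list(
    pattern = sporePattern(pts, center = center, radius = radius),
    truth = list(centers = ctr, membership = rep(seq_len(nClusters), sizes))
  )
}

#' Generate a uniform spore point pattern in a disc
#'
#' The matched null control for clustered patterns: `n` points i.i.d.
#' uniform over the analysis disc.
#'
#' @param n number of points.
#' @param center disc centre `(x, y)`, um.
#' @param radius disc radius, um.
#' @param seed RNG seed.
#' @return a [SporePattern-class] object.
#' @export
uniformSporePattern <- function(n, center = c(0, 0), radius = 50,
                                seed = 1L) {
  set.seed(seed)
  n <- .asCount(n, "n", min = 0L)
  u <- runif(n)
  phi <- runif(n, 0, 2 * pi)
  sporePattern(
    cbind(
      center[1] + radius * sqrt(u) * cos(phi),
      center[2] + radius * sqrt(u) * sin(phi)
    ),
    center = center, radius = radius
  )
}
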