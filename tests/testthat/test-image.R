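test_that("grayscale conversion uses ITU-R 601 luminance", {
  gray <- array(rep(c(0, 100, 255), each = 4), dim = c(2, 2, 3))
  gray[] <- 120
  expect_equal(toGrayscale(gray), matrix(120, 2, 2))
  expect_equal(toGrayscale(array(0, dim = c(3, 3, 3))), matrix(0, 3, 3))
  red <- array(0, dim = c(1, 1, 3))
  red[1, 1, 1] <- 255
  expect_equal(toGrayscale(red)[1, 1], 76)
  expect_error(toGrayscale(array(1, dim = c(2, 2, 4))), "RGB")
})

test_that("image moments recover point masses and are translation
           invariant", {
  I <- matrix(0, 12, 12)
  I[7, 3] <- 5 # x (col) = 3, y (row) = 7
  m <- imageMoments(I)
  expect_equal(m$centroid, c(3, 7))
  expect_equal(c(m$mu20, m$mu11, m$mu02), c(0, 0, 0))

  # two equal masses on a horizontal line, 10 px apart
  J <- matrix(0, 5, 15)
  J[1, c(1, 11)] <- 4
  mj <- imageMoments(J)
  expect_equal(mj$centroid, c(6, 1))
  expect_equal(mj$mu20 / mj$m00, 25)

  set.seed(1)
  K <- matrix(runif(100), 10, 10)
  big <- matrix(0, 20, 20)
  big[6:15, 4:13] <- K
  mk <- imageMoments(K)
  mb <- imageMoments(big)
  expect_equal(mb$mu20, mk$mu20)
  expect_equal(mb$mu11, mk$mu11)
  expect_equal(mb$mu02, mk$mu02)

  expect_error(imageMoments(matrix(0, 4, 4)), "undefined centroid")
})

test_that("the moment ellipse recovers uniform-ellipse parameters over a
           parameter grid", {
  angDiff <- function(a, b) {
    d <- abs(a - b) %% 180
    min(d, 180 - d)
  }
  for (a in c(10, 30, 50)) {
    for (b in unique(c(5, round(a / 2)))) {
      for (ang in c(0, 40, 90, 135)) {
        e <- synthEllipseImage(a, b, angle = ang)
        f <- ellipseFit(e$image)
        expect_lt(abs(f@semiMajor - a) / a, 0.02)
        expect_lt(abs(f@semiMinor - b) / b, 0.02)
        expect_lt(max(abs(f@centroid - e$truth$centroid)), 0.5)
        expect_lt(angDiff(f@orientation, ang), 1)
        expect_false(f@flagged)
        expect_equal(f@eccentricity, e$truth$eccentricity, tolerance = 0.02)
      }
    }
  }
})

test_that("near-circular and degenerate mass distributions are flagged", {
  circ <- synthEllipseImage(20, 20)
  f <- ellipseFit(circ$image)
  expect_lt(f@eccentricity, 0.05)
  expect_true(f@flagged)

  line <- matrix(0, 9, 9)
  line[5, 2:8] <- 10
  expect_true(ellipseFit(line)@flagged)
})

test_that("radial profiles partition pixels and localize rings", {
  e <- synthEllipseImage(30, 20, intensity = 100)
  f <- ellipseFit(e$image)
  rp <- radialProfile(e$image, f, nRings = 10, maxRadius = 1)
  # constant interior: inner annuli flat at the fill intensity with zero sd
  expect_true(all(abs(rp$mean[1:6] - 100) < 1e-9))
  expect_true(all(rp$sd[1:6] == 0))
  # partition: counts sum to the pixels inside the outermost ellipse
  th <- f@orientation * pi / 180
  dx <- col(e$image) - f@centroid[1]
  dy <- row(e$image) - f@centroid[2]
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  inside <- sqrt((u / f@semiMajor)^2 + (v / f@semiMinor)^2) <= 1
  expect_equal(sum(rp$count), sum(inside))

  # a bright ring inside the (0.6, 0.7] annulus peaks there
  r <- sqrt((u / f@semiMajor)^2 + (v / f@semiMinor)^2)
  ringed <- e$image
  ringed[r >= 0.61 & r <= 0.69] <- 220
  rp2 <- radialProfile(ringed, f, nRings = 10, maxRadius = 1)
  expect_equal(rp2$ring[which.max(rp2$mean)], 7)
})

test_that("radial profiles are invariant under image rotation by 90 degrees", {
  e <- synthEllipseImage(25, 12, angle = 20, noiseSd = 10, seed = 3)
  rp1 <- radialProfile(e$image, nRings = 8, maxRadius = 1.2)
  rot <- t(e$image)[, rev(seq_len(nrow(e$image)))] # 90 degree rotation
  rp2 <- radialProfile(rot, nRings = 8, maxRadius = 1.2)
  expect_equal(rp1$count, rp2$count)
  expect_equal(rp1$mean, rp2$mean, tolerance = 1e-9)
})

test_that("angular profiles partition the mask and localize dark wedges", {
  # rotationally symmetric image about the frame centre
  n <- 161
  ctr <- c(81, 81)
  r <- sqrt((col(matrix(0, n, n)) - ctr[1])^2 + (row(matrix(0, n, n)) - ctr[2])^2)
  sym <- ifelse(r <= 70, 200 - r, 0)
  ap <- angularProfile(sym, center = ctr, sectorWidth = 30)
  expect_lt(diff(range(ap$mean)) / mean(ap$mean), 0.005)
  expect_equal(sum(ap$count), sum(sym >= 10))

  # dark wedge around 90 degrees (up in pixel coordinates)
  ang <- (atan2(row(sym) - ctr[2], col(sym) - ctr[1]) * 180 / pi + 360) %% 360
  wedge <- sym
  wedge[ang > 75 & ang < 105 & sym > 0] <- 20
  ap2 <- angularProfile(wedge, center = ctr, sectorWidth = 10)
  expect_equal(ap2$angleMid[which.min(ap2$mean)], 85, tolerance = 11)

  expect_error(angularProfile(sym, center = ctr, sectorWidth = 7), "divide")
})

test_that("per-plane intensity distributions normalize and smooth mass-
           preservingly", {
  vol <- intensityVolume(array(140, dim = c(8, 8, 3)), sliceUm = 5)
  pd <- planeIntensityDistributions(vol, zRange = 1)
  expect_equal(sum(pd$count > 0), 1)
  expect_equal(pd$count[pd$intensity == 140], 64)
  expect_equal(sum(pd$norm), 1)
  expect_lt(abs(sum(pd$smooth) - 1), 1e-9)

  set.seed(4)
  arr <- array(runif(8 * 8 * 2, 0, 255), dim = c(8, 8, 2))
  pd2 <- planeIntensityDistributions(intensityVolume(arr))
  for (z in unique(pd2$z)) {
    sub <- pd2[pd2$z == z, ]
    expect_equal(sum(sub$norm), 1)
    expect_lt(abs(sum(sub$smooth) - sum(sub$norm)), 1e-9)
  }
})

test_that("axis-vs-height regression recovers a linear cone taper", {
  sm <- synthMoundVolume(moundTruth(noiseSd = 0), seed = 2)
  av <- axesVsHeight(sm$volume)
  expect_lt(abs(av$majorSlope - (-60 / 90)) / (60 / 90), 0.1)
  expect_lt(abs(av$minorSlope - (-40 / 90)) / (40 / 90), 0.1)
  expect_gt(av$majorR2, 0.98)
  expect_gt(av$minorR2, 0.98)

  # cylinder phantom: no taper
  plane <- synthEllipseImage(20, 12, intensity = 150, size = 61)$image
  cyl <- intensityVolume(array(rep(plane, 10), dim = c(61, 61, 10)))
  avc <- suppressWarnings(axesVsHeight(cyl)) # zero-slope fit is exact
  expect_lt(abs(avc$majorSlope), 1e-6)
  expect_lt(abs(avc$minorSlope), 1e-6)

  # fewer than three massed planes is an error
  thin <- intensityVolume(array(rep(plane, 2), dim = c(61, 61, 2)))
  expect_error(axesVsHeight(thin), "at least 3")
})

test_that("isovolume extraction labels pockets with faithful diameters", {
  tr <- moundTruth(
    noiseSd = 0,
    pockets = data.frame(x = 0, y = 0, z = 30, diameter = 20, boost = 40)
  )
  v <- synthMoundVolume(tr, seed = 1)
  pk <- isovolumePockets(v$volume, 150)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$eqDiameterUm - 20), 2)
  expect_lt(abs(pk$zUm - 30), 4)

  tr2 <- moundTruth(
    noiseSd = 0,
    pockets = data.frame(
      x = c(-25, 25), y = c(0, 0), z = c(25, 25),
      diameter = c(16, 16), boost = 40
    )
  )
  v2 <- synthMoundVolume(tr2, seed = 1)
  expect_equal(nrow(isovolumePockets(v2$volume, 150)), 2)

  expect_equal(nrow(isovolumePockets(v$volume, 254)), 0)
})

test_that("plane extraction is index-faithful", {
  sm <- synthMoundVolume(moundTruth(noiseSd = 0), seed = 2)
  base <- extractPlane(sm$volume, 1)
  top <- extractPlane(sm$volume, dim(voxels(sm$volume))[3])
  # base cross-section holds the most mound pixels
  expect_gt(sum(base >= 10), sum(top >= 10))
  expect_identical(base, voxels(sm$volume)[, , 1])
  expect_error(extractPlane(sm$volume, 0), "z must lie")
  expect_error(extractPlane(sm$volume, 1e4), "z must lie")
})
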