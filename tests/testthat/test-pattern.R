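test_that("concentration grids count in-window points exactly", {
  empty <- sporePattern(matrix(numeric(0), 0, 2))
  g <- concentrationGrid(empty)
  expect_true(all(fieldValues(g) == 0))

  one <- sporePattern(cbind(5, -3))
  g1 <- concentrationGrid(one)
  expect_equal(sum(fieldValues(g1)), 1)
  expect_equal(sum(fieldValues(g1) == 1), 1)

  set.seed(2)
  pts <- cbind(runif(500, -80, 80), runif(500, -80, 80)) # some out of window
  pat <- sporePattern(pts)
  g2 <- concentrationGrid(pat) # default window: 120 x 120 um
  inWin <- abs(pts[, 1]) <= 60 & abs(pts[, 2]) <= 60
  expect_equal(sum(fieldValues(g2)), sum(inWin))
})

test_that("Gaussian smoothing conserves mass and has a kernel impulse
           response", {
  g <- concentrationGrid(sporePattern(cbind(0, 0)))
  f <- localDensityField(g, sigma = 2)
  v <- fieldValues(f)
  expect_lt(abs(sum(v) - 1), 1e-6)
  # maximum at the impulse node
  expect_equal(which(v == max(v)), which(fieldValues(g) == 1))

  # uniform input stays uniform away from edges
  gu <- g
  gu@values <- matrix(1, 100, 100)
  fu <- localDensityField(gu, sigma = 2)
  interior <- fieldValues(fu)[20:80, 20:80]
  expect_lt(diff(range(interior)), 1e-9)

  # smoothing monotonicity: a larger kernel lowers the peak
  cl <- synthClusteredSpores(seed = 5)
  gc <- concentrationGrid(cl$pattern)
  p1 <- max(fieldValues(localDensityField(gc, sigma = 1.5)))
  p2 <- max(fieldValues(localDensityField(gc, sigma = 4)))
  expect_lt(p2, p1)

  # grid -> field mass conservation within 1 percent for in-disc patterns
  fc <- localDensityField(gc, sigma = 2)
  expect_lt(
    abs(sum(fieldValues(fc)) - sum(fieldValues(gc))) / sum(fieldValues(gc)),
    0.01
  )
})

test_that("the radial curve of the field averages nodes at fixed radius", {
  g <- concentrationGrid(sporePattern(cbind(0, 0)))
  gu <- g
  gu@values <- matrix(3, 100, 100)
  rc <- radialDensityOfField(gu, center = c(0, 0), maxRadius = 50)
  expect_equal(nrow(rc), floor(50 / gu@cellSize))
  expect_true(all(abs(rc$mean - 3) < 1e-9))

  # a ring of clusters at radius 30 um produces a local maximum there
  set.seed(7)
  ang <- runif(200, 0, 2 * pi)
  pts <- cbind(30 * cos(ang), 30 * sin(ang)) + matrix(rnorm(400, 0, 1.5), 200)
  fr <- localDensityField(concentrationGrid(sporePattern(pts)), sigma = 2)
  rr <- radialDensityOfField(fr, center = c(0, 0), maxRadius = 50)
  expect_lt(abs(rr$rMid[which.max(rr$mean)] - 30), 3)

  expect_error(
    radialDensityOfField(gu, center = c(500, 0)),
    "inside the grid"
  )
})

test_that("angular spore counts partition the disc into 3-degree sectors", {
  mids <- (seq_len(120) - 0.5) * 3 * pi / 180
  pat <- sporePattern(cbind(20 * cos(mids), 20 * sin(mids)))
  ac <- angularSporeCounts(pat)
  expect_equal(nrow(ac), 120)
  expect_true(all(ac$count == 1))

  # counts sum to the in-disc point total
  set.seed(3)
  pts <- cbind(runif(400, -60, 60), runif(400, -60, 60))
  pat2 <- sporePattern(pts, radius = 50)
  ac2 <- angularSporeCounts(pat2)
  expect_equal(sum(ac2$count), sum(sqrt(rowSums(pts^2)) <= 50))

  # grid-node mode conserves the in-disc grid mass
  g <- concentrationGrid(pat2)
  acg <- angularSporeCounts(pat2, grid = g)
  n1 <- nrow(fieldValues(g))
  xs <- g@origin[1] + (seq_len(n1) - 0.5) * g@cellSize
  ys <- g@origin[2] + (seq_len(n1) - 0.5) * g@cellSize
  rr <- sqrt(outer(xs, rep(1, n1))^2 + outer(rep(1, n1), ys)^2)
  expect_equal(sum(acg$count), sum(fieldValues(g)[rr <= 50]))

  expect_error(angularSporeCounts(pat2, sectorWidth = 7), "divide")
})

test_that("isotropic patterns give multinomially uniform sector counts", {
  pvals <- vapply(1:20, function(s) {
    pat <- uniformSporePattern(1200, radius = 50, seed = s)
    ac <- angularSporeCounts(pat)
    suppressWarnings(chisq.test(ac$count)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("clustered patterns carry more field variation than matched
           uniform patterns", {
  cvOf <- function(pat) {
    f <- localDensityField(concentrationGrid(pat), sigma = 2)
    v <- fieldValues(f)
    sd(v) / mean(v)
  }
  cvC <- cvU <- numeric(20)
  for (s in 1:20) {
    cl <- synthClusteredSpores(nClusters = 6, meanPerCluster = 30, sdUm = 3, seed = s)
    n <- nrow(sporePoints(cl$pattern))
    cvC[s] <- cvOf(cl$pattern)
    cvU[s] <- cvOf(uniformSporePattern(n, radius = 50, seed = s + 1000))
  }
  expect_gt(mean(cvC), mean(cvU))
  expect_true(all(cvC > cvU))
})

test_that("nearest-neighbour distances are symmetric and edge-safe", {
  pts <- rbind(c(0, 0), c(3, 0), c(10, 0))
  expect_equal(nearestNeighbourDistances(pts), c(3, 3, 7))
  expect_length(nearestNeighbourDistances(pts[1, , drop = FALSE]), 0)
})
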