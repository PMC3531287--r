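test_that("initial placement is uniform with tangential in-disc orientation", {
  cfg <- swarmConfig(nCells = 1e4, seed = 21)
  st <- initSwarm(cfg)
  mid <- st@nodes[, 3:4]
  inDisc <- rep(FALSE, nrow(mid))
  tangentOk <- ccwOk <- logical(0)
  for (d in seq_len(nrow(cfg@discs))) {
    dx <- mid[, 1] - cfg@discs[d, 1]
    dy <- mid[, 2] - cfg@discs[d, 2]
    rr <- sqrt(dx^2 + dy^2)
    sel <- rr <= cfg@discs[d, 3]
    inDisc <- inDisc | sel
    hx <- ifelse(st@head0, st@nodes[, 1], st@nodes[, 5]) - ifelse(st@head0, st@nodes[, 5], st@nodes[, 1])
    hy <- ifelse(st@head0, st@nodes[, 2], st@nodes[, 6]) - ifelse(st@head0, st@nodes[, 6], st@nodes[, 2])
    nn <- sqrt(hx^2 + hy^2)
    # radial component of the head-ward axis vanishes; chirality is CCW
    rad <- abs((dx * hx + dy * hy) / (rr * nn))[sel]
    crs <- ((dx * hy - dy * hx) / (rr * nn))[sel]
    tangentOk <- c(tangentOk, rad < 1e-8)
    ccwOk <- c(ccwOk, crs > 0.999)
  }
  expect_true(all(tangentOk))
  expect_true(all(ccwOk))

  # in-disc fraction matches the area ratio (binomial 3 sigma)
  pArea <- sum(pi * cfg@discs[, 3]^2) / cfg@domain^2
  expect_lt(
    abs(mean(inDisc) - pArea),
    3 * sqrt(pArea * (1 - pArea) / 1e4)
  )

  st2 <- initSwarm(cfg)
  expect_identical(st@nodes, st2@nodes)
  expect_identical(st@nextRev, st2@nextRev)

  expect_error(
    swarmConfig(discs = cbind(c(100, 120), c(100, 100), 50)),
    "overlapping discs"
  )
})

test_that("elastic energy is harmonic in bend angle and stretch", {
  l0 <- 2.5
  straight <- matrix(c(0, 0, l0, 0, 2 * l0, 0), 3, 2, byrow = TRUE)
  expect_equal(elasticEnergy(straight, kb = 10, ks = 20, l0 = l0), 0)

  th <- 0.2
  bent <- matrix(c(
    0, 0, l0, 0,
    l0 + l0 * cos(th), l0 * sin(th)
  ), 3, 2, byrow = TRUE)
  expect_equal(elasticEnergy(bent, kb = 10, ks = 5, l0 = l0),
    0.5 * 10 * th^2,
    tolerance = 1e-10
  )

  # stretching one segment by delta adds ks * delta^2 / 2, independent of bend
  d <- 0.3
  stretched <- bent
  stretched[3, ] <- stretched[2, ] + (1 + d / l0) * (bent[3, ] - bent[2, ])
  expect_equal(
    elasticEnergy(stretched, kb = 10, ks = 5, l0 = l0) -
      elasticEnergy(bent, kb = 10, ks = 5, l0 = l0),
    0.5 * 5 * d^2,
    tolerance = 1e-10
  )

  degenerate <- matrix(c(0, 0, 0, 0, 1, 1), 3, 2, byrow = TRUE)
  expect_error(elasticEnergy(degenerate, 10, 5, l0), "degenerate")
})

test_that("reversal swaps polarity involutively and leaves C-signal alone", {
  st <- makeSwarmState(rbind(rodRow(10, 10), rodRow(20, 20, 45)),
    counter = c(3L, 9L)
  )
  twice <- reverseCell(reverseCell(st, 1), 1)
  expect_identical(twice@head0, st@head0)
  once <- reverseCell(st, 2)
  expect_identical(once@head0[2], !st@head0[2])
  expect_identical(once@counter, st@counter)
  expect_identical(once@nodes, st@nodes)
})

test_that("reversal intervals follow the 8 +/- 1 minute clock", {
  cfg <- swarmConfig(
    domain = 20, discs = matrix(numeric(0), 0, 3), nCells = 1,
    slimeRes = 10, seed = 17
  )
  res <- runSwarm(cfg, maxSteps = 2e5)
  iv <- diff(res@reversalTimes)
  expect_gt(length(iv), 2000)
  expect_lt(abs(mean(iv) - 8), 0.08) # within 1 percent
  expect_lt(abs(sd(iv) - 1), 0.1) # within 10 percent
})

test_that("end-to-end contacts require proximity, alignment and non-lateral
           geometry", {
  cfg <- bareSwarmConfig()
  collinear <- function(angleDeg) {
    # cell A along +x ending at (15, 10); cell B starts 0.3 um further,
    # rotated by angleDeg about its own near end
    a <- rodRow(12.5, 10)
    th <- angleDeg * pi / 180
    ax <- c(cos(th), sin(th))
    start <- c(15.3, 10)
    b <- c(
      start + 5 * ax, start + 2.5 * ax,
      start
    )
    makeSwarmState(rbind(a, b))
  }
  expect_equal(nrow(detectEndContacts(collinear(29), cfg)), 1)
  expect_equal(nrow(detectEndContacts(collinear(31), cfg)), 0)
  # polarity is irrelevant: reversing one cell keeps the contact
  st <- reverseCell(collinear(29), 2)
  expect_equal(nrow(detectEndContacts(st, cfg)), 1)

  # side-by-side parallel cells never signal, even though their end nodes
  # are within the contact distance
  side <- makeSwarmState(rbind(rodRow(20, 10), rodRow(20, 10.6)))
  expect_equal(nrow(detectEndContacts(side, cfg)), 0)

  # spores do not signal
  sp <- collinear(0)
  sp@spore[1] <- TRUE
  expect_equal(nrow(detectEndContacts(sp, cfg)), 0)
})

test_that("a pinned aligned pair sporulates after exactly the threshold
           number of contact events", {
  cfg <- bareSwarmConfig(speed = 0, threshold = 500)
  cfg@nCells <- 2L
  st <- makeSwarmState(rbind(rodRow(12.5, 10), rodRow(18.3, 10)))
  set.seed(4)
  st499 <- stepSwarm(st, cfg, nSteps = 499)
  expect_identical(st499@counter, c(499L, 499L))
  expect_false(any(st499@spore))
  st500 <- stepSwarm(st499, cfg)
  expect_true(all(st500@spore))
  # spore body collapsed to the former midpoint
  expect_equal(st500@nodes[1, 1:2], st500@nodes[1, 3:4])
})

test_that("a cell in several pairs gains one count per pair", {
  cfg <- bareSwarmConfig()
  cfg@nCells <- 3L
  st <- makeSwarmState(rbind(rodRow(12.5, 10), rodRow(18.3, 10), rodRow(6.7, 10)))
  pairs <- detectEndContacts(st, cfg)
  expect_equal(nrow(pairs), 2) # middle cell touches both ends
  out <- applySignaling(st, cfg, pairs)
  expect_equal(sum(out@counter), 4L)
  expect_equal(max(out@counter), 2L)
  # empty pair set leaves the state unchanged
  out0 <- applySignaling(st, cfg, matrix(integer(0), 0, 2))
  expect_identical(out0@counter, st@counter)
})

test_that("stepping conserves agents, bounds speed and fixes spores", {
  cfg <- discSwarmConfig(seed = 5)
  cfg@nCells <- 150L
  st <- initSwarm(cfg)
  out <- stepSwarm(st, cfg, nSteps = 40)
  expect_equal(nrow(out@nodes), 150)
  expect_true(all(out@counter >= st@counter))

  # all-spore state is invariant under stepping
  allSp <- makeSwarmState(rbind(rodRow(10, 10), rodRow(30, 30)),
    spore = TRUE
  )
  allSp@nodes[, c(1, 3, 5)] <- allSp@nodes[, 3]
  allSp@nodes[, c(2, 4, 6)] <- allSp@nodes[, 4]
  set.seed(1)
  stepped <- stepSwarm(allSp, bareSwarmConfig(), nSteps = 10)
  expect_identical(stepped@nodes, allSp@nodes)
  expect_identical(stepped@spore, allSp@spore)

  # isolated cell: the head advances by exactly v * dt every step (no stall
  # in open space), so displacement per step never exceeds the speed bound
  cfg1 <- bareSwarmConfig(wN = 0.1)
  s <- initSwarm(cfg1)
  set.seed(2)
  dh <- numeric(0)
  for (k in 1:300) {
    s2 <- stepSwarm(s, cfg1)
    if (identical(s2@head0, s@head0)) { # skip polarity swaps
      slot <- if (s@head0[1]) 1:2 else 5:6
      d <- s2@nodes[1, slot] - s@nodes[1, slot]
      d <- d - cfg1@domain * round(d / cfg1@domain) # periodic minimum image
      dh <- c(dh, sqrt(sum(d^2)))
    }
    s <- s2
  }
  expect_gt(length(dh), 250)
  expect_lt(max(dh), cfg1@speed * cfg1@dt + 1e-9)
  # and it never stalls in open space: every step advances the full v * dt
  expect_gt(min(dh), cfg1@speed * cfg1@dt - 1e-9)
})

test_that("a cell driven into an immovable spore stalls with its position
           frozen", {
  cfg <- bareSwarmConfig()
  cfg@nCells <- 2L
  # motile cell heading +x toward a spore sitting 1.5 um beyond its head
  st <- makeSwarmState(rbind(rodRow(12.5, 10), rep(c(19, 10), 3)),
    spore = c(FALSE, TRUE)
  )
  set.seed(9)
  for (k in 1:20) st <- stepSwarm(st, cfg)
  frozen <- st@nodes[1, ]
  st2 <- st
  for (k in 1:10) st2 <- stepSwarm(st2, cfg)
  expect_equal(st2@nodes[1, ], frozen, tolerance = 1e-12)
  # the blocked head never penetrates the collision envelope
  gap <- sqrt(sum((st2@nodes[1, 1:2] - c(19, 10))^2))
  expect_gte(gap, cfg@sporeRadius + cfg@width / 2 - 1e-9)
})

test_that("the elastic energy keeps isolated bodies near rest length", {
  cfg <- bareSwarmConfig(wN = 0.1)
  s <- initSwarm(cfg)
  devs <- numeric(0)
  set.seed(6)
  for (k in 1:50) {
    s <- stepSwarm(s, cfg, nSteps = 10)
    l1 <- sqrt(sum((s@nodes[1, 1:2] - s@nodes[1, 3:4])^2))
    l2 <- sqrt(sum((s@nodes[1, 3:4] - s@nodes[1, 5:6])^2))
    devs <- c(devs, abs(c(l1, l2) - cfg@l0) / cfg@l0)
  }
  expect_lt(mean(devs), 0.2)
})

test_that("direction combines axis, neighbours and noise as a weighted sum", {
  # A-motility only: direction equals the head-ward axis exactly
  cfg <- bareSwarmConfig(wS = 0, wT = 0)
  st <- makeSwarmState(rbind(rodRow(30, 30, 30)))
  d <- computeDirection(st, cfg, 1)
  expect_equal(d, c(cos(pi / 6), sin(pi / 6)), tolerance = 1e-12)

  # two symmetric forward neighbours leave the direction on the axis
  cfgS <- bareSwarmConfig(wS = 5, wT = 0)
  cfgS@nCells <- 3L
  st3 <- makeSwarmState(rbind(
    rodRow(30, 30, 0),
    rodRow(36, 31, 10),
    rodRow(36, 29, -10)
  ))
  d3 <- computeDirection(st3, cfgS, 1)
  expect_equal(d3, c(1, 0), tolerance = 1e-9)

  # repeated calls with identical inputs are identical (wN = 0)
  expect_identical(d3, computeDirection(st3, cfgS, 1))
})

test_that("tangentially seeded discs sustain a consistent rotation sense
           before the first synchronized reversal", {
  cfg <- discSwarmConfig(seed = 8)
  cfg@nCells <- 400L
  res <- runSwarm(cfg, maxSteps = 65, snapshotEvery = 5)
  circ <- vapply(res@snapshots, function(s) {
    discCirculation(s, c(62.5, 62.5), 50, 125)
  }, numeric(1))
  expect_gte(mean(sign(circ) == sign(circ[1])), 0.9)
  expect_gt(circ[1], 0) # counter-clockwise seeding
})

test_that("runs are bit-reproducible under the configuration seed", {
  cfg <- discSwarmConfig(seed = 12)
  cfg@nCells <- 120L
  r1 <- runSwarm(cfg, maxSteps = 60)
  r2 <- runSwarm(cfg, maxSteps = 60)
  expect_identical(r1@state@nodes, r2@state@nodes)
  expect_identical(r1@state@counter, r2@state@counter)
  expect_identical(r1@sporeTable, r2@sporeTable)

  # zero-step run returns the initial state
  r0 <- runSwarm(cfg, maxSteps = 0)
  expect_identical(r0@state@nodes, initSwarm(cfg)@nodes)
})
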