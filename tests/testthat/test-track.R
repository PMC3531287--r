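test_that("initialization is uniform, bounded and reproducible", {
  p <- trackParams(trackLength = 100, nCells = 1e5, seed = 7)
  st <- initTrack(p)
  expect_gte(min(st@concentration), 0)
  expect_lte(max(st@concentration), 0.5)
  expect_true(all(st@position >= 0 & st@position < 100))
  # uniform positions: each site frequency near 1000
  expect_lt(max(abs(tabulate(st@position + 1, 100) - 1000)), 5 * sqrt(1000))
  expect_false(any(st@spore))

  one <- initTrack(trackParams(trackLength = 1, nCells = 5))
  expect_identical(one@position, rep(0L, 5))

  a <- initTrack(trackParams(seed = 42))
  b <- initTrack(trackParams(seed = 42))
  expect_identical(a@position, b@position)
  expect_identical(a@concentration, b@concentration)

  expect_error(trackParams(trackLength = 0), "trackLength")
  expect_error(trackParams(nCells = -3), "nCells")
  expect_error(trackParams(passProb = 1.2), "passProb")
})

test_that("passing succeeds with probability P^n", {
  set.seed(1)
  expect_true(all(attemptPass(0, P = 0, n = 100)))
  expect_true(all(attemptPass(7, P = 1, n = 100)))
  freq <- mean(attemptPass(2, P = 0.5, n = 1e5))
  se <- sqrt(0.25 * 0.75 / 1e5)
  expect_lt(abs(freq - 0.25), 3 * se)
  expect_error(attemptPass(-1, P = 0.5), "nSpores")
})

test_that("signal update follows basal + T * neighbour mean", {
  p <- trackParams(trackLength = 10, nCells = 3, transferRate = 0)
  # lone cell, T = 0: basal only
  st <- makeTrackState(4, 0.2, L = 10)
  expect_equal(updateSignals(st, p)@concentration, 0.205)

  # neighbours one ahead (0.3) and one behind (0.5), T = 0.1
  p1 <- trackParams(trackLength = 10, nCells = 3, transferRate = 0.1)
  st <- makeTrackState(c(4, 5, 3), c(0.2, 0.3, 0.5), L = 10)
  expect_equal(updateSignals(st, p1)@concentration[1], 0.245)

  # no motile neighbour: transfer term zero
  st <- makeTrackState(4, 0.2, L = 10)
  expect_equal(updateSignals(st, p1)@concentration, 0.205)

  # spores neither receive nor contribute signal
  st <- makeTrackState(c(4, 5), c(0.2, 0.9), spore = c(FALSE, TRUE), L = 10)
  out <- updateSignals(st, p1)
  expect_equal(out@concentration, c(0.205, 0.9))

  # same-position cells contribute nothing to each other
  st <- makeTrackState(c(4, 4), c(0.2, 0.8), L = 10)
  expect_equal(updateSignals(st, p1)@concentration, c(0.205, 0.805))

  # concentrations never decrease
  set.seed(2)
  st <- makeTrackState(sample(0:9, 20, TRUE), runif(20, 0, 0.5), L = 10)
  expect_true(all(updateSignals(st, p1)@concentration >= st@concentration))
})

test_that("a lone unimpeded cell sporulates exactly when basal production
           reaches the threshold", {
  p <- trackParams(trackLength = 5, nCells = 1, passProb = 1)
  st <- makeTrackState(0, 0, L = 5)
  set.seed(1)
  st199 <- stepTrack(st, p, nSteps = 199)
  expect_false(any(st199@spore))
  st200 <- stepTrack(st199, p)
  expect_true(all(st200@spore))
  expect_equal(st200@step, 200L)
})

test_that("spores are absorbing and block at P = 0", {
  p0 <- trackParams(trackLength = 6, nCells = 4, passProb = 0)
  st <- makeTrackState(c(1, 2, 3, 4), rep(1, 4), spore = rep(TRUE, 4), L = 6)
  set.seed(3)
  out <- stepTrack(st, p0, nSteps = 5)
  expect_identical(out@position, st@position)
  expect_identical(out@spore, st@spore)
  expect_equal(out@concentration, st@concentration)

  # motile cell facing three spores at P = 0 never moves, converts in place
  st <- makeTrackState(c(0, rep(1, 3)), c(0.4, 1, 1, 1),
    spore = c(FALSE, TRUE, TRUE, TRUE), L = 6
  )
  out <- stepTrack(st, p0, nSteps = 200)
  expect_true(out@spore[1])
  expect_equal(out@position[1], 0L)
})

test_that("runs conserve agents, terminate within the basal bound and are
           seed-reproducible", {
  for (P in c(1, 0.3, 0.05)) {
    res <- runTrack(trackParams(passProb = P, transferRate = 0.2, seed = 11))
    expect_equal(sum(sporeCounts(res)), 60)
    expect_lte(stepsToCompletion(res), 200)
  }
  r1 <- runTrack(trackParams(passProb = 0.2, seed = 5))
  r2 <- runTrack(trackParams(passProb = 0.2, seed = 5))
  expect_identical(sporeCounts(r1), sporeCounts(r2))

  resL1 <- runTrack(trackParams(trackLength = 1, nCells = 7))
  expect_equal(sporeCounts(resL1), 7L)
  expect_equal(voidFraction(resL1), 0)
})

test_that("free-flow void fraction matches the uniform-occupancy closed form", {
  # with P = 1, T = 0 there is no interaction: final positions are uniform
  vf <- vapply(1:500, function(r) {
    voidFraction(runTrack(trackParams(passProb = 1, seed = r)))
  }, numeric(1))
  expected <- (1 - 1 / 100)^60
  se <- sd(vf) / sqrt(length(vf))
  expect_lt(abs(mean(vf) - expected), 3 * se)
})

test_that("jamming at low passing probability increases the void fraction", {
  vf <- function(P) {
    mean(vapply(1:100, function(r) {
      voidFraction(runTrack(trackParams(passProb = P, seed = r)))
    }, numeric(1)))
  }
  expect_gt(vf(0.1), vf(1.0))
})

test_that("summaries count voids and clusters directly", {
  p <- trackParams(trackLength = 5, nCells = 5)
  res <- new("TrackResult",
    sporeCounts = c(3L, 0L, 0L, 2L, 0L),
    steps = 150L, params = p
  )
  s <- trackSummary(res)
  expect_equal(s$voidFraction, 0.6)
  expect_equal(s$maxCluster, 3L)
  expect_equal(s$meanCluster, 2.5)

  allOnOne <- new("TrackResult",
    sporeCounts = c(5L, rep(0L, 4)),
    steps = 150L, params = p
  )
  expect_equal(trackSummary(allOnOne)$voidFraction, (5 - 1) / 5)
})

test_that("strong jamming accumulates spore towers of five or more", {
  mx <- vapply(1:50, function(r) {
    trackSummary(runTrack(trackParams(passProb = 0.05, seed = r)))$maxCluster
  }, integer(1))
  expect_gt(mean(mx >= 5), 0.5)
})

test_that("the sweep aggregates per-pair replicates reproducibly", {
  sw <- sweepTrack(
    PGrid = c(0.2, 0.6), TGrid = 0.1, reps = 3,
    base = trackParams(seed = 2), detail = TRUE
  )
  expect_equal(nrow(sw), 2)
  expect_equal(nrow(attr(sw, "replicates")), 6)
  expect_true(all(c("meanVoidFraction", "sdVoidFraction") %in% names(sw)))

  one <- sweepTrack(PGrid = 0.5, TGrid = 0, reps = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$sdVoidFraction, 0)

  # replicate seeds derive from the base seed: identical calls agree
  sw2 <- sweepTrack(PGrid = c(0.2, 0.6), TGrid = 0.1, reps = 3,
    base = trackParams(seed = 2)
  )
  expect_equal(sw$meanVoidFraction, sw2$meanVoidFraction)
})

test_that("without transfer the void fraction decreases monotonically in P", {
  sw <- sweepTrack(
    PGrid = seq(0.05, 1, length.out = 6), TGrid = 0, reps = 30,
    base = trackParams(seed = 1)
  )
  expect_lt(cor(sw$P, sw$meanVoidFraction, method = "spearman"), 0)
  expect_true(all(diff(sw$meanVoidFraction) <= 0.02)) # non-increasing + noise
})
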