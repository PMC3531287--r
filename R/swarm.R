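#' Construct a 2D swarm model configuration
#'
#' Defaults describe the reference study conditions: a 500 x 500 um periodic
#' domain holding four aggregation discs of radius 50 um, cells of total
#' length 5 um (two segments of rest length `l0 = 2.5` um) and width 0.5 um
#' gliding at 2 um/min, reversing every 8 +/- 1 min, exchanging one C-signal
#' unit per step per aligned (< 30 degrees, polarity ignored) end-to-end
#' contact, and sporulating at 500 signal counts. Direction weights keep
#' A-motility dominant with S-motility, slime following and noise active.
#'
#' @param domain side of the periodic square domain, um.
#' @param discs n x 3 matrix `(x, y, radius)` of aggregation discs, um.
#' @param nCells number of cells.
#' @param l0 rest length of each of the two body segments, um.
#' @param width cell body width (capsule diameter), um.
#' @param speed gliding speed, um/min.
#' @param dt step length, min.
#' @param kb bending coefficient, energy/rad^2.
#' @param ks stretching coefficient, energy/um^2.
#' @param wA,wS,wT,wN direction weights (A-motility, S-motility, slime
#'   trail, noise).
#' @param revMean,revSd reversal period mean and sd, min.
#' @param alignMaxDeg maximum axis angle for C-signal exchange, degrees.
#' @param threshold C-signal counts required for sporulation.
#' @param contactDist maximum end-node separation for an end-to-end
#'   contact, um.
#' @param sporeRadius radius of the circular spore obstacle, um.
#' @param temperature Metropolis temperature, energy units.
#' @param slimeRes slime grid resolution, um.
#' @param slimeHalfLife exponential decay half-life of slime deposits, min.
#' @param slimeSense radius around the head within which slime direction is
#'   read, um.
#' @param proposalBudget Metropolis proposals per step before stalling.
#' @param proposalSd sd of Gaussian node-displacement proposals, um.
#' @param seed RNG seed.
#' @return a [SwarmConfig-class] object.
#' @export
swarmConfig <- function(domain = 500,
                        discs = cbind(
                          x = c(125, 375, 125, 375),
                          y = c(125, 125, 375, 375), r = 50
                        ),
                        nCells = 2000, l0 = 2.5, width = 0.5, speed = 2,
                        dt = 0.1, kb = 10, ks = 20, wA = 1, wS = 0.5,
                        wT = 0.5, wN = 0.1, revMean = 8, revSd = 1,
                        alignMaxDeg = 30, threshold = 500,
                        contactDist = 1, sporeRadius = 1, temperature = 1,
                        slimeRes = 1, slimeHalfLife = 10, slimeSense = 1,
                        proposalBudget = 10, proposalSd = 0.1 * l0,
                        seed = 1L) {
  discs <- as.matrix(discs)
  if (ncol(discs) != 3) stop("`discs` must be an n x 3 matrix (x, y, r)")
  colnames(discs) <- c("x", "y", "r")
  new("SwarmConfig",
    domain = domain, discs = discs, nCells = .asCount(nCells, "nCells"),
    l0 = l0, width = width, speed = speed, dt = dt, kb = kb, ks = ks,
    wA = wA, wS = wS, wT = wT, wN = wN, revMean = revMean, revSd = revSd,
    alignMaxDeg = alignMaxDeg, threshold = .asCount(threshold, "threshold"),
    contactDist = contactDist, sporeRadius = sporeRadius,
    temperature = temperature, slimeRes = slimeRes,
    slimeHalfLife = slimeHalfLife, slimeSense = slimeSense,
    proposalBudget = .asCount(proposalBudget, "proposalBudget"),
    proposalSd = proposalSd, seed = as.integer(seed)
  )
}

.cfgList <- function(config) {
  list(
    domain = config@domain, l0 = config@l0, width = config@width,
    speed = config@speed, dt = config@dt, kb = config@kb, ks = config@ks,
    wA = config@wA, wS = config@wS, wT = config@wT, wN = config@wN,
    revMean = config@revMean, revSd = config@revSd,
    alignMaxDeg = config@alignMaxDeg, threshold = config@threshold,
    contactDist = config@contactDist, sporeRadius = config@sporeRadius,
    temperature = config@temperature, slimeRes = config@slimeRes,
    slimeHalfLife = config@slimeHalfLife, slimeSense = config@slimeSense,
    proposalBudget = config@proposalBudget, proposalSd = config@proposalSd
  )
}

.stateList <- function(state) {
  list(
    nodes = state@nodes, head0 = state@head0, spore = state@spore,
    counter = state@counter, nextRev = state@nextRev,
    steps = state@steps, slime = state@slime
  )
}

.stateFromList <- function(lst) {
  new("SwarmState",
    nodes = lst$nodes, head0 = lst$head0,
    counter = as.integer(lst$counter), spore = lst$spore,
    nextRev = lst$nextRev, slime = lst$slime, steps = lst$steps
  )
}

#' Build a swarm state from explicit cell geometries
#'
#' Mainly useful for constructing controlled scenarios (pinned pairs,
#' collision geometries) in analyses and tests.
#'
#' @param nodes n x 6 matrix `(x0, y0, x1, y1, x2, y2)` of node coordinates.
#' @param head0 logical: is node 0 the head? Recycled.
#' @param counter integer C-signal counters. Recycled.
#' @param spore logical states. Recycled.
#' @param nextRev next reversal times (min). Recycled; default far future so
#'   constructed scenarios are not perturbed by reversals.
#' @param steps step counter the state starts at.
#' @return a [SwarmState-class] object.
#' @export
makeSwarmState <- function(nodes, head0 = TRUE, counter = 0L, spore = FALSE,
                           nextRev = Inf, steps = 0) {
  n <- nrow(nodes)
  new("SwarmState",
    nodes = nodes, head0 = rep_len(head0, n),
    counter = rep_len(as.integer(counter), n), spore = rep_len(spore, n),
    nextRev = rep_len(nextRev, n), slime = list(), steps = steps
  )
}

# straight three-node body with middle at (x, y) pointing along unit `axis`,
# head placed axis-forward
.rodNodes <- function(x, y, axis, l0) {
  c(
    x + l0 * axis[1], y + l0 * axis[2], x, y,
    x - l0 * axis[1], y - l0 * axis[2]
  )
}

#' Initialize a swarm state
#'
#' Cells are placed uniformly at random over the whole domain as straight
#' bodies at rest length. A cell whose midpoint falls inside an aggregation
#' disc is oriented along the counter-clockwise tangent of that disc (its
#' head pointing in the direction of rotation); cells outside every disc get
#' uniform random orientations. Which end node carries the head label is
#' random, and per-cell reversal clocks are drawn from the truncated
#' Normal(revMean, revSd) reversal distribution.
#'
#' @param config a [SwarmConfig-class] object (seeds the RNG).
#' @return a [SwarmState-class] object at step 0.
#' @export
initSwarm <- function(config) {
  stopifnot(is(config, "SwarmConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nCells
  L <- config@domain
  mx <- runif(n, 0, L)
  my <- runif(n, 0, L)
  nodes <- matrix(0, n, 6)
  discs <- config@discs
  for (i in seq_len(n)) {
    axis <- NULL
    if (nrow(discs) > 0) {
      for (d in seq_len(nrow(discs))) {
        dx <- mx[i] - discs[d, 1]
        dx <- dx - L * round(dx / L)
        dy <- my[i] - discs[d, 2]
        dy <- dy - L * round(dy / L)
        rr <- sqrt(dx^2 + dy^2)
        if (rr <= discs[d, 3]) {
          if (rr < 1e-9) {
            axis <- c(1, 0)
          } else {
            axis <- c(-dy, dx) / rr # counter-clockwise tangent
          }
          break
        }
      }
    }
    if (is.null(axis)) {
      a <- runif(1, 0, 2 * pi)
      axis <- c(cos(a), sin(a))
    }
    nodes[i, ] <- .rodNodes(mx[i], my[i], axis, config@l0)
  }
  head0 <- runif(n) < 0.5
  # the head must point along the assigned orientation regardless of which
  # array slot carries it: flip node order where node 2 is the head
  for (i in which(!head0)) {
    nodes[i, ] <- nodes[i, c(5, 6, 3, 4, 1, 2)]
  }
  ng <- max(1L, as.integer(round(config@domain / config@slimeRes)))
  zero <- rep(0, ng * ng)
  new("SwarmState",
    nodes = nodes, head0 = head0, counter = rep(0L, n),
    spore = rep(FALSE, n),
    nextRev = .rtruncnorm0(n, config@revMean, config@revSd),
    slime = list(c2 = zero, s2 = zero, w = zero), steps = 0
  )
}

#' Elastic energy of a three-node rod
#'
#' `H = kb * theta^2 / 2 + ks * sum((l - l0)^2) / 2`, where `theta` is the
#' deviation-from-straight angle between the two segments and the sum runs
#' over both segment lengths.
#'
#' @param nodes 3 x 2 matrix of node coordinates (head/middle/tail order is
#'   immaterial to the energy).
#' @param kb bending coefficient, energy/rad^2.
#' @param ks stretching coefficient, energy/um^2.
#' @param l0 rest segment length, um.
#' @return the elastic energy (0 for a straight cell at rest length).
#' @export
elasticEnergy <- function(nodes, kb, ks, l0) {
  .swarm_energy_cpp(nodes, kb, ks, l0)
}

#' Compute a cell's direction of movement
#'
#' Returns the normalized weighted sum of the head-ward long axis, the mean
#' sign-rectified orientation of motile cells sensed within one cell length
#' ahead of the head, the sign-rectified slime direction at the head, and a
#' uniform random unit vector. With a zero resultant the long axis is
#' returned. Deterministic when `wN == 0`.
#'
#' @param state a [SwarmState-class] object.
#' @param config a [SwarmConfig-class] object.
#' @param i cell index (1-based).
#' @return a unit 2-vector.
#' @export
computeDirection <- function(state, config, i) {
  stopifnot(is(state, "SwarmState"), is(config, "SwarmConfig"))
  if (state@spore[i]) stop("cell ", i, " is a spore")
  .swarm_direction_cpp(.stateList(state), .cfgList(config), as.integer(i))
}

#' Reverse a cell's polarity
#'
#' Swaps the head and tail labels (node coordinates and the C-signal counter
#' are untouched); applying it twice restores the original polarity. The
#' engine triggers this whenever the simulation clock passes the cell's
#' scheduled reversal time and then advances the schedule by a fresh
#' truncated Normal(revMean, revSd) interval; the reversal period is
#' independent of C-signal.
#'
#' @param state a [SwarmState-class] object.
#' @param i cell index.
#' @return the state with cell `i`'s polarity swapped.
#' @export
reverseCell <- function(state, i) {
  stopifnot(is(state, "SwarmState"))
  state@head0[i] <- !state@head0[i]
  state
}

#' Detect aligned end-to-end contacts
#'
#' Returns the unordered pairs of motile cells that qualify for C-signal
#' exchange this step: some end node of one within `contactDist` of some end
#' node of the other, body axes within `alignMaxDeg` degrees (the acute
#' angle; polarity is ignored), and no lateral overlap (midpoints farther
#' apart than one segment length), so side-by-side cells never signal.
#'
#' @param state a [SwarmState-class] object.
#' @param config a [SwarmConfig-class] object.
#' @return a two-column integer matrix of cell index pairs (i < j).
#' @export
detectEndContacts <- function(state, config) {
  stopifnot(is(state, "SwarmState"), is(config, "SwarmConfig"))
  out <- .swarm_contacts_cpp(.stateList(state), .cfgList(config))
  colnames(out) <- c("i", "j")
  out
}

#' Apply C-signal exchange and sporulation
#'
#' Both members of every contact pair gain one C-signal count (a cell in `k`
#' pairs gains `k`); any motile cell at or above the threshold converts: its
#' body collapses to a circular spore at the former midpoint and it is
#' removed from future motion and signaling while remaining a collision
#' obstacle.
#'
#' @param state a [SwarmState-class] object.
#' @param config a [SwarmConfig-class] object.
#' @param pairs two-column matrix of cell pairs, as returned by
#'   [detectEndContacts()].
#' @return the updated state.
#' @export
applySignaling <- function(state, config, pairs) {
  stopifnot(is(state, "SwarmState"), is(config, "SwarmConfig"))
  if (length(pairs)) {
    inc <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = nrow(state@nodes))
    state@counter <- state@counter + as.integer(inc)
  }
  conv <- which(!state@spore & state@counter >= config@threshold)
  for (i in conv) {
    state@nodes[i, ] <- state@nodes[i, c(3, 4, 3, 4, 3, 4)]
    state@spore[i] <- TRUE
  }
  state
}

#' Advance the swarm model
#'
#' One step processes every motile cell in a freshly shuffled order
#' (reversal check, direction computation, head displacement by
#' `speed * dt`, Metropolis relaxation of the trailing nodes with collision
#' handling, slime deposition), then performs one round of end-to-end
#' contact detection, C-signal exchange and sporulation, and finally decays
#' the slime field. Uses the current R RNG stream.
#'
#' @param state a [SwarmState-class] object.
#' @param config a [SwarmConfig-class] object.
#' @param nSteps number of steps to take.
#' @return the advanced [SwarmState-class].
#' @export
stepSwarm <- function(state, config, nSteps = 1) {
  stopifnot(is(state, "SwarmState"), is(config, "SwarmConfig"))
  out <- .swarm_run_cpp(
    .stateList(state), .cfgList(config),
    .asCount(nSteps, "nSteps"), 0L, 0L
  )
  .stateFromList(out$state)
}

#' Run the swarm model
#'
#' Seeds the RNG from the configuration, initializes the state (unless one
#' is supplied) and runs until `maxSteps` steps have been taken or
#' `stopSpores` spores have formed, collecting periodic snapshots, the
#' reversal event log and the spore conversion table.
#'
#' @param config a [SwarmConfig-class] object.
#' @param maxSteps maximum number of steps.
#' @param snapshotEvery take a state snapshot every this many steps
#'   (0 = none).
#' @param stopSpores stop once this many spores exist anywhere (0 = never).
#' @param stopInDisc stop once this many spores lie inside the aggregation
#'   discs (0 = never), checked every `checkEvery` steps.
#' @param checkEvery cadence, in steps, of the in-disc stop check.
#' @param state optional starting [SwarmState-class]; when supplied the RNG
#'   is *not* re-seeded, so runs can be continued.
#' @return a [SwarmResult-class]; its `sporeTable` maps every conversion to
#'   the disc containing it (NA outside all discs).
#' @export
runSwarm <- function(config, maxSteps, snapshotEvery = 0, stopSpores = 0,
                     stopInDisc = 0, checkEvery = 50, state = NULL) {
  stopifnot(is(config, "SwarmConfig"))
  maxSteps <- .asCount(maxSteps, "maxSteps", min = 0L)
  snapshotEvery <- .asCount(snapshotEvery, "snapshotEvery", min = 0L)
  stopSpores <- .asCount(stopSpores, "stopSpores", min = 0L)
  stopInDisc <- .asCount(stopInDisc, "stopInDisc", min = 0L)
  if (is.null(state)) {
    state <- initSwarm(config) # seeds the RNG
  }
  assignDisc <- function(x, y) {
    id <- rep(NA_integer_, length(x))
    if (length(x) && nrow(config@discs) > 0) {
      for (d in seq_len(nrow(config@discs))) {
        dx <- x - config@discs[d, 1]
        dx <- dx - config@domain * round(dx / config@domain)
        dy <- y - config@discs[d, 2]
        dy <- dy - config@domain * round(dy / config@domain)
        inside <- sqrt(dx^2 + dy^2) <= config@discs[d, 3]
        id[inside & is.na(id)] <- d
      }
    }
    id
  }
  stateL <- .stateList(state)
  cfgL <- .cfgList(config)
  convX <- convY <- revT <- numeric(0)
  convStep <- convCell <- revC <- integer(0)
  snapshots <- list()
  left <- maxSteps
  stepsRun <- 0L
  while (left > 0) {
    chunk <- if (stopInDisc > 0) min(left, .asCount(checkEvery, "checkEvery")) else left
    out <- .swarm_run_cpp(stateL, cfgL, chunk, snapshotEvery, stopSpores)
    stateL <- out$state
    stepsRun <- stepsRun + as.integer(out$stepsRun)
    left <- left - as.integer(out$stepsRun)
    convX <- c(convX, out$convX)
    convY <- c(convY, out$convY)
    convStep <- c(convStep, out$convStep)
    convCell <- c(convCell, out$convCell)
    revT <- c(revT, out$reversalTimes)
    revC <- c(revC, out$reversalCells)
    snapshots <- c(snapshots, out$snapshots)
    if (stopSpores > 0 && sum(stateL$spore) >= stopSpores) break
    if (stopInDisc > 0) {
      mid <- stateL$nodes[, 3:4, drop = FALSE]
      sp <- stateL$spore
      inDisc <- !is.na(assignDisc(mid[sp, 1], mid[sp, 2]))
      if (sum(inDisc) >= stopInDisc) break
    }
  }
  new("SwarmResult",
    state = .stateFromList(stateL),
    sporeTable = data.frame(
      x_um = convX, y_um = convY, disc_id = assignDisc(convX, convY),
      conversion_step = convStep, cell = convCell
    ),
    snapshots = snapshots,
    reversalTimes = revT,
    reversalCells = as.integer(revC),
    stepsRun = stepsRun, config = config
  )
}

#' Net circulation of cells inside a disc
#'
#' A proxy for the summed angular momentum about the disc centre: the sum
#' over in-disc motile cells of the cross product between the midpoint
#' offset from the centre and the head-ward unit axis (the direction of
#' self-propulsion). Positive values indicate counter-clockwise rotation.
#'
#' @param state a [SwarmState-class] object, or a snapshot entry from
#'   [runSwarm()].
#' @param center disc centre `(x, y)`, um.
#' @param radius disc radius, um.
#' @param domain periodic domain side, um.
#' @return the summed circulation (um units).
#' @export
discCirculation <- function(state, center, radius, domain) {
  if (is(state, "SwarmState")) {
    nodes <- state@nodes
    head0 <- state@head0
    spore <- state@spore
  } else {
    nodes <- state$nodes
    head0 <- state$head0
    spore <- state$spore
  }
  hx <- ifelse(head0, nodes[, 1], nodes[, 5])
  hy <- ifelse(head0, nodes[, 2], nodes[, 6])
  tx <- ifelse(head0, nodes[, 5], nodes[, 1])
  ty <- ifelse(head0, nodes[, 6], nodes[, 2])
  ax <- hx - tx
  ay <- hy - ty
  nrm <- sqrt(ax^2 + ay^2)
  keep <- !spore & nrm > 1e-12
  dx <- nodes[, 3] - center[1]
  dx <- dx - domain * round(dx / domain)
  dy <- nodes[, 4] - center[2]
  dy <- dy - domain * round(dy / domain)
  keep <- keep & sqrt(dx^2 + dy^2) <= radius
  sum((dx * ay / nrm - dy * ax / nrm)[keep])
}
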