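# shared fixture builders

# a straight three-node rod: middle at (x, y), axis at `angleDeg`, head
# forward; returns the 6-vector (x0, y0, x1, y1, x2, y2)
rodRow <- function(x, y, angleDeg = 0, l0 = 2.5) {
  a <- c(cos(angleDeg * pi / 180), sin(angleDeg * pi / 180))
  c(x + l0 * a[1], y + l0 * a[2], x, y, x - l0 * a[1], y - l0 * a[2])
}

# small open-domain swarm configuration for controlled geometries
bareSwarmConfig <- function(..., wN = 0) {
  swarmConfig(
    domain = 60, discs = matrix(numeric(0), 0, 3), nCells = 1,
    wN = wN, seed = 1L, ...
  )
}

# the scaled-down one-disc study configuration used for clustering analyses
discSwarmConfig <- function(seed, ...) {
  swarmConfig(
    domain = 125, discs = cbind(62.5, 62.5, 50), nCells = 600,
    seed = seed, ...
  )
}

# build a TrackState directly (positions 0-based)
makeTrackState <- function(position, concentration, spore = NULL, L,
                           step = 0L) {
  if (is.null(spore)) spore <- rep(FALSE, length(position))
  new("TrackState",
    position = as.integer(position), concentration = as.numeric(concentration),
    spore = spore, step = as.integer(step), trackLength = as.integer(L)
  )
}

# mean nearest-neighbour distance of in-disc spores and of label-shuffled
# controls (spore labels re-drawn over all in-disc agent midpoints)
sporeNndVsShuffled <- function(state, center, radius, nShuffle = 20) {
  mid <- state@nodes[, 3:4]
  dx <- mid[, 1] - center[1]
  dy <- mid[, 2] - center[2]
  inDisc <- sqrt(dx^2 + dy^2) <= radius
  sp <- state@spore & inDisc
  pool <- mid[inDisc, , drop = FALSE]
  k <- sum(sp)
  ctrl <- replicate(nShuffle, {
    mean(nearestNeighbourDistances(pool[sample(nrow(pool), k), , drop = FALSE]))
  })
  c(nnd = mean(nearestNeighbourDistances(mid[sp, , drop = FALSE])),
    ctrl = mean(ctrl))
}
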