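#' @import methods
NULL

# ---------------------------------------------------------------------------
# 1D track model
# ---------------------------------------------------------------------------

#' Parameters of the 1D circular-track model
#'
#' Cells hop clockwise on a ring of `trackLength` discrete sites. A site may
#' hold any number of agents ("side by side" in the pseudo-2D sense); only
#' spores impede movement, with effective passing probability `passProb^n`
#' for `n` spores at the target site. Each step every motile cell gains
#' `basalIncrement` of C-signal plus `transferRate` times the mean
#' concentration of motile cells one site ahead and behind; at
#' `sporeThreshold` it freezes into a spore.
#'
#' @slot trackLength integer, number of ring positions.
#' @slot nCells integer, number of agents.
#' @slot passProb passing probability in \[0, 1\].
#' @slot transferRate non-negative C-signal transfer coefficient.
#' @slot basalIncrement per-step basal C-signal production (> 0, guarantees
#'   termination).
#' @slot sporeThreshold concentration at which a cell sporulates.
#' @slot initRange closed interval for initial concentrations, a subset of
#'   `[0, sporeThreshold)`.
#' @slot seed integer RNG seed.
#' @exportClass TrackParams
setClass("TrackParams",
  representation(
    trackLength = "integer", nCells = "integer", passProb = "numeric",
    transferRate = "numeric", basalIncrement = "numeric",
    sporeThreshold = "numeric", initRange = "numeric", seed = "integer"
  )
)

setValidity("TrackParams", function(object) {
  msg <- character()
  if (length(object@trackLength) != 1 || is.na(object@trackLength) ||
    object@trackLength < 1) {
    msg <- c(msg, "trackLength must be a positive integer")
  }
  if (length(object@nCells) != 1 || is.na(object@nCells) ||
    object@nCells < 1) {
    msg <- c(msg, "nCells must be a positive integer")
  }
  if (object@passProb < 0 || object@passProb > 1) {
    msg <- c(msg, "passProb must lie in [0, 1]")
  }
  if (object@transferRate < 0) msg <- c(msg, "transferRate must be >= 0")
  if (object@basalIncrement <= 0) msg <- c(msg, "basalIncrement must be > 0")
  if (length(object@initRange) != 2 || object@initRange[1] > object@initRange[2]) {
    msg <- c(msg, "initRange must be a non-decreasing length-2 interval")
  } else if (object@initRange[1] < 0 ||
    object@initRange[2] >= object@sporeThreshold) {
    msg <- c(msg, "initRange must be a subset of [0, sporeThreshold)")
  }
  if (length(msg)) msg else TRUE
})

#' State of a 1D track simulation
#'
#' @slot position integer vector of agent positions (0-based, modulo the
#'   track length).
#' @slot concentration numeric vector of per-agent C-signal.
#' @slot spore logical vector; `TRUE` once an agent has sporulated.
#' @slot step integer step counter.
#' @slot trackLength the ring length the positions live on.
#' @exportClass TrackState
setClass("TrackState",
  representation(
    position = "integer", concentration = "numeric", spore = "logical",
    step = "integer", trackLength = "integer"
  )
)

setValidity("TrackState", function(object) {
  n <- length(object@position)
  msg <- character()
  if (length(object@concentration) != n || length(object@spore) != n) {
    msg <- c(msg, "position, concentration and spore must have equal length")
  }
  if (any(object@position < 0) || any(object@position >= object@trackLength)) {
    msg <- c(msg, "positions must lie in [0, trackLength)")
  }
  if (any(object@concentration < 0)) {
    msg <- c(msg, "concentrations must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a completed 1D track run
#'
#' @slot sporeCounts integer vector of final spore counts per track position.
#' @slot steps number of steps until all agents sporulated.
#' @slot params the [TrackParams] the run used.
#' @exportClass TrackResult
setClass("TrackResult",
  representation(
    sporeCounts = "integer", steps = "integer", params = "TrackParams"
  )
)

setValidity("TrackResult", function(object) {
  msg <- character()
  if (sum(object@sporeCounts) != object@params@nCells) {
    msg <- c(msg, "spore counts must sum to the number of cells")
  }
  bound <- ceiling(object@params@sporeThreshold / object@params@basalIncrement)
  if (object@steps > bound + 1L) {
    msg <- c(msg, "steps exceed the basal-production termination bound")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# 2D swarm model
# ---------------------------------------------------------------------------

#' Configuration of the 2D stochastic rod model
#'
#' Cells are three-node bendable rods of rest segment length `l0` (total
#' length `2 * l0`) on a periodic square domain. Direction is a normalized
#' weighted sum of the head-ward long axis (A-motility, `wA`), the mean
#' orientation of cells sensed one cell length ahead (S-motility, `wS`), the
#' local slime-trail direction (`wT`), and a random unit vector (`wN`).
#' Trailing nodes relax by Metropolis sampling of the harmonic
#' bending/stretching energy at temperature `temperature`; candidate
#' configurations that would worsen a body overlap are rejected. Motile cells
#' whose body axes are within `alignMaxDeg` degrees (polarity ignored) and
#' whose end nodes touch within `contactDist`, without lateral midpoint
#' overlap, exchange one C-signal unit per step; at `threshold` counts a cell
#' becomes an immobile circular spore of radius `sporeRadius`.
#'
#' All lengths are in micrometres, times in minutes.
#'
#' @exportClass SwarmConfig
setClass("SwarmConfig",
  representation(
    domain = "numeric", discs = "matrix", nCells = "integer",
    l0 = "numeric", width = "numeric", speed = "numeric", dt = "numeric",
    kb = "numeric", ks = "numeric",
    wA = "numeric", wS = "numeric", wT = "numeric", wN = "numeric",
    revMean = "numeric", revSd = "numeric", alignMaxDeg = "numeric",
    threshold = "integer", contactDist = "numeric", sporeRadius = "numeric",
    temperature = "numeric", slimeRes = "numeric", slimeHalfLife = "numeric",
    slimeSense = "numeric", proposalBudget = "integer", proposalSd = "numeric",
    seed = "integer"
  )
)

setValidity("SwarmConfig", function(object) {
  msg <- character()
  lens <- c(
    domain = object@domain, l0 = object@l0, width = object@width,
    dt = object@dt, sporeRadius = object@sporeRadius,
    contactDist = object@contactDist, slimeRes = object@slimeRes
  )
  if (any(lens <= 0)) {
    msg <- c(msg, paste0(
      "positive length required for: ",
      paste(names(lens)[lens <= 0], collapse = ", ")
    ))
  }
  w <- c(object@wA, object@wS, object@wT, object@wN)
  if (any(w < 0) || all(w == 0)) {
    msg <- c(msg, "direction weights must be >= 0 with at least one > 0")
  }
  if (object@alignMaxDeg <= 0 || object@alignMaxDeg >= 90) {
    msg <- c(msg, "alignMaxDeg must lie in (0, 90)")
  }
  if (object@nCells < 1) msg <- c(msg, "nCells must be >= 1")
  if (ncol(object@discs) != 3) {
    msg <- c(msg, "discs must be an n x 3 matrix (x, y, radius)")
  } else if (nrow(object@discs) > 1) {
    d <- object@discs
    for (i in seq_len(nrow(d) - 1)) {
      for (j in seq(i + 1, nrow(d))) {
        dx <- abs(d[i, 1] - d[j, 1])
        dx <- min(dx, object@domain - dx)
        dy <- abs(d[i, 2] - d[j, 2])
        dy <- min(dy, object@domain - dy)
        if (sqrt(dx^2 + dy^2) < d[i, 3] + d[j, 3]) {
          msg <- c(msg, "overlapping discs")
        }
      }
    }
  }
  if (nrow(object@discs) > 0 && any(object@discs[, 3] * 2 > object@domain)) {
    msg <- c(msg, "discs must fit in the domain")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' State of a 2D swarm simulation
#'
#' @slot nodes numeric matrix, one row per cell with columns
#'   `(x0, y0, x1, y1, x2, y2)`; node 1 is the middle node. For spores all
#'   three nodes coincide at the spore centre.
#' @slot head0 logical; `TRUE` when node 0 is the head.
#' @slot counter integer C-signal counters (monotone non-decreasing).
#' @slot spore logical cell states.
#' @slot nextRev next scheduled reversal time per cell, minutes.
#' @slot slime list of slime-field grids: angle-doubled nematic direction
#'   components `c2`, `s2` and deposit weight `w` (trails are axial, so
#'   opposing traffic reinforces the stored axis).
#' @slot steps number of steps taken so far.
#' @exportClass SwarmState
setClass("SwarmState",
  representation(
    nodes = "matrix", head0 = "logical", counter = "integer",
    spore = "logical", nextRev = "numeric", slime = "list", steps = "numeric"
  )
)

setValidity("SwarmState", function(object) {
  n <- nrow(object@nodes)
  msg <- character()
  if (ncol(object@nodes) != 6) msg <- c(msg, "nodes must have 6 columns")
  if (length(object@head0) != n || length(object@counter) != n ||
    length(object@spore) != n || length(object@nextRev) != n) {
    msg <- c(msg, "per-cell slots must match the number of node rows")
  }
  if (any(object@counter < 0)) msg <- c(msg, "counters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of a 2D swarm run
#'
#' @slot state final [SwarmState].
#' @slot sporeTable data.frame of conversions: `x_um`, `y_um`, `disc_id`
#'   (NA outside every disc), `conversion_step`, `cell`.
#' @slot snapshots list of periodic state snapshots (step, nodes, states).
#' @slot reversalTimes numeric vector of scheduled reversal times (minutes).
#' @slot reversalCells cell index for each logged reversal.
#' @slot stepsRun number of steps executed by this run.
#' @slot config the [SwarmConfig] used.
#' @exportClass SwarmResult
setClass("SwarmResult",
  representation(
    state = "SwarmState", sporeTable = "data.frame", snapshots = "list",
    reversalTimes = "numeric", reversalCells = "integer",
    stepsRun = "integer", config = "SwarmConfig"
  )
)

# ---------------------------------------------------------------------------
# Volumetric image analysis
# ---------------------------------------------------------------------------

#' A 3D grayscale intensity volume
#'
#' The in-memory stand-in for an OCT scan: an 8-bit-range grayscale grid with
#' physical pixel spacing. Slice `z = 1` is the base of the mound (the agar
#' surface); height above the base is `(z - 1) * sliceUm`.
#'
#' @slot data 3D numeric array indexed `[row (y), col (x), z]`, values in
#'   \[0, 255\].
#' @slot pxUm in-plane pixel spacing, micrometres per pixel.
#' @slot sliceUm spacing between z slices, micrometres.
#' @exportClass IntensityVolume
setClass("IntensityVolume",
  representation(data = "array", pxUm = "numeric", sliceUm = "numeric")
)

setValidity("IntensityVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3) msg <- c(msg, "data must be a 3D array")
  if (any(object@data < 0, na.rm = TRUE) ||
    any(object@data > 255, na.rm = TRUE)) {
    msg <- c(msg, "intensities must lie in [0, 255]")
  }
  if (object@pxUm <= 0 || object@sliceUm <= 0) {
    msg <- c(msg, "pixel spacings must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Moment-based ellipse fit of a cross-section
#'
#' Obtained from the intensity-weighted covariance matrix of an image: the
#' semi-axes are `2 * sqrt(lambda)` for the eigenvalues `lambda` (exact for a
#' uniform-intensity ellipse), the orientation is the principal eigenvector
#' angle in degrees counter-clockwise from +x, mapped to (-90, 90].
#'
#' @slot centroid `(x, y)` centroid in pixel coordinates (1-based).
#' @slot orientation degrees in (-90, 90].
#' @slot eccentricity `sqrt(1 - (b/a)^2)` in \[0, 1).
#' @slot semiMajor,semiMinor semi-axes in pixels.
#' @slot m00 total intensity mass.
#' @slot flagged `TRUE` when the fit is degenerate (collinear mass) or nearly
#'   isotropic, in which case the orientation is unconstrained.
#' @exportClass EllipseFit
setClass("EllipseFit",
  representation(
    centroid = "numeric", orientation = "numeric", eccentricity = "numeric",
    semiMajor = "numeric", semiMinor = "numeric", m00 = "numeric",
    flagged = "logical"
  )
)

setValidity("EllipseFit", function(object) {
  msg <- character()
  if (object@semiMajor < object@semiMinor) {
    msg <- c(msg, "semiMajor must be >= semiMinor")
  }
  if (object@eccentricity < 0 || object@eccentricity >= 1) {
    msg <- c(msg, "eccentricity must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Point patterns
# ---------------------------------------------------------------------------

#' A 2D spore point pattern with its analysis disc
#'
#' @slot points n x 2 matrix of coordinates in micrometres.
#' @slot center disc centre `(x, y)`, micrometres.
#' @slot radius disc radius, micrometres.
#' @exportClass SporePattern
setClass("SporePattern",
  representation(points = "matrix", center = "numeric", radius = "numeric")
)

setValidity("SporePattern", function(object) {
  msg <- character()
  if (ncol(object@points) != 2) msg <- c(msg, "points must have 2 columns")
  if (nrow(object@points) > 0 && !all(is.finite(object@points))) {
    msg <- c(msg, "point coordinates must be finite")
  }
  if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
  if (length(msg)) msg else TRUE
})

#' A gridded (possibly kernel-smoothed) spore density field
#'
#' @slot values matrix of per-node values indexed `[x bin, y bin]`.
#' @slot origin `(x, y)` of the lower-left corner of the analysis window.
#' @slot cellSize grid cell side length, micrometres.
#' @exportClass DensityField
setClass("DensityField",
  representation(values = "matrix", origin = "numeric", cellSize = "numeric")
)

setValidity("DensityField", function(object) {
  msg <- character()
  if (any(object@values < 0)) msg <- c(msg, "field values must be >= 0")
  if (object@cellSize <= 0) msg <- c(msg, "cellSize must be > 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Synthetic ground truth
# ---------------------------------------------------------------------------

#' Ground truth of a synthetic cone-shaped mound volume
#'
#' Describes a linearly tapering elliptical cone (semi-axes shrink to zero at
#' `apexHeight`) of roughly uniform interior intensity with additive Gaussian
#' noise, optional embedded spherical high-density pockets, and a dim
#' background.
#'
#' @slot baseAxes base semi-axes `(a, b)` in micrometres.
#' @slot apexHeight apex height in micrometres.
#' @slot baseIntensity interior intensity at the base, in (0, 255).
#' @slot noiseSd additive Gaussian noise standard deviation.
#' @slot background exterior intensity (below the surface isovalue).
#' @slot pockets data.frame with columns `x`, `y`, `z` (micrometres, centred
#'   in-plane on the cone axis), `diameter` (micrometres) and `boost`
#'   (added intensity).
#' @exportClass MoundTruth
setClass("MoundTruth",
  representation(
    baseAxes = "numeric", apexHeight = "numeric", baseIntensity = "numeric",
    noiseSd = "numeric", background = "numeric", pockets = "data.frame"
  )
)

setValidity("MoundTruth", function(object) {
  msg <- character()
  if (any(object@baseAxes <= 0) || object@apexHeight <= 0) {
    msg <- c(msg, "base axes and apex height must be > 0")
  }
  if (object@baseIntensity <= 0 || object@baseIntensity >= 255) {
    msg <- c(msg, "baseIntensity must lie in (0, 255)")
  }
  if (nrow(object@pockets) > 0) {
    if (any(object@pockets$diameter <= 0)) {
      msg <- c(msg, "pocket diameters must be > 0")
    }
    ok <- .pocketsInsideCone(object)
    if (!all(ok)) msg <- c(msg, "pockets must lie inside the cone")
  }
  if (length(msg)) msg else TRUE
})
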