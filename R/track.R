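#' Construct parameters for the 1D circular-track model
#'
#' The track model is a zeroth-order description of cells confined to a
#' closed path inside a nascent fruiting body: agents hop clockwise around a
#' ring of discrete sites, are slowed by spores occupying the site ahead
#' (passing probability `P^n` for `n` spores), accumulate C-signal through a
#' basal production plus transfer from motile cells in the two neighbouring
#' sites, and sporulate in place at a threshold concentration. Because the
#' basal increment is strictly positive every run terminates within
#' `ceiling(sporeThreshold / basalIncrement)` steps.
#'
#' @param trackLength number of discrete ring positions (default 100).
#' @param nCells number of agents (default 60).
#' @param passProb passing probability `P` in \[0, 1\].
#' @param transferRate C-signal transfer rate `T` (>= 0).
#' @param basalIncrement basal C-signal production per step (default 0.005).
#' @param sporeThreshold sporulation threshold (default 1.0).
#' @param initRange interval initial concentrations are drawn from
#'   (default `c(0, 0.5)`).
#' @param seed RNG seed used by [initTrack()] and [runTrack()].
#' @return a [TrackParams-class] object.
#' @examples
#' p <- trackParams(passProb = 0.1)
#' res <- runTrack(p)
#' trackSummary(res)$voidFraction
#' @export
trackParams <- function(trackLength = 100, nCells = 60, passProb = 1,
                        transferRate = 0, basalIncrement = 0.005,
                        sporeThreshold = 1, initRange = c(0, 0.5),
                        seed = 1L) {
  new("TrackParams",
    trackLength = .asCount(trackLength, "trackLength"),
    nCells = .asCount(nCells, "nCells"),
    passProb = .assertScalar(passProb, "passProb", 0, 1),
    transferRate = .assertScalar(transferRate, "transferRate", 0),
    basalIncrement = basalIncrement, sporeThreshold = sporeThreshold,
    initRange = as.numeric(initRange), seed = as.integer(seed)
  )
}

#' Initialize a track state
#'
#' Places agents i.i.d. uniformly on the ring positions and draws initial
#' C-signal concentrations i.i.d. uniformly from the configured interval;
#' all agents start motile. Reproducible from the seed in `params`.
#'
#' @param params a [TrackParams-class] object.
#' @return a [TrackState-class] object at step 0.
#' @export
initTrack <- function(params) {
  stopifnot(is(params, "TrackParams"))
  validObject(params)
  set.seed(params@seed)
  ini <- .track_init_cpp(
    params@trackLength, params@nCells,
    params@initRange[1], params@initRange[2]
  )
  new("TrackState",
    position = ini$position, concentration = ini$concentration,
    spore = rep(FALSE, params@nCells), step = 0L,
    trackLength = params@trackLength
  )
}

#' Draw passing attempts against a spore-occupied site
#'
#' A cell moving into a site holding `nSpores` spores passes with effective
#' probability `P^nSpores` (`P^0 = 1`). Uses the current R RNG stream.
#'
#' @param nSpores number of spores at the target site (>= 0).
#' @param P passing probability in \[0, 1\].
#' @param n number of independent attempts to draw.
#' @return logical vector of length `n`: `TRUE` where the pass succeeds.
#' @export
attemptPass <- function(nSpores, P, n = 1) {
  nSpores <- .asCount(nSpores, "nSpores", min = 0L)
  .assertScalar(P, "P", 0, 1)
  .track_pass_cpp(nSpores, P, .asCount(n, "n"))
}

#' Apply one synchronous C-signal update
#'
#' Every motile cell gains the basal increment plus `T * cbar`, where `cbar`
#' is the mean pre-update concentration over all motile cells at the two
#' neighbouring ring positions (cells sharing the cell's own position
#' contribute nothing; spores are excluded; with no motile neighbour the
#' transfer term is zero). Concentrations never decrease. No movement or
#' conversion is performed.
#'
#' @param state a [TrackState-class] object.
#' @param params a [TrackParams-class] object.
#' @return the state with updated concentrations.
#' @export
updateSignals <- function(state, params) {
  stopifnot(is(state, "TrackState"), is(params, "TrackParams"))
  state@concentration <- .track_signals_cpp(
    state@position, state@concentration, state@spore,
    params@trackLength, params@transferRate, params@basalIncrement
  )
  state
}

#' Advance the track model
#'
#' One step is: movement of every motile cell in a freshly shuffled random
#' order, each attempting one clockwise hop gated by [attemptPass()] against
#' the spore count at the target; then the synchronous signaling update of
#' [updateSignals()]; then conversion of every motile cell at or above the
#' spore threshold into a spore at its current position.
#'
#' @param state a [TrackState-class] object.
#' @param params a [TrackParams-class] object.
#' @param nSteps number of steps to take.
#' @return the advanced state. Uses the current R RNG stream (seed the run
#'   with `set.seed()` or start from [initTrack()], which seeds it).
#' @export
stepTrack <- function(state, params, nSteps = 1) {
  stopifnot(is(state, "TrackState"), is(params, "TrackParams"))
  out <- .track_step_cpp(
    state@position, state@concentration, state@spore,
    params@trackLength, params@passProb, params@transferRate,
    params@basalIncrement, params@sporeThreshold, .asCount(nSteps, "nSteps")
  )
  new("TrackState",
    position = out$position, concentration = out$concentration,
    spore = out$spore, step = state@step + as.integer(nSteps),
    trackLength = params@trackLength
  )
}

#' Run the track model to completion
#'
#' Seeds the RNG from `params`, initializes the state and iterates
#' [stepTrack()] until every agent has sporulated (guaranteed within
#' `ceiling(sporeThreshold / basalIncrement)` steps by basal production).
#'
#' @param params a [TrackParams-class] object.
#' @return a [TrackResult-class] with the final per-position spore counts.
#' @export
runTrack <- function(params) {
  stopifnot(is(params, "TrackParams"))
  validObject(params)
  state <- initTrack(params)
  out <- .track_run_cpp(
    state@position, state@concentration, state@spore,
    params@trackLength, params@passProb, params@transferRate,
    params@basalIncrement, params@sporeThreshold
  )
  new("TrackResult",
    sporeCounts = out$sporeCounts, steps = as.integer(out$steps),
    params = params
  )
}

#' Summarize a completed track run
#'
#' @param result a [TrackResult-class] object.
#' @return a list with `voidFraction` (fraction of positions holding no
#'   spore), `sporeCounts` (per-position counts), `maxCluster` (largest
#'   spore count at a single position) and `meanCluster` (mean count over
#'   occupied positions).
#' @export
trackSummary <- function(result) {
  stopifnot(is(result, "TrackResult"))
  counts <- result@sporeCounts
  occupied <- counts[counts > 0]
  list(
    voidFraction = mean(counts == 0),
    sporeCounts = counts,
    maxCluster = max(counts),
    meanCluster = if (length(occupied)) mean(occupied) else 0,
    steps = result@steps
  )
}

#' Sweep passing probability and transfer rate
#'
#' Runs `reps` independent simulations for every `(P, T)` pair, deriving the
#' replicate seed as `base@seed + replicate - 1` so the whole table is
#' reproducible, and aggregates the void fraction per pair.
#'
#' @param PGrid passing probabilities (default 20 values, 0.05 to 1).
#' @param TGrid transfer rates (default 0 to 0.4 in steps of 0.1).
#' @param reps replicates per pair (default 100).
#' @param base a [TrackParams-class] supplying all other parameters.
#' @param detail if `TRUE` also return the per-replicate table.
#' @return a long-format data.frame with one row per `(P, T)` pair:
#'   `P`, `T`, `reps`, `meanVoidFraction`, `sdVoidFraction` (0 when
#'   `reps == 1`), `meanMaxCluster`, `meanSteps`. With `detail = TRUE` the
#'   per-replicate rows are attached as `attr(, "replicates")`.
#' @export
sweepTrack <- function(PGrid = seq(0.05, 1, by = 0.05),
                       TGrid = seq(0, 0.4, by = 0.1),
                       reps = 100, base = trackParams(), detail = FALSE) {
  stopifnot(length(PGrid) > 0, length(TGrid) > 0, is(base, "TrackParams"))
  reps <- .asCount(reps, "reps")
  grid <- expand.grid(P = PGrid, T = TGrid, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    vf <- mx <- st <- numeric(reps)
    for (r in seq_len(reps)) {
      p <- base
      p@passProb <- grid$P[g]
      p@transferRate <- grid$T[g]
      p@seed <- base@seed + as.integer(r - 1)
      res <- runTrack(p)
      vf[r] <- mean(res@sporeCounts == 0)
      mx[r] <- max(res@sporeCounts)
      st[r] <- res@steps
    }
    rows[[g]] <- data.frame(
      P = grid$P[g], T = grid$T[g], rep = seq_len(reps),
      voidFraction = vf, maxCluster = mx, steps = st
    )
  }
  det <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(det, list(det$P, det$T), drop = TRUE),
    function(d) {
      data.frame(
        P = d$P[1], T = d$T[1], reps = nrow(d),
        meanVoidFraction = mean(d$voidFraction),
        sdVoidFraction = if (nrow(d) > 1) sd(d$voidFraction) else 0,
        meanMaxCluster = mean(d$maxCluster),
        meanSteps = mean(d$steps)
      )
    }
  ))
  agg <- agg[order(agg$T, agg$P), ]
  rownames(agg) <- NULL
  if (detail) attr(agg, "replicates") <- det
  agg
}
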