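#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sporeCounts", function(object) standardGeneric("sporeCounts"))

#' @rdname accessors
#' @export
setGeneric("voidFraction", function(object) standardGeneric("voidFraction"))

#' @rdname accessors
#' @export
setGeneric("stepsToCompletion", function(object) {
  standardGeneric("stepsToCompletion")
})

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))

#' @rdname accessors
#' @export
setGeneric("sliceSpacing", function(object) standardGeneric("sliceSpacing"))

#' @rdname accessors
#' @export
setGeneric("sporePoints", function(object) standardGeneric("sporePoints"))

#' @rdname accessors
#' @export
setGeneric("discCenter", function(object) standardGeneric("discCenter"))

#' @rdname accessors
#' @export
setGeneric("discRadius", function(object) standardGeneric("discRadius"))

#' @rdname accessors
#' @export
setGeneric("fieldValues", function(object) standardGeneric("fieldValues"))

#' @rdname accessors
#' @export
setGeneric("sporeTable", function(object) standardGeneric("sporeTable"))

#' @rdname accessors
#' @export
setMethod("sporeCounts", "TrackResult", function(object) object@sporeCounts)

#' @rdname accessors
#' @export
setMethod("voidFraction", "TrackResult", function(object) {
  mean(object@sporeCounts == 0)
})

#' @rdname accessors
#' @export
setMethod("stepsToCompletion", "TrackResult", function(object) object@steps)

#' @rdname accessors
#' @export
setMethod("voxels", "IntensityVolume", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("pixelSpacing", "IntensityVolume", function(object) object@pxUm)

#' @rdname accessors
#' @export
setMethod("sliceSpacing", "IntensityVolume", function(object) object@sliceUm)

#' @rdname accessors
#' @export
setMethod("sporePoints", "SporePattern", function(object) object@points)

#' @rdname accessors
#' @export
setMethod("discCenter", "SporePattern", function(object) object@center)

#' @rdname accessors
#' @export
setMethod("discRadius", "SporePattern", function(object) object@radius)

#' @rdname accessors
#' @export
setMethod("fieldValues", "DensityField", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("sporeTable", "SwarmResult", function(object) object@sporeTable)

setMethod("show", "TrackParams", function(object) {
  cat(sprintf(
    "TrackParams: L=%d sites, N=%d cells, P=%g, T=%g, basal=%g, threshold=%g\n",
    object@trackLength, object@nCells, object@passProb, object@transferRate,
    object@basalIncrement, object@sporeThreshold
  ))
})

setMethod("show", "TrackState", function(object) {
  cat(sprintf(
    "TrackState: %d agents on %d sites, %d spores, step %d\n",
    length(object@position), object@trackLength, sum(object@spore),
    object@step
  ))
})

setMethod("show", "TrackResult", function(object) {
  cat(sprintf(
    "TrackResult: %d spores on %d sites, void fraction %.3f, %d steps\n",
    sum(object@sporeCounts), object@params@trackLength,
    mean(object@sporeCounts == 0), object@steps
  ))
})

setMethod("show", "SwarmConfig", function(object) {
  cat(sprintf(
    paste0(
      "SwarmConfig: %g x %g um periodic domain, %d cells, %d disc(s)\n",
      "  rod: l0=%g um, width=%g um, v=%g um/min, dt=%g min\n",
      "  weights (A,S,T,noise) = (%g, %g, %g, %g); reversals %g +/- %g min\n",
      "  signaling: <%g deg end-to-end within %g um, threshold %d\n"
    ),
    object@domain, object@domain, object@nCells, nrow(object@discs),
    object@l0, object@width, object@speed, object@dt,
    object@wA, object@wS, object@wT, object@wN,
    object@revMean, object@revSd,
    object@alignMaxDeg, object@contactDist, object@threshold
  ))
})

setMethod("show", "SwarmState", function(object) {
  cat(sprintf(
    "SwarmState: %d cells (%d spores), step %g\n",
    nrow(object@nodes), sum(object@spore), object@steps
  ))
})

setMethod("show", "SwarmResult", function(object) {
  cat(sprintf(
    "SwarmResult: %d steps run, %d spores formed\n",
    object@stepsRun, nrow(object@sporeTable)
  ))
})

setMethod("show", "IntensityVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "IntensityVolume: %d x %d px x %d slices (%.2f um/px, %.2f um/slice)\n",
    d[1], d[2], d[3], object@pxUm, object@sliceUm
  ))
})

setMethod("show", "EllipseFit", function(object) {
  cat(sprintf(
    paste0(
      "EllipseFit: centroid (%.2f, %.2f), orientation %.1f deg, ",
      "axes (%.2f, %.2f), ecc %.3f%s\n"
    ),
    object@centroid[1], object@centroid[2], object@orientation,
    object@semiMajor, object@semiMinor, object@eccentricity,
    if (object@flagged) " [flagged]" else ""
  ))
})

setMethod("show", "SporePattern", function(object) {
  cat(sprintf(
    "SporePattern: %d points, disc centre (%.1f, %.1f), radius %.1f um\n",
    nrow(object@points), object@center[1], object@center[2], object@radius
  ))
})

setMethod("show", "DensityField", function(object) {
  cat(sprintf(
    "DensityField: %d x %d grid, cell %.3f um, total mass %.3f\n",
    nrow(object@values), ncol(object@values), object@cellSize,
    sum(object@values)
  ))
})

setMethod("show", "MoundTruth", function(object) {
  cat(sprintf(
    "MoundTruth: base semi-axes (%g, %g) um, apex %g um, intensity %g, %d pocket(s)\n",
    object@baseAxes[1], object@baseAxes[2], object@apexHeight,
    object@baseIntensity, nrow(object@pockets)
  ))
})
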