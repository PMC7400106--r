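## Generics, accessors and show methods.

#' Adhered cells of a simulated field
#'
#' @param x a \linkS4class{SimulatedField}
#' @return data.frame(cell_id, x_um, y_um, attach_s, detach_s)
#' @export
setGeneric("adheredCells", function(x) standardGeneric("adheredCells"))

#' @rdname adheredCells
#' @export
setMethod("adheredCells", "SimulatedField", function(x) x@cells)

#' Event log of a simulated field
#'
#' @param x a \linkS4class{SimulatedField}
#' @return data.frame(cell_id, event, time_s, x_um, y_um)
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))

#' @rdname eventLog
#' @export
setMethod("eventLog", "SimulatedField", function(x) x@events)

#' Frame times of a simulated field
#'
#' @param x a \linkS4class{SimulatedField}
#' @return numeric vector of frame timestamps (s)
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "SimulatedField", function(x) x@frameTimes)

#' Positions adhered at one frame
#'
#' Cells with attach <= t < detach at the requested frame time.
#'
#' @param x a \linkS4class{SimulatedField}
#' @param frame frame index (1-based into \code{frameTimes(x)})
#' @return data.frame(cell_id, x_um, y_um, attach_s)
#' @export
setGeneric("framePositions", function(x, frame) {
    standardGeneric("framePositions")
})

#' @rdname framePositions
#' @export
setMethod("framePositions", "SimulatedField", function(x, frame) {
    stopifnot(frame >= 1, frame <= length(x@frameTimes))
    t <- x@frameTimes[frame]
    keep <- x@cells$attach_s <= t & x@cells$detach_s > t
    x@cells[keep, c("cell_id", "x_um", "y_um", "attach_s")]
})

#' Slopes of a two-phase fit
#'
#' @param x a \linkS4class{TwoPhaseFit}
#' @return named numeric c(s1, s2) in cells/(cm^2.min)
#' @export
setGeneric("slopes", function(x) standardGeneric("slopes"))

#' @rdname slopes
#' @export
setMethod("slopes", "TwoPhaseFit", function(x) {
    setNames(x@slopes, c("s1", "s2"))
})

#' Breakpoint of a two-phase fit
#'
#' @param x a \linkS4class{TwoPhaseFit}
#' @return breakpoint time (s)
#' @export
setGeneric("breakpoint", function(x) standardGeneric("breakpoint"))

#' @rdname breakpoint
#' @export
setMethod("breakpoint", "TwoPhaseFit", function(x) x@breakpoint)

#' Normalised density map of a pair-correlation map
#'
#' @param x a \linkS4class{PairCorrelationMap}
#' @return matrix of per-bin probability mass (sums to 1 over the disc)
#' @export
setGeneric("densityMap", function(x) standardGeneric("densityMap"))

#' @rdname densityMap
#' @export
setMethod("densityMap", "PairCorrelationMap", function(x) x@density)

#' Pair count of a pair-correlation map
#'
#' @param x a \linkS4class{PairCorrelationMap}
#' @return total number of accumulated pairs
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname nPairs
#' @export
setMethod("nPairs", "PairCorrelationMap", function(x) x@nPairs)

## ---- show methods ---------------------------------------------------------

setMethod("show", "ChannelGeometry", function(object) {
    cat(sprintf(
        "ChannelGeometry: %.4g x %.4g m cross-section, length %.4g m, x = %.4g m\n",
        object@width, object@height, object@length, object@axialPosition))
})

setMethod("show", "FlowCondition", function(object) {
    cat(sprintf(
        "FlowCondition: Q = %.3g mL/s, v_av = %.3g m/s, gamma = %.3g /s, tau_w = %.3g Pa (%s)\n",
        object@flowRate * 1e6, object@averageVelocity, object@shearRate,
        object@wallShearStress, object@shearSource))
})

setMethod("show", "SimulatedField", function(object) {
    nAdh <- sum(object@cells$attach_s <= object@config@duration &
                object@cells$detach_s > object@config@duration)
    cat(sprintf(
        paste0("SimulatedField: %d x %d um, %d frames, %d attach events",
               " (%d rejected), %d adhered at end\n"),
        round(object@config@fieldWidth), round(object@config@fieldHeight),
        length(object@frameTimes), nrow(object@cells), object@nRejected,
        nAdh))
})

setMethod("show", "ImageFrame", function(object) {
    cat(sprintf("ImageFrame: %d x %d px at %.3g um/px, t = %.6g s\n",
                nrow(object@data), ncol(object@data), object@pixelScale,
                object@timestamp))
})

setMethod("show", "AdhesionTimeSeries", function(object) {
    cat(sprintf(
        "AdhesionTimeSeries '%s' (rep %s): %d points, %.6g-%.6g s, final %.4g cells/cm^2\n",
        object@condition, object@replicate, length(object@times),
        min(object@times), max(object@times),
        object@densities[length(object@densities)]))
})

setMethod("show", "TwoPhaseFit", function(object) {
    cat(sprintf(
        paste0("TwoPhaseFit: t_b = %.4g min, s1 = %.4g, s2 = %.4g",
               " cells/(cm^2.min), reduction = %.1f%%\n"),
        object@breakpoint / 60, object@slopes[1], object@slopes[2],
        rateReduction(object)))
})

setMethod("show", "RateComparison", function(object) {
    cat(sprintf("RateComparison: %d groups, F = %.4g (p = %.3g)\n",
                length(object@groups), object@fStatistic, object@fPValue))
    print(object@table, row.names = FALSE)
})

setMethod("show", "PairCorrelationMap", function(object) {
    cat(sprintf(
        "PairCorrelationMap (%s): rMax = %d px, %d field(s), %d refs, %.0f pairs, max bin %.3g\n",
        object@mode, object@rMax, object@nFields, object@nRef, object@nPairs,
        max(object@density)))
})

setMethod("show", "AnisotropyResult", function(object) {
    cat(sprintf(
        "AnisotropyResult: index = %.3f (theta = %g deg, r_s = %g px, %s mode)\n",
        object@index, object@theta, object@rS, object@mode))
    if (!is.na(object@pValue))
        cat(sprintf("  permutation p = %.4g (%d permutations)%s\n",
                    object@pValue, object@nPerm,
                    if (object@caveat) " [caveat: < 50 pairs]" else ""))
})

setMethod("show", "RunConfig", function(object) {
    cat(sprintf("RunConfig: mode = %s, %d condition(s), seed = %d\n",
                object@mode, nrow(object@conditions), object@seed))
})
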