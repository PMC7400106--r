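## S4 class definitions and validity. Internal units are strictly SI for the
## hydrodynamics (m, s, kg) and micrometres for simulator/image coordinates;
## cells/(cm^2.s) appears only at reporting boundaries.

#' ChannelGeometry: rectangular flow-channel geometry
#'
#' Geometry of the parallel-plate flow cell: channel width \code{w}, height
#' \code{h0} (the small dimension of the rectangular cross-section), total
#' channel length, and the axial observation position \code{x} at which
#' transport estimates are evaluated.
#'
#' @slot width channel width w (m)
#' @slot height channel height h0 (m); must not exceed the width
#' @slot length channel length (m)
#' @slot axialPosition axial distance x of the observation window from the
#'   inlet (m); must not exceed the channel length
#' @exportClass ChannelGeometry
setClass("ChannelGeometry",
    representation(width = "numeric", height = "numeric",
                   length = "numeric", axialPosition = "numeric"),
    validity = function(object) {
        v <- c(width = object@width, height = object@height,
               length = object@length, axialPosition = object@axialPosition)
        if (any(!is.finite(v)) || any(v <= 0))
            return("all geometry fields must be finite and > 0")
        if (object@height > object@width)
            return("height h0 must not exceed width w")
        if (object@axialPosition > object@length)
            return("axialPosition x must not exceed channel length")
        TRUE
    })

#' Construct a ChannelGeometry
#'
#' @param width,height,length channel width, height and length (m)
#' @param axialPosition axial observation position (m); defaults to
#'   mid-channel, \code{length/2}
#' @return a \linkS4class{ChannelGeometry}
#' @examples
#' ChannelGeometry(width = 0.016, height = 0.008, length = 0.2542)
#' @export
ChannelGeometry <- function(width, height, length, axialPosition = length / 2) {
    new("ChannelGeometry", width = width, height = height, length = length,
        axialPosition = axialPosition)
}

#' FluidProperties: bulk fluid and suspension properties
#'
#' @slot density fluid density rho (kg/m^3)
#' @slot viscosity dynamic viscosity mu (kg/(m.s))
#' @slot diffusionCoefficient cell diffusion coefficient D_inf (m^2/s)
#' @slot cellConcentration bulk cell concentration C_b (cells/m^3)
#' @exportClass FluidProperties
setClass("FluidProperties",
    representation(density = "numeric", viscosity = "numeric",
                   diffusionCoefficient = "numeric",
                   cellConcentration = "numeric"),
    validity = function(object) {
        v <- c(object@density, object@viscosity,
               object@diffusionCoefficient, object@cellConcentration)
        if (any(!is.finite(v)) || any(v <= 0))
            return("all fluid properties must be finite and > 0")
        TRUE
    })

#' Construct FluidProperties
#'
#' @param density rho (kg/m^3)
#' @param viscosity mu (kg/(m.s))
#' @param diffusionCoefficient D_inf (m^2/s)
#' @param cellConcentration C_b (cells/m^3)
#' @return a \linkS4class{FluidProperties}
#' @export
FluidProperties <- function(density, viscosity, diffusionCoefficient,
                            cellConcentration) {
    new("FluidProperties", density = density, viscosity = viscosity,
        diffusionCoefficient = diffusionCoefficient,
        cellConcentration = cellConcentration)
}

#' CellMorphology: rod-shaped cell dimensions and equivalent radius
#'
#' The equivalent hydrodynamic radius can either be supplied directly or
#' derived from the cell length and diameter with
#' \code{\link{microbialRadius}}. The radius is never silently recomputed
#' from \code{length}/\code{diameter} once set.
#'
#' @slot length cell length L (m); \code{NA} when only a radius is given
#' @slot diameter cell diameter b (m); \code{NA} when only a radius is given
#' @slot radius equivalent radius R_b (m)
#' @exportClass CellMorphology
setClass("CellMorphology",
    representation(length = "numeric", diameter = "numeric",
                   radius = "numeric"),
    validity = function(object) {
        if (!is.finite(object@radius) || object@radius <= 0)
            return("equivalent radius R_b must be finite and > 0")
        if (!is.na(object@length) || !is.na(object@diameter)) {
            if (is.na(object@length) || is.na(object@diameter))
                return("length and diameter must be given together")
            if (object@diameter <= 0 || object@length < object@diameter)
                return("need L >= b > 0")
        }
        TRUE
    })

#' Construct a CellMorphology
#'
#' @param radius equivalent radius R_b (m); when missing it is computed from
#'   \code{length} and \code{diameter} via \code{\link{microbialRadius}}
#' @param length,diameter cell length L and diameter b (m), optional
#' @return a \linkS4class{CellMorphology}
#' @examples
#' CellMorphology(radius = 4.5e-7)
#' CellMorphology(length = 2e-6, diameter = 1e-6)
#' @export
CellMorphology <- function(radius = NULL, length = NA_real_,
                           diameter = NA_real_) {
    if (is.null(radius)) {
        if (is.na(length) || is.na(diameter))
            stop("supply either `radius` or both `length` and `diameter`")
        radius <- microbialRadius(length, diameter)
    }
    new("CellMorphology", length = length, diameter = diameter,
        radius = radius)
}

#' FlowCondition: one hydraulic operating point
#'
#' One operating point of the flow cell: volumetric flow rate, mean velocity,
#' wall shear rate and wall shear stress. Shear values can be supplied (e.g.
#' from a CFD computation of the real channel) or derived from the Newtonian
#' wide-slot approximation; \code{shearSource} records which.
#'
#' @slot flowRate volumetric flow rate Q (m^3/s)
#' @slot averageVelocity mean velocity v_av = Q/(w h0) (m/s)
#' @slot shearRate wall shear rate gamma (1/s)
#' @slot wallShearStress wall shear stress tau_w (Pa)
#' @slot shearSource \code{"analytic"} or \code{"supplied"}
#' @exportClass FlowCondition
setClass("FlowCondition",
    representation(flowRate = "numeric", averageVelocity = "numeric",
                   shearRate = "numeric", wallShearStress = "numeric",
                   shearSource = "character"),
    validity = function(object) {
        if (!is.finite(object@flowRate) || object@flowRate <= 0)
            return("flowRate Q must be finite and > 0")
        if (object@averageVelocity <= 0)
            return("averageVelocity must be > 0")
        if (object@shearRate < 0 || object@wallShearStress < 0)
            return("shearRate and wallShearStress must be >= 0")
        if (!object@shearSource %in% c("analytic", "supplied"))
            return("shearSource must be 'analytic' or 'supplied'")
        TRUE
    })

#' ShadowModel: hydrodynamic-blocking shadow geometry
#'
#' Rectangular footprint downstream (+x, the flow direction) of every adhered
#' cell inside which further adhesion is prohibited while the cell remains
#' adhered. Colloid deposition studies report blocked areas of 8 to 675 times
#' the particle cross-section; the default footprint is 20 times the
#' cross-section of a cell of radius 0.45 um.
#'
#' @slot enabled logical; when FALSE the shadow rule is skipped
#' @slot length downstream extent of the shadow (um)
#' @slot halfwidth half-width of the shadow strip (um)
#' @exportClass ShadowModel
setClass("ShadowModel",
    representation(enabled = "logical", length = "numeric",
                   halfwidth = "numeric"),
    validity = function(object) {
        if (object@length < 0 || object@halfwidth < 0)
            return("shadow length and halfwidth must be >= 0")
        TRUE
    })

#' Construct a ShadowModel
#'
#' @param enabled enable the blocking rule
#' @param length downstream extent (um)
#' @param halfwidth strip half-width (um); the default geometry
#'   (14.14 x 0.9 um) blocks 20 cell cross-sections for R_cell = 0.45 um
#' @return a \linkS4class{ShadowModel}
#' @export
ShadowModel <- function(enabled = FALSE, length = 14.14, halfwidth = 0.45) {
    new("ShadowModel", enabled = enabled, length = length,
        halfwidth = halfwidth)
}

#' Shadow-to-cell area multiple
#'
#' Ratio of the shadow footprint area to the cross-sectional area of a cell,
#' the conventional way blocked areas are reported for colloid deposition.
#'
#' @param shadow a \linkS4class{ShadowModel}
#' @param cellRadius cell radius (um)
#' @return dimensionless area multiple
#' @export
shadowAreaMultiple <- function(shadow, cellRadius) {
    stopifnot(is(shadow, "ShadowModel"), cellRadius > 0)
    (shadow@length * 2 * shadow@halfwidth) / (pi * cellRadius^2)
}

#' SimulationConfig: parameters of one synthetic adhesion experiment
#'
#' @slot fieldWidth,fieldHeight observed field size (um)
#' @slot pixelScale image scale (um/pixel)
#' @slot arrivalRate attempted deposition rate (cells/(cm^2.s)); typically the
#'   Smoluchowski-Levich flux for the flow condition being emulated
#' @slot detachRate first-order detachment rate k_det (1/s)
#' @slot hardCoreRadius hard-core radius (um); adhered cells are never closer
#'   than twice this value
#' @slot shadow a \linkS4class{ShadowModel}
#' @slot duration assay duration (s)
#' @slot frameInterval time between frames (s)
#' @slot seed integer RNG seed
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(fieldWidth = "numeric", fieldHeight = "numeric",
                   pixelScale = "numeric", arrivalRate = "numeric",
                   detachRate = "numeric", hardCoreRadius = "numeric",
                   shadow = "ShadowModel", duration = "numeric",
                   frameInterval = "numeric", seed = "integer"),
    validity = function(object) {
        if (object@fieldWidth <= 0 || object@fieldHeight <= 0)
            return("field dimensions must be > 0")
        if (object@pixelScale <= 0) return("pixelScale must be > 0")
        if (object@arrivalRate < 0) return("arrivalRate must be >= 0")
        if (object@detachRate < 0) return("detachRate must be >= 0")
        if (object@hardCoreRadius < 0) return("hardCoreRadius must be >= 0")
        if (object@frameInterval <= 0) return("frameInterval must be > 0")
        if (object@duration < object@frameInterval)
            return("duration must be >= frameInterval")
        TRUE
    })

#' Construct a SimulationConfig
#'
#' Defaults mirror a 30-minute flow-cell assay imaged every 60 s at
#' 0.61 um/pixel on a 1000 x 1000 px field, with an arrival rate equal to the
#' Smoluchowski-Levich flux at the lowest flow condition of the bundled
#' preset (about 80 cells/(cm^2.s)) and no detachment or blocking.
#'
#' @param fieldWidth,fieldHeight field size (um)
#' @param pixelScale um per pixel
#' @param arrivalRate cells/(cm^2.s)
#' @param detachRate k_det (1/s)
#' @param hardCoreRadius um
#' @param shadow a \linkS4class{ShadowModel}
#' @param duration s
#' @param frameInterval s
#' @param seed integer seed
#' @return a \linkS4class{SimulationConfig}
#' @export
SimulationConfig <- function(fieldWidth = 610, fieldHeight = 610,
                             pixelScale = 0.61, arrivalRate = 79.6,
                             detachRate = 0, hardCoreRadius = 0.5,
                             shadow = ShadowModel(), duration = 1800,
                             frameInterval = 60, seed = 1L) {
    new("SimulationConfig", fieldWidth = fieldWidth,
        fieldHeight = fieldHeight, pixelScale = pixelScale,
        arrivalRate = arrivalRate, detachRate = detachRate,
        hardCoreRadius = hardCoreRadius, shadow = shadow,
        duration = duration, frameInterval = frameInterval,
        seed = as.integer(seed))
}

#' SimulatedField: output of one simulated adhesion experiment
#'
#' Ground-truth record of a simulated assay: per-cell attach/detach times and
#' positions, the event log, and the frame grid. Frame t contains exactly the
#' cells with attach <= t < detach.
#'
#' @slot config the \linkS4class{SimulationConfig} used
#' @slot cells data.frame(cell_id, x_um, y_um, attach_s, detach_s); detach_s
#'   is \code{Inf} for cells that never detach
#' @slot events data.frame(cell_id, event, time_s, x_um, y_um) in time order
#' @slot frameTimes frame timestamps (s)
#' @slot nAttempts number of attempted arrivals
#' @slot nRejected arrivals rejected by the hard-core or shadow rule
#' @exportClass SimulatedField
setClass("SimulatedField",
    representation(config = "SimulationConfig", cells = "data.frame",
                   events = "data.frame", frameTimes = "numeric",
                   nAttempts = "integer", nRejected = "integer"))

#' ImageFrame: one grayscale microscopy frame
#'
#' @slot data numeric matrix of 8-bit intensities in [0, 255]; rows are image
#'   rows (y, top to bottom), columns are x
#' @slot pixelScale um per pixel
#' @slot timestamp acquisition time (s)
#' @exportClass ImageFrame
setClass("ImageFrame",
    representation(data = "matrix", pixelScale = "numeric",
                   timestamp = "numeric"),
    validity = function(object) {
        if (object@pixelScale <= 0) return("pixelScale must be > 0")
        rng <- range(object@data)
        if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
            return("pixel values must lie in [0, 255]")
        TRUE
    })

#' Construct an ImageFrame
#'
#' @param data intensity matrix in [0, 255]
#' @param pixelScale um/pixel
#' @param timestamp s
#' @return an \linkS4class{ImageFrame}
#' @export
ImageFrame <- function(data, pixelScale = 0.61, timestamp = 0) {
    new("ImageFrame", data = data, pixelScale = pixelScale,
        timestamp = timestamp)
}

#' DetectionParams: cell-detection parameters
#'
#' @slot noiseTolerance minimum prominence (8-bit intensity units) a maximum
#'   must have, after inversion, to count as a cell
#' @slot minSeparation minimum separation between reported maxima (px);
#'   closer maxima are suppressed keeping the brighter one
#' @slot smoothSigma Gaussian pre-smoothing sigma (px) applied to the
#'   inverted image before maxima detection; 0 disables
#' @slot areaThresholdMethod \code{"otsu"} or \code{"fixed"} for
#'   \code{\link{areaFraction}}
#' @slot fixedThreshold threshold (applied to the inverted image) when
#'   \code{areaThresholdMethod = "fixed"}
#' @exportClass DetectionParams
setClass("DetectionParams",
    representation(noiseTolerance = "numeric", minSeparation = "numeric",
                   smoothSigma = "numeric", areaThresholdMethod = "character",
                   fixedThreshold = "numeric"),
    validity = function(object) {
        if (object@noiseTolerance < 0) return("noiseTolerance must be >= 0")
        if (object@minSeparation < 1) return("minSeparation must be >= 1")
        if (object@smoothSigma < 0) return("smoothSigma must be >= 0")
        if (!object@areaThresholdMethod %in% c("otsu", "fixed"))
            return("areaThresholdMethod must be 'otsu' or 'fixed'")
        TRUE
    })

#' Construct DetectionParams
#'
#' @param noiseTolerance prominence threshold (default 10 intensity units)
#' @param minSeparation px (default 3, about two cell radii at 0.61 um/px)
#' @param smoothSigma px (default 1.5, a matched filter against shot noise)
#' @param areaThresholdMethod "otsu" or "fixed"
#' @param fixedThreshold intensity for the fixed method
#' @return a \linkS4class{DetectionParams}
#' @export
DetectionParams <- function(noiseTolerance = 10, minSeparation = 3,
                            smoothSigma = 1.5,
                            areaThresholdMethod = c("otsu", "fixed"),
                            fixedThreshold = 128) {
    new("DetectionParams", noiseTolerance = noiseTolerance,
        minSeparation = minSeparation, smoothSigma = smoothSigma,
        areaThresholdMethod = match.arg(areaThresholdMethod),
        fixedThreshold = fixedThreshold)
}

#' AdhesionTimeSeries: adhered-cell density versus time
#'
#' @slot times timestamps (s), strictly increasing
#' @slot densities adhered-cell surface densities (cells/cm^2), >= 0
#' @slot condition condition label
#' @slot replicate replicate identifier
#' @exportClass AdhesionTimeSeries
setClass("AdhesionTimeSeries",
    representation(times = "numeric", densities = "numeric",
                   condition = "character", replicate = "character"),
    validity = function(object) {
        if (length(object@times) != length(object@densities))
            return("times and densities must have equal length")
        if (length(object@times) > 1 && any(diff(object@times) <= 0))
            return("times must be strictly increasing")
        if (any(object@densities < 0)) return("densities must be >= 0")
        TRUE
    })

#' Construct an AdhesionTimeSeries
#'
#' @param times s
#' @param densities cells/cm^2
#' @param condition,replicate labels
#' @return an \linkS4class{AdhesionTimeSeries}
#' @export
AdhesionTimeSeries <- function(times, densities, condition = "condition",
                               replicate = "1") {
    new("AdhesionTimeSeries", times = as.numeric(times),
        densities = as.numeric(densities), condition = condition,
        replicate = replicate)
}

#' TwoPhaseFit: two-segment linear fit of adhesion kinetics
#'
#' @slot breakpoint breakpoint time t_b (s); the first segment uses points
#'   with t <= t_b, the second t > t_b
#' @slot slopes initial and final slopes s1, s2 (cells/(cm^2.min))
#' @slot intercepts per-segment intercepts (cells/cm^2, at t = 0)
#' @slot r2 per-segment coefficients of determination
#' @slot sse total sum of squared errors of the two segments
#' @slot nPoints points per segment
#' @slot window breakpoint search window (s)
#' @slot candidates data.frame(time_s, sse) of all candidate breakpoints
#' @exportClass TwoPhaseFit
setClass("TwoPhaseFit",
    representation(breakpoint = "numeric", slopes = "numeric",
                   intercepts = "numeric", r2 = "numeric", sse = "numeric",
                   nPoints = "integer", window = "numeric",
                   candidates = "data.frame"))

#' RateComparison: ANOVA + Tukey HSD comparison of adhesion rates
#'
#' @slot groups named list of per-condition replicate slopes
#' @slot fStatistic one-way ANOVA F
#' @slot fPValue ANOVA p-value
#' @slot table data.frame of pairwise Tukey HSD comparisons
#' @slot alpha significance level used for the flags
#' @exportClass RateComparison
setClass("RateComparison",
    representation(groups = "list", fStatistic = "numeric",
                   fPValue = "numeric", table = "data.frame",
                   alpha = "numeric"))

#' PairCorrelationMap: 2D pair-correlation probability-density map
#'
#' Square histogram of displacement vectors from each reference cell to its
#' neighbours within a disc of radius \code{rMax}, with 1-px bins, normalised
#' so the bins within the disc sum to 1. Rows index Delta-y (-rMax..rMax, top
#' to bottom) and columns Delta-x; the flow direction is +x.
#'
#' @slot density normalised map; each bin is pair mass / total pairs
#' @slot counts raw integer pair counts
#' @slot nPairs total pairs within the disc
#' @slot nRef number of reference cells (after the border margin)
#' @slot nFields number of pooled fields
#' @slot rMax disc radius (px)
#' @slot mode \code{"unordered"} or \code{"time_ordered"}
#' @slot pairs optional data.frame(field, i, j, dx, dy) of raw pair
#'   displacements, kept when \code{keepPairs = TRUE}
#' @exportClass PairCorrelationMap
setClass("PairCorrelationMap",
    representation(density = "matrix", counts = "matrix", nPairs = "numeric",
                   nRef = "integer", nFields = "integer", rMax = "integer",
                   mode = "character", pairs = "data.frame"))

#' AnisotropyResult: flow-axis depletion index and permutation test
#'
#' @slot index observed pair mass in the flow-axis cone divided by the
#'   rotationally-uniform expectation; 1 means no blocking signature, < 1
#'   means downstream depletion
#' @slot theta cone half-angle (degrees)
#' @slot rS cone radius (px)
#' @slot mode map mode the index was computed in
#' @slot nPairs pairs within r <= rS
#' @slot pValue permutation p-value (NA when no test was run)
#' @slot nPerm number of permutations
#' @slot nullIndices null distribution of the index under random rotations
#' @slot caveat TRUE when fewer than 50 pairs supported the statistic
#' @exportClass AnisotropyResult
setClass("AnisotropyResult",
    representation(index = "numeric", theta = "numeric", rS = "numeric",
                   mode = "character", nPairs = "numeric", pValue = "numeric",
                   nPerm = "integer", nullIndices = "numeric",
                   caveat = "logical"))

#' RunConfig: configuration of an end-to-end pipeline run
#'
#' @slot mode \code{"simulate"}, \code{"images"} or \code{"coordinates"}
#' @slot geometry a \linkS4class{ChannelGeometry}
#' @slot fluid a \linkS4class{FluidProperties}
#' @slot cell a \linkS4class{CellMorphology}
#' @slot conditions data.frame(label, Q_mL_per_s, shear_rate_per_s,
#'   tau_w_Pa); shear columns may be NA to request the analytic slot formula
#' @slot simulation list of \linkS4class{SimulationConfig} overrides plus the
#'   detachment coupling constants \code{k0} (1/s) and \code{F_ref} (N)
#' @slot detection a \linkS4class{DetectionParams}
#' @slot blocking list(rMax, theta, rS, nPerm, mode)
#' @slot input for images/coordinates modes: path to a frame manifest or a
#'   coordinates CSV
#' @slot seed root seed
#' @exportClass RunConfig
setClass("RunConfig",
    representation(mode = "character", geometry = "ChannelGeometry",
                   fluid = "FluidProperties", cell = "CellMorphology",
                   conditions = "data.frame", simulation = "list",
                   detection = "DetectionParams", blocking = "list",
                   input = "character", seed = "integer"),
    validity = function(object) {
        if (!object@mode %in% c("simulate", "images", "coordinates"))
            return("mode must be one of 'simulate', 'images', 'coordinates'")
        need <- c("label", "Q_mL_per_s")
        if (!all(need %in% names(object@conditions)))
            return("conditions must have columns label and Q_mL_per_s")
        TRUE
    })
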