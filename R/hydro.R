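## Closed-form hydrodynamic, transport and force relations for the
## parallel-plate flow cell. All inputs/outputs SI; the Smoluchowski-Levich
## flux alone is reported in cells/(cm^2.s) because that is the unit the
## deposition literature uses.

.checkPositive <- function(...) {
    v <- c(...)
    bad <- !is.finite(v) | v <= 0
    if (any(bad))
        stop("invalid parameter: ", paste(names(v)[bad], collapse = ", "),
             " must be finite and > 0", call. = FALSE)
    invisible(TRUE)
}

#' Mean velocity in a rectangular channel
#'
#' Plug mean velocity v_av = Q / (w h0) for a channel of width w and height
#' h0.
#'
#' @param Q volumetric flow rate (m^3/s)
#' @param geom a \linkS4class{ChannelGeometry}
#' @return mean velocity (m/s)
#' @examples
#' g <- ChannelGeometry(0.016, 0.008, 0.2542)
#' averageVelocity(1e-6, g)  # 7.8125e-3 m/s
#' @export
averageVelocity <- function(Q, geom) {
    stopifnot(is(geom, "ChannelGeometry"))
    .checkPositive(Q = Q)
    Q / (geom@width * geom@height)
}

#' Analytic wall shear rate for a wide rectangular slot
#'
#' Newtonian plane-Poiseuille wall shear rate gamma = 6 Q / (w h0^2). This is
#' an approximation for the real channel (whose shear is usually obtained
#' from CFD); it is offered as a fallback and is never substituted for
#' supplied shear values.
#'
#' @inheritParams averageVelocity
#' @return wall shear rate (1/s)
#' @export
analyticShearRate <- function(Q, geom) {
    stopifnot(is(geom, "ChannelGeometry"))
    .checkPositive(Q = Q)
    6 * Q / (geom@width * geom@height^2)
}

#' Equivalent hydrodynamic radius of a rod-shaped cell
#'
#' R_b = (L/2) / (ln(L/b) - 0.11) for a cylinder of length L and diameter b.
#' The denominator must be positive, which requires L/b > exp(0.11).
#'
#' @param length cell length L (m)
#' @param diameter cell diameter b (m)
#' @return equivalent radius (m)
#' @examples
#' microbialRadius(2e-6, 1e-6)  # 1.715e-6 m
#' @export
microbialRadius <- function(length, diameter) {
    .checkPositive(length = length, diameter = diameter)
    denom <- log(length / diameter) - 0.11
    if (denom <= 0)
        stop("domain error: microbialRadius requires L/b > exp(0.11) ",
             "(ln(L/b) - 0.11 must be positive)", call. = FALSE)
    (length / 2) / denom
}

#' Peclet number for the parallel-plate configuration
#'
#' Pe = 3 v_av R_b^3 / (2 (h0/2)^2 D_inf), the ratio of convective to
#' diffusive transport of a cell of radius R_b at the channel wall.
#'
#' @param vav mean velocity (m/s); may be 0
#' @param Rb cell equivalent radius (m)
#' @param h0 channel height (m)
#' @param Dinf diffusion coefficient (m^2/s)
#' @return dimensionless Peclet number
#' @export
pecletNumber <- function(vav, Rb, h0, Dinf) {
    .checkPositive(Rb = Rb, h0 = h0, Dinf = Dinf)
    if (!is.finite(vav) || vav < 0)
        stop("invalid parameter: vav must be finite and >= 0", call. = FALSE)
    3 * vav * Rb^3 / (2 * (h0 / 2)^2 * Dinf)
}

#' Smoluchowski-Levich deposition flux
#'
#' Perfect-sink solution of the convective-diffusion equation for particle
#' deposition in a parallel-plate channel:
#' SL = 0.538 (D_inf C_b / R_b) (Pe h0 / x)^(1/3), evaluated at the axial
#' position x of the observation window. Computed in SI (cells/(m^2.s)) and
#' reported in cells/(cm^2.s).
#'
#' @param fluid a \linkS4class{FluidProperties}
#' @param Rb cell equivalent radius (m)
#' @param Pe Peclet number (>= 0)
#' @param geom a \linkS4class{ChannelGeometry}; its \code{axialPosition} is
#'   the x of the formula
#' @return deposition flux (cells/(cm^2.s))
#' @export
slDepositionRate <- function(fluid, Rb, Pe, geom) {
    stopifnot(is(fluid, "FluidProperties"), is(geom, "ChannelGeometry"))
    .checkPositive(Rb = Rb)
    if (!is.finite(Pe) || Pe < 0)
        stop("invalid parameter: Pe must be finite and >= 0", call. = FALSE)
    sl_si <- 0.538 * fluid@diffusionCoefficient * fluid@cellConcentration /
        Rb * (Pe * geom@height / geom@axialPosition)^(1 / 3)
    sl_si / 1e4
}

#' Drag force on an adhered cell
#'
#' Stokes-regime wall drag D = 32 tau_w R_b^2; higher-order terms in the
#' local Reynolds number are negligible for Re_c << 1.
#'
#' @param tauW wall shear stress (Pa, >= 0)
#' @param Rb cell equivalent radius (m)
#' @return drag force (N)
#' @export
dragForce <- function(tauW, Rb) {
    .checkPositive(Rb = Rb)
    if (!is.finite(tauW) || tauW < 0)
        stop("invalid parameter: tauW must be finite and >= 0", call. = FALSE)
    32 * tauW * Rb^2
}

#' Local Reynolds number at the particle scale
#'
#' Re_c = rho gamma R_b^2 / mu, the shear Reynolds number in the near-wall
#' region; Re_c << 1 justifies the Stokes drag scaling.
#'
#' @param rho fluid density (kg/m^3)
#' @param gamma shear rate (1/s, >= 0)
#' @param Rb cell equivalent radius (m)
#' @param mu dynamic viscosity (kg/(m.s))
#' @return dimensionless local Reynolds number
#' @export
localReynolds <- function(rho, gamma, Rb, mu) {
    .checkPositive(rho = rho, Rb = Rb, mu = mu)
    if (!is.finite(gamma) || gamma < 0)
        stop("invalid parameter: gamma must be finite and >= 0",
             call. = FALSE)
    rho * gamma * Rb^2 / mu
}

#' Construct a FlowCondition
#'
#' Derives the mean velocity from Q and the geometry. Shear values may be
#' supplied (e.g. CFD results for the real channel); when both are missing
#' the analytic wide-slot formula is used and \code{shearSource} is set to
#' \code{"analytic"}. A supplied shear rate without a stress is completed
#' with the Newtonian relation tau_w = mu gamma.
#'
#' @param Q volumetric flow rate (m^3/s)
#' @param geom a \linkS4class{ChannelGeometry}
#' @param fluid a \linkS4class{FluidProperties}
#' @param shearRate wall shear rate (1/s), optional
#' @param wallShearStress wall shear stress (Pa), optional
#' @return a \linkS4class{FlowCondition}
#' @export
FlowCondition <- function(Q, geom, fluid, shearRate = NULL,
                          wallShearStress = NULL) {
    stopifnot(is(geom, "ChannelGeometry"), is(fluid, "FluidProperties"))
    .checkPositive(Q = Q)
    vav <- averageVelocity(Q, geom)
    if (is.null(shearRate) && is.null(wallShearStress)) {
        shearRate <- analyticShearRate(Q, geom)
        wallShearStress <- fluid@viscosity * shearRate
        source <- "analytic"
    } else {
        source <- "supplied"
        if (is.null(shearRate)) shearRate <- wallShearStress / fluid@viscosity
        if (is.null(wallShearStress))
            wallShearStress <- fluid@viscosity * shearRate
    }
    new("FlowCondition", flowRate = Q, averageVelocity = vav,
        shearRate = shearRate, wallShearStress = wallShearStress,
        shearSource = source)
}

#' Transport and force table over flow conditions
#'
#' Evaluates the Peclet number, Smoluchowski-Levich flux, drag force and
#' local Reynolds number for each flow condition, one row per condition.
#'
#' @param conditions list of \linkS4class{FlowCondition} objects
#' @param fluid a \linkS4class{FluidProperties}
#' @param cell a \linkS4class{CellMorphology}
#' @param geom a \linkS4class{ChannelGeometry}
#' @return data.frame with columns Q_mL_per_s, v_av_m_s, shear_rate_per_s,
#'   tau_w_Pa, Pe, SL_cells_cm2_s, drag_N, Re_c
#' @examples
#' preset <- flowCellPreset()
#' tt <- transportTable(presetFlowConditions(preset), preset@fluid,
#'                      preset@cell, preset@geometry)
#' round(tt$SL_cells_cm2_s, -1)
#' @export
transportTable <- function(conditions, fluid, cell, geom) {
    stopifnot(length(conditions) > 0)
    rows <- lapply(seq_along(conditions), function(k) {
        fc <- conditions[[k]]
        if (!is(fc, "FlowCondition"))
            stop("condition ", k, " is not a FlowCondition", call. = FALSE)
        res <- tryCatch({
            Pe <- pecletNumber(fc@averageVelocity, cell@radius, geom@height,
                               fluid@diffusionCoefficient)
            data.frame(
                Q_mL_per_s = fc@flowRate * 1e6,
                v_av_m_s = fc@averageVelocity,
                shear_rate_per_s = fc@shearRate,
                tau_w_Pa = fc@wallShearStress,
                Pe = Pe,
                SL_cells_cm2_s = slDepositionRate(fluid, cell@radius, Pe,
                                                  geom),
                drag_N = dragForce(fc@wallShearStress, cell@radius),
                Re_c = localReynolds(fluid@density, fc@shearRate,
                                     cell@radius, fluid@viscosity))
        }, error = function(e) {
            stop("condition ", k, ": ", conditionMessage(e), call. = FALSE)
        })
        res
    })
    do.call(rbind, rows)
}
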