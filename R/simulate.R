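## Stochastic adhesion/detachment point process with optional hydrodynamic
## shadowing, the synthetic test bed standing in for flow-cell experiments.

# evaluate expr under a seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Simulate an adhesion/detachment experiment
#'
#' Cells arrive as a homogeneous Poisson process in time at rate
#' \code{arrivalRate} x field area and are placed uniformly over the field.
#' An arrival is rejected (lost, not re-queued: the convective sweep carries
#' it away) when it lands within twice the hard-core radius of a currently
#' adhered cell or inside the downstream shadow of one (when the shadow rule
#' is enabled; flow is along +x). Each adhered cell detaches independently at
#' rate \code{detachRate} (memoryless). The same seed and config always give
#' an identical event log.
#'
#' A warning is raised when more than half of the early arrival attempts are
#' rejected, which indicates the jamming regime where the field can no longer
#' accept the requested rate.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return a \linkS4class{SimulatedField}
#' @examples
#' field <- simulateAdhesion(SimulationConfig(duration = 600, seed = 7))
#' field
#' @export
simulateAdhesion <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    .withSeed(config@seed, .simulateAdhesionImpl(config))
}

.simulateAdhesionImpl <- function(config) {
    W <- config@fieldWidth; H <- config@fieldHeight
    areaCm2 <- W * H * 1e-8
    lambda <- config@arrivalRate * areaCm2   # arrivals per second
    dmin <- 2 * config@hardCoreRadius
    shadow <- config@shadow

    # arrival times over the assay
    times <- numeric(0)
    if (lambda > 0) {
        t <- 0; acc <- numeric(2048); nacc <- 0
        repeat {
            t <- t + rexp(1, lambda)
            if (t > config@duration) break
            nacc <- nacc + 1
            if (nacc > length(acc)) acc <- c(acc, numeric(length(acc)))
            acc[nacc] <- t
        }
        times <- acc[seq_len(nacc)]
    }
    nArr <- length(times)

    x <- y <- attach <- detach <- numeric(nArr)
    n <- 0L; nRej <- 0L; nRejEarly <- 0L
    nEarly <- min(nArr, 200L)
    for (k in seq_len(nArr)) {
        px <- runif(1, 0, W); py <- runif(1, 0, H)
        live <- seq_len(n)[attach[seq_len(n)] <= times[k] &
                           detach[seq_len(n)] > times[k]]
        blocked <- FALSE
        if (length(live)) {
            dx <- x[live] - px; dy <- y[live] - py
            if (dmin > 0 && any(dx * dx + dy * dy < dmin * dmin))
                blocked <- TRUE
            if (!blocked && shadow@enabled && shadow@length > 0) {
                # inside any adhered cell's downstream strip?
                sx <- px - x[live]  # positive downstream of the cell
                if (any(sx > 0 & sx <= shadow@length &
                        abs(py - y[live]) <= shadow@halfwidth))
                    blocked <- TRUE
            }
        }
        if (blocked) {
            nRej <- nRej + 1L
            if (k <= nEarly) nRejEarly <- nRejEarly + 1L
            next
        }
        n <- n + 1L
        x[n] <- px; y[n] <- py; attach[n] <- times[k]
        detach[n] <- if (config@detachRate > 0)
            times[k] + rexp(1, config@detachRate) else Inf
    }
    if (nEarly >= 20 && nRejEarly > nEarly / 2)
        warning("jamming regime: >50% of early placements rejected",
                call. = FALSE)

    cells <- data.frame(cell_id = seq_len(n), x_um = x[seq_len(n)],
                        y_um = y[seq_len(n)], attach_s = attach[seq_len(n)],
                        detach_s = detach[seq_len(n)])
    ev <- rbind(
        data.frame(cell_id = cells$cell_id, event = "attach",
                   time_s = cells$attach_s, x_um = cells$x_um,
                   y_um = cells$y_um),
        {
            det <- cells[is.finite(cells$detach_s) &
                         cells$detach_s <= config@duration, ]
            if (nrow(det))
                data.frame(cell_id = det$cell_id, event = "detach",
                           time_s = det$detach_s, x_um = det$x_um,
                           y_um = det$y_um)
            else
                data.frame(cell_id = integer(0), event = character(0),
                           time_s = numeric(0), x_um = numeric(0),
                           y_um = numeric(0))
        })
    ev <- ev[order(ev$time_s, ev$cell_id), , drop = FALSE]
    rownames(ev) <- NULL
    frames <- seq(config@frameInterval, config@duration,
                  by = config@frameInterval)
    new("SimulatedField", config = config, cells = cells, events = ev,
        frameTimes = frames, nAttempts = nArr, nRejected = nRej)
}

#' Simulate several independent fields from one root seed
#'
#' Field k runs with seed \code{seed + k - 1} (documented stream splitting),
#' emulating images taken in different regions of the surface.
#'
#' @param config a \linkS4class{SimulationConfig}; its seed is the root seed
#' @param nFields number of fields
#' @return list of \linkS4class{SimulatedField}
#' @export
simulateFields <- function(config, nFields) {
    stopifnot(nFields >= 1)
    lapply(seq_len(nFields), function(k) {
        cfg <- config
        cfg@seed <- config@seed + k - 1L
        simulateAdhesion(cfg)
    })
}

#' Uniform hard-core point field
#'
#' Random sequential adsorption of \code{n} points on a rectangle with
#' minimum separation \code{2 * hardCoreRadius}; the arrival order is
#' recorded as a surrogate attachment time. This is the non-blocking null
#' pattern for the pair-correlation analysis.
#'
#' @param n number of points
#' @param width,height field size (um)
#' @param hardCoreRadius hard-core radius (um)
#' @param seed integer seed
#' @return data.frame(x_um, y_um, t) with t = arrival rank
#' @export
uniformHardCoreField <- function(n, width, height, hardCoreRadius = 0.5,
                                 seed = 1L) {
    stopifnot(n >= 1, width > 0, height > 0, hardCoreRadius >= 0)
    res <- .withSeed(seed,
        cpp_rsa_field(as.integer(n), 0, width, 0, height,
                      2 * hardCoreRadius, as.integer(max(1000, 200 * n))))
    if (length(res$x) < n)
        warning("jamming: only ", length(res$x), " of ", n,
                " points placed after ", res$attempts, " attempts",
                call. = FALSE)
    data.frame(x_um = res$x, y_um = res$y, t = seq_along(res$x))
}

#' Simulation scenario for a flow condition
#'
#' Binds the transport estimates to the simulator: the arrival rate is set to
#' the Smoluchowski-Levich flux of the condition and the detachment rate is
#' scaled with the drag force, k_det = k0 * D / F_ref. The coupling constants
#' k0 and F_ref have no measured values and are exposed as configuration;
#' their defaults are arbitrary order-of-magnitude choices.
#'
#' @param transportRow one row of a \code{\link{transportTable}}
#' @param k0 detachment rate at the reference drag force (1/s)
#' @param Fref reference drag force (N); \code{k0 = 0} disables detachment
#' @param ... further arguments passed to \code{\link{SimulationConfig}}
#' @return a \linkS4class{SimulationConfig}
#' @export
scenarioFromTransport <- function(transportRow, k0 = 1 / 600,
                                  Fref = 3.37e-14, ...) {
    stopifnot(is.data.frame(transportRow), nrow(transportRow) == 1)
    kdet <- if (k0 > 0) k0 * transportRow$drag_N / Fref else 0
    SimulationConfig(arrivalRate = transportRow$SL_cells_cm2_s,
                     detachRate = kdet, ...)
}

#' Ground-truth adhesion time series of a simulated field
#'
#' @param field a \linkS4class{SimulatedField}
#' @param condition,replicate labels for the series
#' @return an \linkS4class{AdhesionTimeSeries} (cells/cm^2 at each frame)
#' @export
countSeries <- function(field, condition = "simulated", replicate = "1") {
    stopifnot(is(field, "SimulatedField"))
    areaCm2 <- field@config@fieldWidth * field@config@fieldHeight * 1e-8
    counts <- vapply(field@frameTimes, function(t) {
        sum(field@cells$attach_s <= t & field@cells$detach_s > t)
    }, numeric(1))
    AdhesionTimeSeries(field@frameTimes, counts / areaCm2, condition,
                       replicate)
}
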