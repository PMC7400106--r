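## End-to-end orchestration: preset configuration, YAML config round-trip,
## and the simulate -> detect -> kinetics -> blocking -> transport pipeline.

# CSV with numbers fixed to 6 significant digits for byte-stable outputs
.writeCsv <- function(df, path) {
    out <- df
    for (j in seq_along(out)) {
        if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
            out[[j]] <- formatC(out[[j]], digits = 6, format = "g")
    }
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    path
}

#' Bundled flow-cell experiment preset
#'
#' The configuration of a six-flow-rate initial-adhesion experiment on an
#' E. coli / PDMS system in a 0.8 x 1.6 cm x 25.42 cm parallel-plate flow
#' cell: flow rates 1, 2, 4, 6, 8 and 10 mL/s with CFD-derived wall shear
#' rates 7.5, 15.0, 33.7, 51.6, 80.3 and 100.8 /s, citrate-buffer fluid
#' properties (rho = 993.37 kg/m^3, mu = 6.94e-4 kg/(m.s)), cell diffusion
#' coefficient 4.0e-13 m^2/s, bulk concentration 7.6e13 cells/m^3, cell
#' equivalent radius 4.5e-7 m, 30-min assays imaged every 60 s at
#' 0.61 um/px, and a 50-px pair-correlation radius. The axial observation
#' position defaults to mid-channel (0.1271 m).
#'
#' @param mode pipeline input mode
#' @param seed root seed
#' @return a \linkS4class{RunConfig}
#' @examples
#' preset <- flowCellPreset()
#' preset@conditions
#' @export
flowCellPreset <- function(mode = "simulate", seed = 1L) {
    new("RunConfig",
        mode = mode,
        geometry = ChannelGeometry(width = 0.016, height = 0.008,
                                   length = 0.2542, axialPosition = 0.1271),
        fluid = FluidProperties(density = 993.37, viscosity = 0.000694,
                                diffusionCoefficient = 4.0e-13,
                                cellConcentration = 7.6e13),
        cell = CellMorphology(radius = 4.5e-7),
        conditions = data.frame(
            label = paste0("Q", c(1, 2, 4, 6, 8, 10), "mLs"),
            Q_mL_per_s = c(1, 2, 4, 6, 8, 10),
            shear_rate_per_s = c(7.5, 15.0, 33.7, 51.6, 80.3, 100.8),
            tau_w_Pa = NA_real_),
        simulation = list(fieldWidth = 610, fieldHeight = 610,
                          pixelScale = 0.61, hardCoreRadius = 0.5,
                          duration = 1800, frameInterval = 60,
                          k0 = 1 / 600, F_ref = 3.37e-14,
                          shadowEnabled = FALSE, shadowLength = 14.14,
                          shadowHalfwidth = 0.45),
        detection = DetectionParams(),
        blocking = list(rMax = 50L, theta = 30, rS = 50, nPerm = 199L,
                        mode = "unordered"),
        input = NA_character_,
        seed = as.integer(seed))
}

#' Flow conditions of a run configuration
#'
#' Builds one \linkS4class{FlowCondition} per row of the conditions table,
#' using the supplied shear values where present and the analytic wide-slot
#' formula otherwise.
#'
#' @param config a \linkS4class{RunConfig}
#' @return list of \linkS4class{FlowCondition}
#' @export
presetFlowConditions <- function(config) {
    stopifnot(is(config, "RunConfig"))
    cd <- config@conditions
    lapply(seq_len(nrow(cd)), function(k) {
        g <- if ("shear_rate_per_s" %in% names(cd) &&
                 !is.na(cd$shear_rate_per_s[k])) cd$shear_rate_per_s[k]
             else NULL
        tw <- if ("tau_w_Pa" %in% names(cd) && !is.na(cd$tau_w_Pa[k]))
            cd$tau_w_Pa[k] else NULL
        FlowCondition(cd$Q_mL_per_s[k] * 1e-6, config@geometry,
                      config@fluid, shearRate = g, wallShearStress = tw)
    })
}

.configToList <- function(config) {
    g <- config@geometry; f <- config@fluid; d <- config@detection
    list(mode = config@mode,
         geometry = list(width_m = g@width, height_m = g@height,
                         length_m = g@length,
                         axial_position_m = g@axialPosition),
         fluid = list(rho = f@density, mu = f@viscosity,
                      D_inf = f@diffusionCoefficient,
                      C_b = f@cellConcentration),
         cell = list(R_b = config@cell@radius),
         conditions = lapply(seq_len(nrow(config@conditions)), function(k) {
             as.list(config@conditions[k, ])
         }),
         simulation = config@simulation,
         detection = list(noise_tolerance = d@noiseTolerance,
                          min_separation = d@minSeparation,
                          smooth_sigma = d@smoothSigma,
                          area_threshold_method = d@areaThresholdMethod,
                          fixed_threshold = d@fixedThreshold),
         blocking = config@blocking,
         input = if (is.na(config@input)) NULL else config@input,
         seed = config@seed)
}

.listToConfig <- function(x) {
    cd <- do.call(rbind, lapply(x$conditions, function(r) {
        as.data.frame(r, stringsAsFactors = FALSE)
    }))
    cd$tau_w_Pa <- if (is.null(cd$tau_w_Pa)) NA_real_
                   else as.numeric(cd$tau_w_Pa)
    d <- x$detection
    new("RunConfig",
        mode = x$mode,
        geometry = ChannelGeometry(x$geometry$width_m, x$geometry$height_m,
                                   x$geometry$length_m,
                                   x$geometry$axial_position_m),
        fluid = FluidProperties(x$fluid$rho, x$fluid$mu, x$fluid$D_inf,
                                x$fluid$C_b),
        cell = CellMorphology(radius = x$cell$R_b),
        conditions = cd,
        simulation = x$simulation,
        detection = DetectionParams(d$noise_tolerance, d$min_separation,
                                    d$smooth_sigma,
                                    d$area_threshold_method,
                                    d$fixed_threshold),
        blocking = x$blocking,
        input = if (is.null(x$input)) NA_character_ else x$input,
        seed = as.integer(x$seed))
}

#' Write / read a run configuration as YAML
#'
#' The serialisation round-trips: write -> read -> write is idempotent.
#'
#' @param config a \linkS4class{RunConfig}
#' @param path YAML file path
#' @return \code{readRunConfig} returns a \linkS4class{RunConfig};
#'   \code{writeRunConfig} returns the path invisibly
#' @export
writeRunConfig <- function(config, path) {
    stopifnot(is(config, "RunConfig"))
    yaml::write_yaml(.configToList(config), path)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    .listToConfig(yaml::yaml.load_file(path))
}

.simConfigFor <- function(config, transportRow, seed) {
    s <- config@simulation
    scenarioFromTransport(
        transportRow, k0 = s$k0, Fref = s$F_ref,
        fieldWidth = s$fieldWidth, fieldHeight = s$fieldHeight,
        pixelScale = s$pixelScale, hardCoreRadius = s$hardCoreRadius,
        shadow = ShadowModel(isTRUE(s$shadowEnabled), s$shadowLength,
                             s$shadowHalfwidth),
        duration = s$duration, frameInterval = s$frameInterval, seed = seed)
}

.writeMapOutputs <- function(map, outDir, label) {
    mapCsv <- file.path(outDir, paste0("paircorr_", label, ".csv"))
    .writeCsv(as.data.frame(densityMap(map)), mapCsv)
    sidecar <- file.path(outDir, paste0("paircorr_", label, ".json"))
    jsonlite::write_json(
        list(r_max_px = map@rMax, mode = map@mode, n_pairs = map@nPairs,
             n_ref = map@nRef, n_fields = map@nFields,
             normalization = "bins sum to 1 over the disc",
             max_bin = max(densityMap(map))),
        sidecar, auto_unbox = TRUE, digits = NA)
    c(mapCsv, sidecar)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order for the configured input mode and
#' writes CSV/JSON outputs plus a manifest to \code{outDir}:
#' \itemize{
#'   \item \code{simulate}: transport table for every condition, then per
#'     condition a simulated assay, its adhesion series, two-phase fit and
#'     pair-correlation map of the final frame.
#'   \item \code{coordinates}: a coordinates CSV (frame_index, time_s, x_px,
#'     y_px) is analysed for kinetics (when >= 6 frames) and blocking.
#'   \item \code{images}: a frame-manifest CSV (path, time_s) is read,
#'     cells are detected, then kinetics and blocking run on the detections.
#' }
#' All numeric CSV output is written with 6 significant digits so repeated
#' runs with the same seed are byte-identical.
#'
#' @param config a \linkS4class{RunConfig}
#' @param outDir output directory (created if needed)
#' @param seed optional override of the config root seed
#' @return the manifest, invisibly (also written as manifest.json): config
#'   echo, package version, per-stage outputs and wall-clock seconds
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
    stopifnot(is(config, "RunConfig"))
    validObject(config)
    if (!is.null(seed)) config@seed <- as.integer(seed)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(config = .configToList(config),
                     version = as.character(packageVersion("ppfcAdhesion")),
                     stages = list(), timings_s = list())
    stage <- function(name, fun) {
        t0 <- proc.time()[["elapsed"]]
        files <- tryCatch(fun(), error = function(e) {
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
        manifest$stages[[name]] <<- as.list(files)
        manifest$timings_s[[name]] <<- round(
            proc.time()[["elapsed"]] - t0, 3)
    }

    tt <- NULL
    stage("transport", function() {
        conds <- presetFlowConditions(config)
        tt <<- transportTable(conds, config@fluid, config@cell,
                              config@geometry)
        .writeCsv(tt, file.path(outDir, "transport.csv"))
    })

    blk <- config@blocking
    if (config@mode == "simulate") {
        s <- config@simulation
        wPx <- s$fieldWidth / s$pixelScale
        hPx <- s$fieldHeight / s$pixelScale
        fitRows <- list()
        for (k in seq_len(nrow(config@conditions))) {
            label <- config@conditions$label[k]
            stage(paste0("simulate_", label), function() {
                simCfg <- .simConfigFor(config, tt[k, , drop = FALSE],
                                        config@seed + k - 1L)
                field <- simulateAdhesion(simCfg)
                series <- countSeries(field, condition = label)
                seriesCsv <- file.path(outDir,
                                       paste0("series_", label, ".csv"))
                .writeCsv(data.frame(time_s = series@times,
                                     cells_per_cm2 = series@densities),
                          seriesCsv)
                fit <- fitTwoPhase(series)
                fitRows[[label]] <<- data.frame(
                    condition = label, replicate = "1",
                    t_b_min = breakpoint(fit) / 60,
                    s1 = slopes(fit)[["s1"]], s2 = slopes(fit)[["s2"]],
                    reduction_pct = rateReduction(fit),
                    R2_1 = fit@r2[1], R2_2 = fit@r2[2])
                last <- framePositions(field, length(frameTimes(field)))
                pts <- data.frame(x_px = last$x_um / s$pixelScale,
                                  y_px = last$y_um / s$pixelScale,
                                  t = last$attach_s)
                map <- pairCorrelationMap(pts, wPx, hPx, blk$rMax,
                                          blk$mode)
                c(seriesCsv, .writeMapOutputs(map, outDir, label))
            })
        }
        stage("kinetics", function() {
            .writeCsv(do.call(rbind, fitRows),
                      file.path(outDir, "fits.csv"))
        })
    } else if (config@mode == "coordinates") {
        coords <- read.csv(config@input)
        s <- config@simulation
        wPx <- s$fieldWidth / s$pixelScale
        hPx <- s$fieldHeight / s$pixelScale
        if (length(unique(coords$frame_index)) >= 6) {
            stage("kinetics", function() {
                areaCm2 <- wPx * hPx * (s$pixelScale * 1e-4)^2
                perFrame <- aggregate(x_px ~ frame_index + time_s, coords,
                                      length)
                perFrame <- perFrame[order(perFrame$time_s), ]
                series <- AdhesionTimeSeries(perFrame$time_s,
                                             perFrame$x_px / areaCm2,
                                             condition = "coordinates")
                fit <- fitTwoPhase(series)
                .writeCsv(data.frame(condition = "coordinates",
                                     replicate = "1",
                                     t_b_min = breakpoint(fit) / 60,
                                     s1 = slopes(fit)[["s1"]],
                                     s2 = slopes(fit)[["s2"]],
                                     reduction_pct = rateReduction(fit),
                                     R2_1 = fit@r2[1], R2_2 = fit@r2[2]),
                          file.path(outDir, "fits.csv"))
            })
        }
        stage("blocking", function() {
            last <- coords[coords$frame_index == max(coords$frame_index), ]
            pts <- data.frame(x_px = last$x_px, y_px = last$y_px,
                              t = last$time_s)
            if (!is.null(last$t)) pts$t <- last$t
            map <- pairCorrelationMap(pts, wPx, hPx, blk$rMax, blk$mode)
            .writeMapOutputs(map, outDir, "coordinates")
        })
    } else {  # images
        fm <- read.csv(config@input)
        frames <- readFrames(fm$path, fm$time_s,
                             pixelScale = config@simulation$pixelScale)
        series <- NULL
        stage("detect", function() {
            series <<- detectSequence(frames, config@detection)
            .writeCsv(detectCoordinates(frames, config@detection),
                      file.path(outDir, "coordinates.csv"))
        })
        if (length(frames) >= 6) {
            stage("kinetics", function() {
                fit <- fitTwoPhase(series)
                .writeCsv(data.frame(condition = "images", replicate = "1",
                                     t_b_min = breakpoint(fit) / 60,
                                     s1 = slopes(fit)[["s1"]],
                                     s2 = slopes(fit)[["s2"]],
                                     reduction_pct = rateReduction(fit),
                                     R2_1 = fit@r2[1], R2_2 = fit@r2[2]),
                          file.path(outDir, "fits.csv"))
            })
        }
        stage("blocking", function() {
            mx <- findMaxima(frames[[length(frames)]], config@detection)
            nr <- nrow(frames[[length(frames)]]@data)
            nc <- ncol(frames[[length(frames)]]@data)
            map <- pairCorrelationMap(
                data.frame(x_px = mx$x_px, y_px = mx$y_px), nc, nr,
                blk$rMax, "unordered")
            .writeMapOutputs(map, outDir, "images")
        })
    }

    manifestPath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(manifest)
}
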