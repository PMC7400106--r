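# Stochastic adhesion/detachment simulator and the hard-core generators.

test_that("identical seed and config give bit-identical event logs", {
    cfg <- SimulationConfig(duration = 600, detachRate = 1 / 400, seed = 42)
    f1 <- simulateAdhesion(cfg)
    f2 <- simulateAdhesion(cfg)
    expect_identical(eventLog(f1), eventLog(f2))
    expect_identical(adheredCells(f1), adheredCells(f2))
    f3 <- simulateAdhesion(SimulationConfig(duration = 600,
                                            detachRate = 1 / 400, seed = 43))
    expect_false(identical(eventLog(f1), eventLog(f3)))
})

test_that("arrivals follow the homogeneous Poisson mean a*A*T", {
    rate <- 200  # cells/(cm^2.s)
    cfg <- SimulationConfig(fieldWidth = 305, fieldHeight = 305,
                            arrivalRate = rate, duration = 1800,
                            hardCoreRadius = 0, seed = 1)
    areaCm2 <- 305 * 305 * 1e-8
    nSeeds <- 5
    tot <- sum(vapply(seq_len(nSeeds), function(s) {
        cfg@seed <- s
        simulateAdhesion(cfg)@nAttempts
    }, numeric(1)))
    mu <- rate * areaCm2 * 1800 * nSeeds
    expect_lt(abs(tot - mu), 4 * sqrt(mu))
})

test_that("with detachment the count saturates at a*A/k_det", {
    # birth-death closed form: E[N(t)] = (aA/k)(1 - exp(-kt))
    rate <- 500; k <- 1 / 200
    cfg <- SimulationConfig(fieldWidth = 305, fieldHeight = 305,
                            arrivalRate = rate, detachRate = k,
                            duration = 1800, seed = 1)
    areaCm2 <- 305 * 305 * 1e-8
    plateau <- rate * areaCm2 / k    # ~93 cells
    lastCounts <- vapply(1:5, function(s) {
        cfg@seed <- s
        f <- simulateAdhesion(cfg)
        n <- length(frameTimes(f))
        mean(vapply((n - 4):n, function(i) nrow(framePositions(f, i)),
                    numeric(1)))
    }, numeric(1))
    expect_lt(abs(mean(lastCounts) - plateau) / plateau, 0.10)
})

test_that("shadowing strictly reduces the final adhered count", {
    base <- SimulationConfig(fieldWidth = 305, fieldHeight = 305,
                             arrivalRate = 800, duration = 900, seed = 5)
    on <- base
    on@shadow <- ShadowModel(TRUE, length = 50, halfwidth = 5)
    nOff <- nrow(adheredCells(simulateAdhesion(base)))
    nOn <- nrow(adheredCells(simulateAdhesion(on)))
    expect_lt(nOn, nOff)
})

test_that("no frame ever violates the hard-core exclusion", {
    cfg <- SimulationConfig(fieldWidth = 200, fieldHeight = 200,
                            arrivalRate = 3000, detachRate = 1 / 300,
                            hardCoreRadius = 1, duration = 900, seed = 9)
    f <- simulateAdhesion(cfg)
    for (i in seq_along(frameTimes(f))) {
        pos <- framePositions(f, i)
        if (nrow(pos) >= 2) {
            dmin <- min(dist(pos[, c("x_um", "y_um")]))
            expect_gte(dmin, 2 * cfg@hardCoreRadius)
        }
    }
    # frame content is exactly {attach <= t < detach}
    ce <- adheredCells(f)
    t5 <- frameTimes(f)[5]
    expect_setequal(framePositions(f, 5)$cell_id,
                    ce$cell_id[ce$attach_s <= t5 & ce$detach_s > t5])
})

test_that("jamming (most placements rejected) raises a warning", {
    cfg <- SimulationConfig(fieldWidth = 20, fieldHeight = 20,
                            arrivalRate = 5e5, hardCoreRadius = 3,
                            duration = 600, seed = 2)
    expect_warning(simulateAdhesion(cfg), "jamming")
})

test_that("uniform hard-core fields respect the minimum separation", {
    f <- uniformHardCoreField(400, 200, 200, hardCoreRadius = 2, seed = 3)
    expect_identical(nrow(f), 400L)
    expect_gte(min(dist(cbind(f$x_um, f$y_um))), 4)
    expect_true(all(f$x_um >= 0 & f$x_um <= 200))
    # determinism
    expect_identical(f, uniformHardCoreField(400, 200, 200, 2, seed = 3))
})

test_that("transport-bound scenarios inherit the SL flux and scale k_det", {
    preset <- flowCellPreset()
    tt <- transportTable(presetFlowConditions(preset), preset@fluid,
                         preset@cell, preset@geometry)
    c1 <- scenarioFromTransport(tt[1, ], k0 = 1 / 600, Fref = tt$drag_N[1])
    c6 <- scenarioFromTransport(tt[6, ], k0 = 1 / 600, Fref = tt$drag_N[1])
    expect_equal(c1@arrivalRate, tt$SL_cells_cm2_s[1])
    expect_equal(round(c1@arrivalRate, -1), 80)
    expect_gt(c6@arrivalRate, c1@arrivalRate)
    expect_gt(c6@detachRate, c1@detachRate)
    expect_identical(scenarioFromTransport(tt[1, ], k0 = 0)@detachRate, 0)
})

test_that("countSeries reports the ground-truth density per frame", {
    cfg <- SimulationConfig(fieldWidth = 305, fieldHeight = 305,
                            arrivalRate = 300, detachRate = 1 / 500,
                            duration = 900, seed = 4)
    f <- simulateAdhesion(cfg)
    s <- countSeries(f)
    areaCm2 <- 305 * 305 * 1e-8
    manual <- vapply(seq_along(frameTimes(f)), function(i) {
        nrow(framePositions(f, i)) / areaCm2
    }, numeric(1))
    expect_equal(s@densities, manual)
    expect_identical(s@times, frameTimes(f))
})

test_that("simulation config validity rejects inconsistent settings", {
    expect_error(SimulationConfig(arrivalRate = -1), "arrivalRate")
    expect_error(SimulationConfig(duration = 10, frameInterval = 60),
                 "duration")
    expect_error(SimulationConfig(pixelScale = 0), "pixelScale")
})
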