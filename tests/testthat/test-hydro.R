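# Closed-form transport, force and geometry relations.

geomDefault <- ChannelGeometry(width = 0.016, height = 0.008,
                               length = 0.2542, axialPosition = 0.1271)
fluidDefault <- FluidProperties(993.37, 0.000694, 4.0e-13, 7.6e13)
cellDefault <- CellMorphology(radius = 4.5e-7)

test_that("average velocity is Q/(w h0) and exactly linear in Q", {
    expect_equal(averageVelocity(1e-6, geomDefault), 7.8125e-3)
    expect_equal(averageVelocity(1e-5, geomDefault), 7.8125e-2)
    expect_identical(averageVelocity(2e-6, geomDefault),
                     2 * averageVelocity(1e-6, geomDefault))
    expect_error(averageVelocity(-1e-6, geomDefault), "invalid parameter")
})

test_that("analytic slot shear rate is 6Q/(w h0^2) and linear", {
    expect_equal(analyticShearRate(1e-6, geomDefault), 5.859375)
    expect_equal(analyticShearRate(0.5e-6, geomDefault), 5.859375 / 2)
    expect_equal(analyticShearRate(1e-5, geomDefault), 58.59375)
})

test_that("equivalent rod radius obeys its formula and its domain", {
    expect_equal(microbialRadius(2e-6, 1e-6),
                 (2e-6 / 2) / (log(2) - 0.11), tolerance = 1e-12)
    expect_equal(microbialRadius(2e-6, 1e-6), 1.715e-6, tolerance = 1e-3)
    # ln(L/b) - 0.11 = 1 when L/b = e^1.11, so R_b = L/2
    L <- 3e-6
    expect_equal(microbialRadius(L, L / exp(1.11)), L / 2)
    expect_error(microbialRadius(1e-6, 1e-6), "L/b > exp\\(0.11\\)")
})

test_that("Peclet number matches its formula and vanishes with velocity", {
    Pe <- pecletNumber(7.8125e-3, 4.5e-7, 0.008, 4.0e-13)
    expect_equal(Pe, 1.6685e-4, tolerance = 1e-4)
    expect_identical(pecletNumber(0, 4.5e-7, 0.008, 4.0e-13), 0)
    expect_equal(pecletNumber(7.8125e-2, 4.5e-7, 0.008, 4.0e-13), 10 * Pe)
})

test_that("SL deposition flux reproduces the 80-170 cells/cm^2.s range", {
    Pe1 <- pecletNumber(averageVelocity(1e-6, geomDefault), 4.5e-7, 0.008,
                        4.0e-13)
    sl1 <- slDepositionRate(fluidDefault, 4.5e-7, Pe1, geomDefault)
    sl10 <- slDepositionRate(fluidDefault, 4.5e-7, 10 * Pe1, geomDefault)
    expect_equal(round(sl1, -1), 80)
    expect_equal(round(sl10, -1), 170)
    expect_equal(sl1, 79.6, tolerance = 1e-2)
    expect_equal(sl10, 171.5, tolerance = 1e-2)
    expect_identical(slDepositionRate(fluidDefault, 4.5e-7, 0, geomDefault),
                     0)
})

test_that("drag force and local Reynolds number are exact and linear", {
    expect_equal(dragForce(0.000694 * 7.5, 4.5e-7), 3.373e-14,
                 tolerance = 1e-3)
    expect_equal(dragForce(0.000694 * 100.8, 4.5e-7), 4.533e-13,
                 tolerance = 1e-3)
    expect_identical(dragForce(0, 4.5e-7), 0)
    expect_identical(dragForce(2 * 0.05, 4.5e-7), 2 * dragForce(0.05, 4.5e-7))
    expect_equal(localReynolds(993.37, 100.8, 4.5e-7, 0.000694), 2.922e-5,
                 tolerance = 1e-3)
    expect_identical(localReynolds(993.37, 0, 4.5e-7, 0.000694), 0)
    expect_identical(localReynolds(993.37, 2 * 50, 4.5e-7, 0.000694),
                     2 * localReynolds(993.37, 50, 4.5e-7, 0.000694))
})

test_that("unit round-trip: SI and CGS evaluations of the SL flux agree", {
    Pe <- pecletNumber(7.8125e-3, 4.5e-7, 0.008, 4.0e-13)
    si <- slDepositionRate(fluidDefault, 4.5e-7, Pe, geomDefault)
    # direct evaluation with lengths in cm and concentration in cells/cm^3
    cgs <- 0.538 * (4.0e-13 * 1e4) * (7.6e13 * 1e-6) / (4.5e-7 * 1e2) *
        (Pe * (0.008 * 1e2) / (0.1271 * 1e2))^(1 / 3)
    expect_equal(si, cgs, tolerance = 1e-12)
})

test_that("FlowCondition completes shear consistently", {
    fcA <- FlowCondition(1e-6, geomDefault, fluidDefault)
    expect_identical(fcA@shearSource, "analytic")
    expect_identical(fcA@wallShearStress, 0.000694 * fcA@shearRate)
    fcS <- FlowCondition(1e-6, geomDefault, fluidDefault, shearRate = 7.5)
    expect_identical(fcS@shearSource, "supplied")
    expect_equal(fcS@wallShearStress, 0.000694 * 7.5)
    fcT <- FlowCondition(1e-6, geomDefault, fluidDefault,
                         wallShearStress = 0.01)
    expect_equal(fcT@shearRate, 0.01 / 0.000694)
})

test_that("transport table is monotone in Q with the cube-root SL law", {
    Q <- c(1, 2, 4, 6, 8, 10) * 1e-6
    conds <- lapply(Q, FlowCondition, geom = geomDefault,
                    fluid = fluidDefault)
    tt <- transportTable(conds, fluidDefault, cellDefault, geomDefault)
    expect_identical(nrow(tt), 6L)
    expect_true(all(diff(tt$SL_cells_cm2_s) > 0))
    expect_true(all(diff(tt$drag_N) > 0))
    # SL(Q2)/SL(Q1) = (Q2/Q1)^(1/3) when only Q varies
    expect_equal(tt$SL_cells_cm2_s / tt$SL_cells_cm2_s[1],
                 (Q / Q[1])^(1 / 3), tolerance = 1e-12)
    one <- transportTable(conds[1], fluidDefault, cellDefault, geomDefault)
    expect_identical(nrow(one), 1L)
})

test_that("transport table errors carry the condition index", {
    conds <- list(FlowCondition(1e-6, geomDefault, fluidDefault), "junk")
    expect_error(
        transportTable(conds, fluidDefault, cellDefault, geomDefault),
        "condition 2")
})

test_that("geometry and fluid validity rules reject bad inputs", {
    expect_error(ChannelGeometry(0.016, 0.02, 0.25), "height")
    expect_error(ChannelGeometry(0.016, 0.008, 0.25, axialPosition = 0.3),
                 "axialPosition")
    expect_error(ChannelGeometry(-1, 0.008, 0.25), "> 0")
    expect_error(FluidProperties(0, 1, 1, 1), "> 0")
    expect_error(CellMorphology(radius = -1), "R_b")
})
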