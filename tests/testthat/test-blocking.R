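# Pair-correlation probability-density maps and the anisotropy test.

# shared non-blocking fixture: 3 pooled hard-core fields at ~1e6 cells/cm^2
uniformFields <- hardCoreFieldsPx(3, 3721, 1000, seed = 50)
uniformMap <- pairCorrelationMap(uniformFields, 1000, 1000, rMax = 50)

test_that("a two-point field produces two mirrored bins of mass 0.5", {
    pts <- data.frame(x_px = c(60, 70), y_px = c(60, 60))
    m <- pairCorrelationMap(pts, 130, 130, rMax = 50)
    d <- densityMap(m)
    expect_equal(sum(d), 1)
    expect_equal(d["0", "10"], 0.5)
    expect_equal(d["0", "-10"], 0.5)
    expect_identical(sum(d > 0), 2L)
})

test_that("the grid implementation matches the brute-force oracle bit-exactly", {
    set.seed(61)
    for (case in 1:3) {
        n <- c(60, 150, 200)[case]
        fields <- lapply(1:2, function(k) {
            data.frame(x_px = runif(n, 0, 300), y_px = runif(n, 0, 300),
                       t = sample(n))
        })
        for (mode in c("unordered", "time_ordered")) {
            m <- pairCorrelationMap(fields, 300, 300, rMax = 50,
                                    mode = mode)
            oracle <- bruteForceMapCounts(fields, 300, 300, 50, mode)
            expect_identical(unname(m@counts), oracle)
        }
    }
})

test_that("unordered maps are exactly centro-symmetric", {
    d <- densityMap(uniformMap)
    expect_identical(d, d[nrow(d):1, ncol(d):1, drop = FALSE],
                     ignore_attr = TRUE)
    expect_identical(unname(uniformMap@counts),
                     unname(uniformMap@counts[101:1, 101:1]))
})

test_that("normalisation and disc support are exact", {
    expect_equal(sum(densityMap(uniformMap)), 1)
    offs <- -50:50
    outside <- sqrt(outer(offs^2, offs^2, "+")) > 50
    expect_true(all(densityMap(uniformMap)[outside] == 0))
    expect_identical(densityMap(uniformMap)["0", "0"], 0)
    # time-ordered mode still sums to 1 but need not be symmetric
    mT <- pairCorrelationMap(uniformFields, 1000, 1000, 50,
                             mode = "time_ordered")
    expect_equal(sum(densityMap(mT)), 1)
    # time-ordering keeps about a quarter of the symmetrised entries
    expect_lt(abs(mT@nPairs - uniformMap@nPairs / 4) / uniformMap@nPairs,
              0.05)
})

test_that("uniform hard-core fields give a flat map at 1/(pi rMax^2)", {
    level <- 1 / (pi * 50^2)
    d <- densityMap(uniformMap)
    offs <- -50:50
    r <- sqrt(outer(offs^2, offs^2, "+"))
    ring <- r > 3 & r <= 50   # beyond the hard-core ring
    expect_lt(abs(mean(d[ring]) - level) / level, 0.05)
    expect_lt(max(d), 4.0e-4)
    prof <- radialProfile(uniformMap, ringWidth = 2)
    outer_rings <- prof[prof$r_inner >= 4, ]
    # every ring within 3 standard errors of the uniform level; the factor 4
    # accounts for each unique pair feeding all four mirror entries of a ring
    se <- sqrt(4 * level / (uniformMap@nPairs * outer_rings$n_bins))
    expect_true(all(abs(outer_rings$mean_density - level) <= 3 * se))
    # innermost rings are hard-core depleted
    inner <- prof$mean_density[prof$r_inner == 0]
    expect_lt(inner, level / 2)
})

test_that("radial profile of a single pair occupies exactly one ring", {
    pts <- data.frame(x_px = c(60, 70), y_px = c(60, 60))
    m <- pairCorrelationMap(pts, 130, 130, rMax = 50)
    prof <- radialProfile(m, ringWidth = 1)
    expect_identical(sum(prof$mean_density > 0), 1L)
    expect_error(radialProfile(m, ringWidth = 0.5), "ringWidth")
})

test_that("the depletion index is ~1 for uniform data and 0 for an empty cone", {
    res <- flowAxisDepletionIndex(uniformMap, theta = 30, rS = 50)
    expect_gt(res@index, 0.9)
    expect_lt(res@index, 1.1)
    # zero out both cones: index must be exactly 0
    zeroed <- uniformMap
    offs <- -50:50
    dx <- matrix(offs, 101, 101, byrow = TRUE)
    dy <- matrix(offs, 101, 101)
    ang <- atan2(abs(dy), dx) * 180 / pi
    cone <- (ang <= 30 | ang >= 150) & sqrt(dx^2 + dy^2) > 0
    zeroed@density[cone] <- 0
    zeroed@density <- zeroed@density / sum(zeroed@density)
    expect_identical(flowAxisDepletionIndex(zeroed, 30, 50)@index, 0)
})

test_that("a simulated downstream shadow depresses the time-ordered index", {
    cfg <- SimulationConfig(fieldWidth = 305, fieldHeight = 305,
                            arrivalRate = 1000, duration = 1000,
                            shadow = ShadowModel(TRUE), seed = 71)
    flds <- simulateFields(cfg, 4)
    pts <- do.call(rbind, lapply(seq_along(flds), function(k) {
        ce <- adheredCells(flds[[k]])
        data.frame(field = k, x_px = ce$x_um / 0.61, y_px = ce$y_um / 0.61,
                   t = ce$attach_s)
    }))
    m <- pairCorrelationMap(pts, 500, 500, 50, mode = "time_ordered")
    res <- flowAxisDepletionIndex(m, theta = 30, rS = 23)
    expect_lt(res@index, 1)
})

test_that("the permutation p-value follows its counting formula", {
    cfg <- SimulationConfig(fieldWidth = 305, fieldHeight = 305,
                            arrivalRate = 1000, duration = 1200,
                            shadow = ShadowModel(TRUE, length = 30,
                                                 halfwidth = 2),
                            seed = 81)
    flds <- simulateFields(cfg, 4)
    pts <- do.call(rbind, lapply(seq_along(flds), function(k) {
        ce <- adheredCells(flds[[k]])
        data.frame(field = k, x_px = ce$x_um / 0.61, y_px = ce$y_um / 0.61,
                   t = ce$attach_s)
    }))
    res <- anisotropyTest(pts, 500, 500, 50, mode = "time_ordered",
                          rS = 49, nPerm = 99, seed = 5)
    # blocking this strong beats every rotated null: p = 1/(nPerm + 1)
    expect_lt(res@index, 1)
    expect_identical(res@pValue, 1 / 100)
    expect_identical(res@nPerm, 99L)
    expect_identical(length(res@nullIndices), 99L)
})

test_that("errors and caveats fire on degenerate inputs", {
    pts <- data.frame(x_px = c(60, 70), y_px = c(60, 60))
    expect_error(pairCorrelationMap(pts, 1000, 1000, 50,
                                    borderMargin = 500),
                 "no reference cells")
    expect_error(pairCorrelationMap(data.frame(x_px = 1, y_px = 1),
                                    100, 100, 50), "at least 2 points")
    expect_error(pairCorrelationMap(pts, 130, 130, 50,
                                    mode = "time_ordered"), "'t' column")
    expect_error(anisotropyTest(pts, 130, 130, 50, nPerm = 50),
                 "nPerm")
    expect_warning(
        anisotropyTest(pts, 130, 130, 50, mode = "unordered", seed = 1),
        "fewer than 50 pairs")
    expect_error(flowAxisDepletionIndex(uniformMap, theta = 30, rS = 0.5),
                 "rS|zero pair mass")
})
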