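# Prominence-based maxima detection and covered-area estimation.

test_that("a uniform image has no maxima and a degenerate area fraction", {
    fr <- ImageFrame(matrix(200, 64, 64))
    expect_identical(nrow(findMaxima(fr)), 0L)
    expect_warning(af <- areaFraction(fr), "degenerate")
    expect_identical(af, 0)
})

test_that("a single noiseless cell yields one maximum at its centre", {
    fr <- renderFrame(data.frame(x_um = 30.5, y_um = 30.5), 61, 61,
                      noiseSd = 0)
    mx <- findMaxima(fr, DetectionParams(smoothSigma = 0))
    expect_identical(nrow(mx), 1L)
    expect_identical(c(mx$x_px, mx$y_px), c(50, 50))
    # the centre pixel is the global intensity minimum of the frame
    expect_identical(unname(which(fr@data == min(fr@data), arr.ind = TRUE)[1, ]),
                     c(51L, 51L))
})

test_that("detection is invariant to intensity offsets and equivariant to flips", {
    pos <- uniformHardCoreField(40, 120, 120, 2, seed = 11)
    fr <- renderFrame(pos, 120, 120, noiseSd = 0)
    par <- DetectionParams(smoothSigma = 0)
    base <- findMaxima(fr, par)
    shifted <- ImageFrame(fr@data - 30, fr@pixelScale)
    mxS <- findMaxima(shifted, par)
    expect_identical(base[, c("x_px", "y_px")], mxS[, c("x_px", "y_px")])
    flipped <- ImageFrame(fr@data[nrow(fr@data):1, ], fr@pixelScale)
    mxF <- findMaxima(flipped, par)
    expect_setequal(mxF$y_px, nrow(fr@data) - 1 - base$y_px)
    expect_setequal(mxF$x_px, base$x_px)
})

test_that("constant plateaus report their centroid pixel", {
    m <- matrix(0, 21, 21)
    m[9:11, 9:11] <- 50          # 3x3 plateau centred at row/col 10 (1-based)
    fr <- ImageFrame(255 - m)    # dark square on light background
    mx <- findMaxima(fr, DetectionParams(noiseTolerance = 10,
                                         smoothSigma = 0))
    expect_identical(nrow(mx), 1L)
    expect_identical(c(mx$x_px, mx$y_px), c(9, 9))  # 0-based centroid
})

test_that("close maxima are suppressed keeping the brighter", {
    m <- matrix(200, 31, 31)
    m[15, 15] <- 100             # deeper (brighter after inversion)
    m[15, 17] <- 140             # 2 px away, shallower
    m[15, 25] <- 150             # far away, kept
    fr <- ImageFrame(m)
    mx <- findMaxima(fr, DetectionParams(noiseTolerance = 5,
                                         minSeparation = 3,
                                         smoothSigma = 0))
    expect_identical(nrow(mx), 2L)
    expect_true(all(c(14, 24) %in% mx$x_px))
    expect_false(16 %in% mx$x_px)
})

test_that("rendered fields at SNR >= 5 are recovered almost perfectly", {
    pos <- uniformHardCoreField(100, 312, 312, 2, seed = 21)
    fr <- renderFrame(pos, 312, 312, noiseSd = 12, amplitude = 60,
                      seed = 22)
    mx <- findMaxima(fr)
    m <- matchDetections(mx, pos)
    expect_gte(m$recall, 95)
    expect_lte(m$falsePos, 5)
})

test_that("detected counts are an unbiased density estimate over seeds", {
    relErr <- vapply(1:20, function(s) {
        pos <- uniformHardCoreField(100, 312, 312, 2, seed = 100 + s)
        fr <- renderFrame(pos, 312, 312, noiseSd = 12, seed = 200 + s)
        (nrow(findMaxima(fr)) - 100) / 100
    }, numeric(1))
    expect_lt(abs(mean(relErr)), 0.03)
})

test_that("area fraction handles binary, complementary and dense frames", {
    m <- matrix(0, 50, 50); m[, 1:25] <- 255
    par0 <- DetectionParams(smoothSigma = 0)
    expect_equal(areaFraction(ImageFrame(m), par0), 50)
    # Otsu on an image and its photographic negative gives complementary
    # fractions (up to pixels exactly at the threshold)
    pos <- uniformHardCoreField(60, 120, 120, 2, seed = 31)
    fr <- renderFrame(pos, 120, 120, noiseSd = 0)
    a <- areaFraction(ImageFrame(fr@data), par0)
    b <- areaFraction(ImageFrame(255 - fr@data), par0)
    npx <- length(fr@data)
    expect_lte(abs((a + b) - 100), 100 / npx + 1e-9)
    # a field at 1e6 cells/cm^2 renders to a low covered fraction
    dense <- uniformHardCoreField(3721, 610, 610, 0.5, seed = 7)
    frD <- renderFrame(dense, 610, 610, noiseSd = 12, seed = 8)
    afD <- areaFraction(frD)
    expect_gt(afD, 0)
    expect_lt(afD, 10)
    # fixed threshold path
    expect_equal(areaFraction(ImageFrame(m),
                              DetectionParams(smoothSigma = 0,
                                              areaThresholdMethod = "fixed",
                                              fixedThreshold = 128)), 50)
})

test_that("frame sequences become density series matching ground truth", {
    cfg <- SimulationConfig(fieldWidth = 200, fieldHeight = 200,
                            arrivalRate = 2000, duration = 360,
                            frameInterval = 60, seed = 13)
    f <- simulateAdhesion(cfg)
    frames <- renderField(f, noiseSd = 0)
    s <- detectSequence(frames, DetectionParams(smoothSigma = 0))
    truth <- countSeries(f)
    expect_identical(s@times, truth@times)
    nz <- truth@densities > 0
    expect_true(all(abs(s@densities[nz] - truth@densities[nz]) /
                    truth@densities[nz] <= 0.05))
    # single frame and empty input
    s1 <- detectSequence(frames[1])
    expect_identical(length(s1@times), 1L)
    expect_error(detectSequence(list()), "empty")
    # unordered timestamps name the offending index
    bad <- list(frames[[2]], frames[[1]], frames[[3]])
    expect_error(detectSequence(bad), "index 2")
})

test_that("border maxima are flagged but still counted", {
    m <- matrix(200, 41, 41)
    m[2, 2] <- 80; m[20, 20] <- 80
    mx <- findMaxima(ImageFrame(m), DetectionParams(smoothSigma = 0))
    expect_identical(nrow(mx), 2L)
    expect_identical(sum(mx$border), 1L)
})
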