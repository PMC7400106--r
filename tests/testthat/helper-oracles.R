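# Independent oracles and fixture builders used across the suite.

# Brute-force O(n^2) pair-correlation counts: the reference the grid-indexed
# implementation must reproduce bit-exactly.
bruteForceMapCounts <- function(fields, fieldWidth, fieldHeight, rMax,
                                mode = "unordered", margin = rMax) {
    if (is.data.frame(fields)) fields <- list(fields)
    side <- 2 * rMax + 1
    counts <- matrix(0L, side, side)
    for (f in fields) {
        n <- nrow(f)
        ref <- f$x_px >= margin & f$x_px <= fieldWidth - margin &
               f$y_px >= margin & f$y_px <= fieldHeight - margin
        for (i in seq_len(n)) {
            if (!ref[i]) next
            for (j in seq_len(n)) {
                if (j == i) next
                if (mode == "time_ordered" && !(f$t[j] > f$t[i])) next
                bdx <- round(f$x_px[j] - f$x_px[i])
                bdy <- round(f$y_px[j] - f$y_px[i])
                rr <- bdx^2 + bdy^2
                if (rr == 0 || rr > rMax^2) next
                counts[bdy + rMax + 1, bdx + rMax + 1] <-
                    counts[bdy + rMax + 1, bdx + rMax + 1] + 1L
                if (mode == "unordered") {
                    # directionless displacement: mirror entry
                    counts[-bdy + rMax + 1, -bdx + rMax + 1] <-
                        counts[-bdy + rMax + 1, -bdx + rMax + 1] + 1L
                }
            }
        }
    }
    counts
}

# Match detections (px) against ground-truth positions (um -> px); returns
# recall and false-positive counts at the given pixel tolerance.
matchDetections <- function(maxima, truth, pixelScale = 0.61, tol = 2) {
    tx <- truth$x_um / pixelScale
    ty <- truth$y_um / pixelScale
    d <- sqrt(outer(maxima$x_px, tx, "-")^2 + outer(maxima$y_px, ty, "-")^2)
    list(recall = sum(apply(d, 2, min) <= tol),
         falsePos = sum(apply(d, 1, min) > tol))
}

# Noise-free piecewise-linear adhesion series: slopes in cells/(cm^2.min),
# breakpoint in minutes, sampled every dt seconds.
makeTwoPhaseSeries <- function(s1, s2, tbMin, dt = 60, total = 1800,
                               noiseSd = 0, seed = 1) {
    t <- seq(dt, total, by = dt)
    tb <- tbMin * 60
    d <- ifelse(t <= tb, s1 * t / 60,
                s1 * tbMin + s2 * (t - tb) / 60)
    if (noiseSd > 0) {
        set.seed(seed)
        d <- pmax(0, d + rnorm(length(d), 0, noiseSd))
    }
    AdhesionTimeSeries(t, d)
}

# Hard-core point fields in pixel coordinates, one data.frame per field.
hardCoreFieldsPx <- function(nFields, nPoints, sidePx, pixelScale = 0.61,
                             hardCoreRadius = 0.5, seed = 1) {
    lapply(seq_len(nFields), function(k) {
        f <- uniformHardCoreField(nPoints, sidePx * pixelScale,
                                  sidePx * pixelScale, hardCoreRadius,
                                  seed = seed + k - 1)
        data.frame(x_px = f$x_um / pixelScale, y_px = f$y_um / pixelScale,
                   t = f$t)
    })
}
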