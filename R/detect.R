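## Detection of adhered cells in grayscale frames: image inversion followed
## by prominence-based local-maxima finding (the ImageJ "find maxima with
## noise tolerance" idea, implemented as topological persistence), plus
## covered-area thresholding.

#' Detect cells as intensity maxima
#'
#' The frame is inverted (cells appear dark in brightfield, so they become
#' bright peaks), optionally smoothed with a small Gaussian, and local maxima
#' with prominence at least \code{noiseTolerance} are reported. Maxima closer
#' than \code{minSeparation} px are suppressed keeping the brighter one (ties
#' keep the smaller row-major pixel index). Constant plateaus report their
#' centroid pixel. Coordinates are 0-based with x = column and y = row,
#' origin at the top-left.
#'
#' Prominence-based detection is invariant under a global intensity offset;
#' a uniform image yields no maxima.
#'
#' @param frame an \linkS4class{ImageFrame}
#' @param params a \linkS4class{DetectionParams}
#' @return data.frame(x_px, y_px, value, prominence, border) sorted by
#'   decreasing inverted intensity; \code{border} flags maxima within
#'   \code{minSeparation} of the field edge. Attributes \code{count} and
#'   \code{density} (cells/cm^2) summarise the detection.
#' @export
findMaxima <- function(frame, params = DetectionParams()) {
    stopifnot(is(frame, "ImageFrame"), is(params, "DetectionParams"))
    inv <- 255 - frame@data
    if (params@smoothSigma > 0)
        inv <- EBImage::gblur(inv, sigma = params@smoothSigma)
    mx <- cpp_find_maxima(inv, params@noiseTolerance)
    if (nrow(mx)) {
        # order by decreasing value, ties by row-major index
        ord <- order(-mx$value, mx$y * ncol(frame@data) + mx$x)
        mx <- mx[ord, , drop = FALSE]
        keep <- logical(nrow(mx))
        minSep2 <- params@minSeparation^2
        for (k in seq_len(nrow(mx))) {
            prev <- which(keep)
            d2 <- (mx$x[prev] - mx$x[k])^2 + (mx$y[prev] - mx$y[k])^2
            keep[k] <- !any(d2 < minSep2)
        }
        mx <- mx[keep, , drop = FALSE]
    }
    nr <- nrow(frame@data); nc <- ncol(frame@data)
    out <- data.frame(x_px = mx$x, y_px = mx$y, value = mx$value,
                      prominence = mx$prominence)
    out$border <- out$x_px < params@minSeparation |
        out$y_px < params@minSeparation |
        out$x_px > nc - 1 - params@minSeparation |
        out$y_px > nr - 1 - params@minSeparation
    rownames(out) <- NULL
    areaCm2 <- nr * nc * (frame@pixelScale * 1e-4)^2
    attr(out, "count") <- nrow(out)
    attr(out, "density") <- nrow(out) / areaCm2
    out
}

#' Covered-area fraction of a frame
#'
#' The frame is inverted, smoothed with the same Gaussian as the maxima
#' detector (suppressing pixel noise that would otherwise dominate an Otsu
#' split of a mostly-background frame) and thresholded (Otsu by default);
#' the fraction of pixels on the bright (cell) side of the threshold is
#' reported in percent.
#'
#' @param frame an \linkS4class{ImageFrame}
#' @param params a \linkS4class{DetectionParams}
#' @return covered-area percentage
#' @export
areaFraction <- function(frame, params = DetectionParams()) {
    stopifnot(is(frame, "ImageFrame"), is(params, "DetectionParams"))
    inv <- 255 - frame@data
    if (params@smoothSigma > 0 && diff(range(inv)) > 0) {
        inv <- EBImage::gblur(inv, sigma = params@smoothSigma)
        inv[] <- pmin(255, pmax(0, inv))
    }
    if (diff(range(inv)) == 0) {
        if (params@areaThresholdMethod == "otsu") {
            warning("degenerate single-intensity image; area fraction 0",
                    call. = FALSE)
            return(0)
        }
        return(100 * mean(inv > params@fixedThreshold))
    }
    thr <- if (params@areaThresholdMethod == "otsu")
        255 * EBImage::otsu(inv / 255, range = c(0, 1), levels = 256L)
    else params@fixedThreshold
    100 * mean(inv > thr)
}

#' Detect a time-ordered frame sequence
#'
#' Runs \code{\link{findMaxima}} on every frame and assembles the adhered
#' cell density (cells/cm^2) versus time.
#'
#' @param frames non-empty list of \linkS4class{ImageFrame}, time-ordered
#' @param params a \linkS4class{DetectionParams}
#' @param condition,replicate labels for the series
#' @return an \linkS4class{AdhesionTimeSeries}
#' @export
detectSequence <- function(frames, params = DetectionParams(),
                           condition = "images", replicate = "1") {
    if (length(frames) == 0) stop("empty frame list", call. = FALSE)
    times <- vapply(frames, function(f) f@timestamp, numeric(1))
    if (length(times) > 1) {
        bad <- which(diff(times) <= 0)
        if (length(bad))
            stop("frame timestamps not strictly increasing at index ",
                 bad[1] + 1, call. = FALSE)
    }
    dens <- vapply(frames, function(f) {
        attr(findMaxima(f, params), "density")
    }, numeric(1))
    AdhesionTimeSeries(times, dens, condition, replicate)
}

#' Detected coordinates of a frame sequence as a table
#'
#' Convenience wrapper pooling \code{\link{findMaxima}} results with frame
#' indices and times, matching the coordinates CSV layout.
#'
#' @inheritParams detectSequence
#' @return data.frame(frame_index, time_s, x_px, y_px)
#' @export
detectCoordinates <- function(frames, params = DetectionParams()) {
    if (length(frames) == 0) stop("empty frame list", call. = FALSE)
    do.call(rbind, lapply(seq_along(frames), function(i) {
        mx <- findMaxima(frames[[i]], params)
        if (nrow(mx) == 0)
            return(data.frame(frame_index = integer(0), time_s = numeric(0),
                              x_px = numeric(0), y_px = numeric(0)))
        data.frame(frame_index = i, time_s = frames[[i]]@timestamp,
                   x_px = mx$x_px, y_px = mx$y_px)
    }))
}
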