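## Brightfield-like rendering of point fields and image I/O.

#' Render a point field as a brightfield-like frame
#'
#' Each cell is drawn as a dark Gaussian blob of the given amplitude on a
#' light background, optional seeded Gaussian noise is added, and intensities
#' are clipped to [0, 255] and rounded to 8-bit levels.
#'
#' @param positions data.frame with columns x_um, y_um (positions inside the
#'   field)
#' @param width,height field size (um)
#' @param pixelScale um per pixel
#' @param psfSigma blob standard deviation (um); defaults to 0.7 um, the
#'   effective optical blur for a micron-sized cell
#' @param amplitude blob depth below background (intensity units)
#' @param background background level (intensity units)
#' @param noiseSd Gaussian noise standard deviation; 0 disables
#' @param timestamp frame time (s)
#' @param seed seed for the noise (ignored when \code{noiseSd = 0})
#' @return an \linkS4class{ImageFrame}
#' @examples
#' pts <- data.frame(x_um = 30, y_um = 30)
#' fr <- renderFrame(pts, 61, 61, noiseSd = 0)
#' which(fr@data == min(fr@data), arr.ind = TRUE)  # blob at the centre
#' @export
renderFrame <- function(positions, width, height, pixelScale = 0.61,
                        psfSigma = 0.7, amplitude = 60, background = 200,
                        noiseSd = 0, timestamp = 0, seed = 1L) {
    if (pixelScale <= 0)
        stop("invalid parameter: pixelScale must be > 0", call. = FALSE)
    nc <- max(1L, round(width / pixelScale))
    nr <- max(1L, round(height / pixelScale))
    if (nrow(positions) > 0 &&
        (any(positions$x_um < 0 | positions$x_um > width) ||
         any(positions$y_um < 0 | positions$y_um > height)))
        stop("positions must lie inside the field", call. = FALSE)
    img <- matrix(background, nrow = nr, ncol = nc)
    sig <- psfSigma / pixelScale     # px
    half <- ceiling(4 * sig)
    for (k in seq_len(nrow(positions))) {
        cx <- positions$x_um[k] / pixelScale  # 0-based px coordinates
        cy <- positions$y_um[k] / pixelScale
        c0 <- max(0L, floor(cx - half)); c1 <- min(nc - 1L, ceiling(cx + half))
        r0 <- max(0L, floor(cy - half)); r1 <- min(nr - 1L, ceiling(cy + half))
        if (c0 > c1 || r0 > r1) next
        cols <- c0:c1; rows <- r0:r1
        blob <- amplitude *
            exp(-outer((rows - cy)^2, (cols - cx)^2, "+") / (2 * sig^2))
        img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] - blob
    }
    if (noiseSd > 0)
        img <- img + .withSeed(seed, matrix(rnorm(nr * nc, 0, noiseSd), nr))
    img[] <- round(pmin(255, pmax(0, img)))
    ImageFrame(img, pixelScale = pixelScale, timestamp = timestamp)
}

#' Render all frames of a simulated field
#'
#' @param field a \linkS4class{SimulatedField}
#' @param ... passed to \code{\link{renderFrame}} (psfSigma, amplitude,
#'   background, noiseSd). Noise seeds are split per frame from the
#'   simulation seed.
#' @return list of \linkS4class{ImageFrame}, one per frame time
#' @export
renderField <- function(field, ...) {
    stopifnot(is(field, "SimulatedField"))
    cfg <- field@config
    lapply(seq_along(field@frameTimes), function(i) {
        renderFrame(framePositions(field, i), cfg@fieldWidth,
                    cfg@fieldHeight, pixelScale = cfg@pixelScale,
                    timestamp = field@frameTimes[i],
                    seed = cfg@seed * 1000L + i, ...)
    })
}

#' Read grayscale frames from image files
#'
#' Reads 8-bit grayscale TIFF or PNG frames (16-bit input is linearly
#' rescaled to 8-bit with a message). Multi-channel images are averaged to
#' grayscale.
#'
#' @param paths image file paths, in time order
#' @param times frame timestamps (s); defaults to 60 s spacing
#' @param pixelScale um per pixel
#' @return list of \linkS4class{ImageFrame}
#' @export
readFrames <- function(paths, times = 60 * seq_along(paths) ,
                       pixelScale = 0.61) {
    stopifnot(length(paths) == length(times))
    lapply(seq_along(paths), function(i) {
        img <- EBImage::readImage(paths[i])
        m <- EBImage::imageData(img)
        if (length(dim(m)) == 3) m <- apply(m, c(1, 2), mean)
        # EBImage stores x as rows; transpose to row = y convention
        m <- t(m)
        if (max(m) > 1) {
            message("rescaling 16-bit frame to 8-bit: ", paths[i])
            m <- m / max(m)
        }
        ImageFrame(round(m * 255), pixelScale = pixelScale,
                   timestamp = times[i])
    })
}

#' Write frames as 8-bit TIFF files
#'
#' @param frames list of \linkS4class{ImageFrame}
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisibly, the written paths
#' @export
writeFrames <- function(frames, dir, prefix = "frame") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(seq_along(frames), function(i) {
        p <- file.path(dir, sprintf("%s_%04d.tif", prefix, i))
        EBImage::writeImage(EBImage::Image(t(frames[[i]]@data) / 255), p,
                            type = "tiff", bits.per.sample = 8L)
        p
    }, character(1))
    invisible(paths)
}
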