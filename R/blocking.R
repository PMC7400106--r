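## 2D pair-correlation probability-density maps and the flow-axis
## anisotropy (hydrodynamic blocking) test.

.asFieldList <- function(points) {
    if (is.data.frame(points)) {
        if ("field" %in% names(points))
            points <- split(points, points$field)
        else points <- list(points)
    }
    if (!is.list(points) || length(points) == 0)
        stop("points must be a data.frame or a non-empty list of them",
             call. = FALSE)
    lapply(points, function(p) {
        if (!all(c("x_px", "y_px") %in% names(p)))
            stop("each field needs columns x_px and y_px", call. = FALSE)
        p
    })
}

#' 2D pair-correlation probability-density map
#'
#' For every reference cell (those at least \code{borderMargin} from each
#' field edge, so the disc of radius \code{rMax} lies fully inside the
#' field), the displacement to every other cell within Euclidean distance
#' (0, rMax] is accumulated on a (2 rMax + 1)^2 grid of 1-px bins; the
#' self-pair is excluded. Multiple fields are pooled before normalisation,
#' after which every bin holds pair mass / total pairs, so the bins within
#' the disc sum to 1. Displacements are assigned to bins by rounding, and
#' disc membership is decided at bin resolution, so bins outside the disc
#' are exactly zero.
#'
#' In \code{unordered} mode a displacement is directionless, so every
#' reference-to-neighbour displacement is accumulated together with its
#' mirror: the map is exactly centro-symmetric by construction and its
#' per-bin expectation stays flat for uniform fields. In
#' \code{time_ordered} mode only cells attaching after the reference are
#' accumulated, which is the mode that can reveal a one-sided downstream
#' shadow.
#'
#' @param points data.frame with columns \code{x_px}, \code{y_px}, optional
#'   \code{t} (required for time_ordered mode) and optional \code{field},
#'   or a list of such data.frames (one per field)
#' @param fieldWidth,fieldHeight field extent (px); all fields must share it
#' @param rMax disc radius (px)
#' @param mode \code{"unordered"} or \code{"time_ordered"}
#' @param borderMargin reference-cell margin (px), default \code{rMax}
#' @param keepPairs keep the raw pair displacements (needed by
#'   \code{\link{anisotropyTest}})
#' @return a \linkS4class{PairCorrelationMap}
#' @examples
#' pts <- data.frame(x_px = c(60, 70), y_px = c(60, 60))
#' m <- pairCorrelationMap(pts, 130, 130, rMax = 50)
#' which(densityMap(m) > 0, arr.ind = TRUE)  # bins at (+10, 0) and (-10, 0)
#' @export
pairCorrelationMap <- function(points, fieldWidth, fieldHeight, rMax = 50L,
                               mode = c("unordered", "time_ordered"),
                               borderMargin = rMax, keepPairs = FALSE) {
    mode <- match.arg(mode)
    rMax <- as.integer(rMax)
    stopifnot(rMax >= 1, fieldWidth > 0, fieldHeight > 0, borderMargin >= 0)
    fields <- .asFieldList(points)
    if (!any(vapply(fields, nrow, numeric(1)) >= 2))
        stop("need at least 2 points in at least one field", call. = FALSE)
    ordered <- mode == "time_ordered"
    side <- 2L * rMax + 1L
    counts <- matrix(0L, side, side)
    nPairs <- 0; nRef <- 0L
    pairs <- list()
    for (k in seq_along(fields)) {
        f <- fields[[k]]
        tvec <- if (ordered) {
            if (is.null(f$t))
                stop("time_ordered mode needs a 't' column", call. = FALSE)
            as.numeric(f$t)
        } else numeric(nrow(f))
        res <- cpp_pair_displacements(
            as.numeric(f$x_px), as.numeric(f$y_px), tvec, ordered, rMax,
            borderMargin, 0, fieldWidth, 0, fieldHeight, keepPairs)
        counts <- counts + res$counts
        nPairs <- nPairs + res$n_pairs
        nRef <- nRef + res$n_ref
        if (keepPairs && nrow(res$pairs))
            pairs[[length(pairs) + 1L]] <- cbind(field = k, res$pairs)
    }
    if (nRef == 0)
        stop("no reference cells remain after the border-margin filter",
             call. = FALSE)
    dens <- if (nPairs > 0) counts / nPairs else counts * 0
    offs <- -rMax:rMax
    dimnames(dens) <- dimnames(counts) <- list(dy = offs, dx = offs)
    new("PairCorrelationMap", density = dens, counts = counts,
        nPairs = nPairs, nRef = nRef, nFields = length(fields),
        rMax = rMax, mode = mode,
        pairs = if (length(pairs)) do.call(rbind, pairs)
                else data.frame(field = integer(0), i = integer(0),
                                j = integer(0), dx = numeric(0),
                                dy = numeric(0)))
}

#' Radial profile of a pair-correlation map
#'
#' Mean bin density per annulus of the given ring width. For a uniform
#' (non-blocking) pattern the profile is flat beyond the hard-core ring at
#' the level 1 / (pi rMax^2).
#'
#' @param map a \linkS4class{PairCorrelationMap}
#' @param ringWidth annulus width (px), >= 1
#' @return data.frame(r_inner, r_outer, mean_density, n_bins)
#' @export
radialProfile <- function(map, ringWidth = 1) {
    stopifnot(is(map, "PairCorrelationMap"))
    if (ringWidth < 1)
        stop("invalid parameter: ringWidth must be >= 1", call. = FALSE)
    offs <- -map@rMax:map@rMax
    r <- sqrt(outer(offs^2, offs^2, "+"))
    sel <- r > 0 & r <= map@rMax
    ring <- ceiling(r[sel] / ringWidth)
    dens <- map@density[sel]
    agg <- tapply(dens, ring, mean)
    nb <- tapply(dens, ring, length)
    idx <- as.integer(names(agg))
    data.frame(r_inner = (idx - 1) * ringWidth, r_outer = idx * ringWidth,
               mean_density = as.numeric(agg), n_bins = as.integer(nb))
}

.angleFromFlow <- function(dx, dy, flowDirection) {
    f <- flowDirection / sqrt(sum(flowDirection^2))
    r <- sqrt(dx^2 + dy^2)
    cosang <- (dx * f[1] + dy * f[2]) / pmax(r, .Machine$double.eps)
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi   # [0, 180]
}

.depletionIndexFromPairs <- function(dx, dy, theta, rS, flowDirection,
                                     mode) {
    r <- sqrt(dx^2 + dy^2)
    sel <- r > 0 & r <= rS
    nSel <- sum(sel)
    if (nSel == 0)
        stop("undefined index: zero pair mass at r <= rS", call. = FALSE)
    ang <- .angleFromFlow(dx[sel], dy[sel], flowDirection)
    if (mode == "unordered") {
        inCone <- ang <= theta | ang >= 180 - theta
        frac <- 4 * theta / 360
    } else {
        inCone <- ang <= theta
        frac <- 2 * theta / 360
    }
    list(index = sum(inCone) / (nSel * frac), n = nSel)
}

#' Flow-axis depletion index
#'
#' Observed pair mass inside a cone of half-angle \code{theta} about the
#' flow axis (both cones in unordered mode) and radius \code{rS}, divided by
#' the rotationally-uniform expectation (total mass at r <= rS times the
#' angular fraction of the cone). An index near 1 means no blocking
#' signature; a downstream shadow pulls the time-ordered index below 1.
#'
#' @param map a \linkS4class{PairCorrelationMap}
#' @param theta cone half-angle (degrees)
#' @param rS cone radius (px); defaults to the map radius, but the shadow
#'   length in px is the sensitive choice when testing a blocking model
#' @param flowDirection flow axis as an (x, y) vector; default +x
#' @return an \linkS4class{AnisotropyResult} (index only, no p-value)
#' @export
flowAxisDepletionIndex <- function(map, theta = 30, rS = map@rMax,
                                   flowDirection = c(1, 0)) {
    stopifnot(is(map, "PairCorrelationMap"), theta > 0, theta <= 90, rS > 0)
    offs <- -map@rMax:map@rMax
    dx <- matrix(offs, nrow = length(offs), ncol = length(offs),
                 byrow = TRUE)
    dy <- matrix(offs, nrow = length(offs), ncol = length(offs))
    r <- sqrt(dx^2 + dy^2)
    sel <- r > 0 & r <= rS
    total <- sum(map@density[sel])
    if (total == 0)
        stop("undefined index: zero pair mass at r <= rS", call. = FALSE)
    ang <- .angleFromFlow(dx[sel], dy[sel], flowDirection)
    if (map@mode == "unordered") {
        inCone <- ang <= theta | ang >= 180 - theta
        frac <- 4 * theta / 360
    } else {
        inCone <- ang <= theta
        frac <- 2 * theta / 360
    }
    observed <- sum(map@density[sel][inCone])
    new("AnisotropyResult", index = observed / (total * frac),
        theta = theta, rS = rS, mode = map@mode,
        nPairs = total * map@nPairs, pValue = NA_real_, nPerm = 0L,
        nullIndices = numeric(0), caveat = FALSE)
}

#' Permutation test for flow-axis blocking anisotropy
#'
#' Computes the flow-axis depletion index from the raw pair displacements
#' and compares it against a rotation null: every unique pair is rotated
#' about the reference cell by an independent uniform angle (preserving the
#' radial structure, destroying direction; mirrored duplicates of an
#' unordered pair rotate together so the symmetry of the map is preserved).
#' The one-sided p-value is (1 + #\{null index <= observed\}) / (1 + nPerm),
#' small when the observed downstream mass is lower than rotations can
#' explain. With fewer than 50 supporting pairs a caveat is flagged and a
#' warning raised.
#'
#' @inheritParams pairCorrelationMap
#' @param theta cone half-angle (degrees)
#' @param rS cone radius (px)
#' @param flowDirection flow axis as an (x, y) vector
#' @param nPerm number of permutations (>= 99)
#' @param seed seed for the rotation null
#' @return an \linkS4class{AnisotropyResult}
#' @export
anisotropyTest <- function(points, fieldWidth, fieldHeight, rMax = 50L,
                           mode = c("time_ordered", "unordered"),
                           borderMargin = rMax, theta = 30, rS = rMax,
                           flowDirection = c(1, 0), nPerm = 199L,
                           seed = 1L) {
    mode <- match.arg(mode)
    if (nPerm < 99) stop("nPerm must be >= 99", call. = FALSE)
    map <- pairCorrelationMap(points, fieldWidth, fieldHeight, rMax, mode,
                              borderMargin, keepPairs = TRUE)
    pr <- map@pairs
    obs <- .depletionIndexFromPairs(pr$dx, pr$dy, theta, rS, flowDirection,
                                    mode)
    caveat <- obs$n < 50
    if (caveat)
        warning("fewer than 50 pairs support the statistic; p-value is ",
                "unreliable", call. = FALSE)
    key <- paste(pr$field, pmin(pr$i, pr$j), pmax(pr$i, pr$j))
    keyId <- match(key, unique(key))
    r <- sqrt(pr$dx^2 + pr$dy^2)
    ang0 <- atan2(pr$dy, pr$dx)
    null <- .withSeed(seed, vapply(seq_len(nPerm), function(p) {
        phi <- runif(max(keyId), 0, 2 * pi)[keyId]
        a <- ang0 + phi
        .depletionIndexFromPairs(r * cos(a), r * sin(a), theta, rS,
                                 flowDirection, mode)$index
    }, numeric(1)))
    pval <- (1 + sum(null <= obs$index)) / (1 + nPerm)
    new("AnisotropyResult", index = obs$index, theta = theta, rS = rS,
        mode = mode, nPairs = obs$n, pValue = pval,
        nPerm = as.integer(nPerm), nullIndices = null, caveat = caveat)
}
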