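## Two-phase adhesion kinetics: breakpoint selection by SSE-minimising grid
## search over the observation times, two independent ordinary least-squares
## segments, and rate comparison across conditions.

.olsSegment <- function(t_min, d) {
    # returns c(intercept, slope, sse, r2); slope per minute
    n <- length(t_min)
    mt <- mean(t_min); md <- mean(d)
    sxx <- sum((t_min - mt)^2)
    slope <- if (sxx > 0) sum((t_min - mt) * (d - md)) / sxx else 0
    intercept <- md - slope * mt
    res <- d - intercept - slope * t_min
    sse <- sum(res^2)
    sst <- sum((d - md)^2)
    r2 <- if (sse <= .Machine$double.eps * max(1, sst)) 1
          else if (sst > 0) 1 - sse / sst else 1
    c(intercept, slope, sse, r2)
}

#' Two-phase linear fit of an adhesion time series
#'
#' Fits two independent straight lines to the density-versus-time data with
#' the breakpoint chosen, over the observation times falling inside the
#' search window, to minimise the total sum of squared errors. The first
#' segment uses points with t <= t_b, the second t > t_b; segments are not
#' constrained to meet at the breakpoint, mirroring the two separate
#' regressions used in flow-cell practice. SSE ties resolve to the latest
#' candidate, which assigns an exactly-fitting kink observation to the
#' first segment. Slopes are reported in cells/(cm^2.min).
#'
#' @param series an \linkS4class{AdhesionTimeSeries} (>= 6 points)
#' @param window breakpoint search window in seconds; the default c(300,
#'   540) covers the 5-9 min interval where flow-cell adhesion rates are
#'   typically observed to drop
#' @return a \linkS4class{TwoPhaseFit}
#' @examples
#' t <- seq(60, 1800, by = 60)
#' d <- ifelse(t <= 420, 10 * t / 60, 70 + 4.5 * (t - 420) / 60)
#' fit <- fitTwoPhase(AdhesionTimeSeries(t, d))
#' slopes(fit); rateReduction(fit)  # 10, 4.5 -> 55%
#' @export
fitTwoPhase <- function(series, window = c(300, 540)) {
    stopifnot(is(series, "AdhesionTimeSeries"), length(window) == 2,
              window[1] <= window[2])
    t <- series@times; d <- series@densities
    if (length(t) < 6)
        stop("need at least 6 points for a two-phase fit", call. = FALSE)
    cand <- t[t >= window[1] & t <= window[2]]
    # each segment needs >= 3 points
    cand <- cand[vapply(cand, function(tb) {
        sum(t <= tb) >= 3 && sum(t > tb) >= 3
    }, logical(1))]
    if (length(cand) == 0)
        stop("no candidate breakpoint in the window leaves >= 3 points per ",
             "segment", call. = FALSE)
    fits <- lapply(cand, function(tb) {
        f1 <- .olsSegment(t[t <= tb] / 60, d[t <= tb])
        f2 <- .olsSegment(t[t > tb] / 60, d[t > tb])
        list(tb = tb, f1 = f1, f2 = f2, sse = f1[3] + f2[3])
    })
    sses <- vapply(fits, `[[`, numeric(1), "sse")
    # ties (continuous kinks fit exactly from either side) resolve to the
    # latest candidate so the kink observation belongs to the first segment
    tol <- min(sses) + 1e-9 * (1 + min(sses))
    best <- fits[[max(which(sses <= tol))]]
    new("TwoPhaseFit",
        breakpoint = best$tb,
        slopes = c(best$f1[2], best$f2[2]),
        intercepts = c(best$f1[1], best$f2[1]),
        r2 = c(best$f1[4], best$f2[4]),
        sse = best$sse,
        nPoints = c(sum(t <= best$tb), sum(t > best$tb)),
        window = window,
        candidates = data.frame(time_s = cand, sse = sses))
}

#' Percent reduction between the two adhesion rates
#'
#' (1 - s2/s1) x 100: the drop from the initial to the final adhesion rate.
#' Negative when the second rate exceeds the first.
#'
#' @param fit a \linkS4class{TwoPhaseFit}, or the initial slope s1
#' @param s2 final slope (when \code{fit} is numeric)
#' @return percent reduction
#' @examples
#' rateReduction(10, 4.5)  # 55
#' @export
rateReduction <- function(fit, s2 = NULL) {
    if (is(fit, "TwoPhaseFit")) {
        s1 <- fit@slopes[1]; s2 <- fit@slopes[2]
    } else {
        s1 <- fit
        if (is.null(s2)) stop("supply s2 with a numeric s1", call. = FALSE)
    }
    if (s1 == 0)
        stop("undefined reduction: initial slope s1 is 0", call. = FALSE)
    (1 - s2 / s1) * 100
}

#' Compare adhesion rates across conditions
#'
#' One-way ANOVA on per-condition replicate slopes followed by Tukey HSD
#' pairwise comparisons, both computed from first principles (group means,
#' pooled within-group variance, studentized-range distribution via
#' \code{ptukey}). Pairs with p below \code{alpha} are flagged significant.
#' With zero between-group variance F = 0; with zero within-group variance
#' and distinct means the pairwise p-values are 0.
#'
#' @param groups named list of numeric vectors, one per condition, each with
#'   at least 2 replicates
#' @param alpha significance level for the flags
#' @return a \linkS4class{RateComparison}
#' @examples
#' compareRates(list(a = c(10, 11, 9), b = c(3, 4, 3.5)))
#' @export
compareRates <- function(groups, alpha = 0.05) {
    if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
    if (is.null(names(groups)) || any(names(groups) == ""))
        names(groups) <- paste0("group", seq_along(groups))
    ni <- vapply(groups, length, numeric(1))
    if (any(ni < 2))
        stop("every group needs >= 2 replicates", call. = FALSE)
    k <- length(groups); N <- sum(ni)
    mi <- vapply(groups, mean, numeric(1))
    grand <- sum(ni * mi) / N
    ssb <- sum(ni * (mi - grand)^2)
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
    dfb <- k - 1; dfw <- N - k
    msb <- ssb / dfb; msw <- ssw / dfw
    if (ssb == 0) {
        fstat <- 0; fp <- 1
    } else if (msw == 0) {
        fstat <- Inf; fp <- 0
    } else {
        fstat <- msb / msw
        fp <- pf(fstat, dfb, dfw, lower.tail = FALSE)
    }
    pairs <- utils::combn(k, 2)
    tab <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c2) {
        i <- pairs[1, c2]; j <- pairs[2, c2]
        diff <- mi[j] - mi[i]
        se <- sqrt(msw / 2 * (1 / ni[i] + 1 / ni[j]))
        if (se == 0) {
            p <- if (diff == 0) 1 else 0
            q <- if (diff == 0) 0 else Inf
        } else {
            q <- abs(diff) / se
            p <- ptukey(q, k, dfw, lower.tail = FALSE)
        }
        data.frame(pair = paste(names(groups)[i], names(groups)[j],
                                sep = "-"),
                   diff = unname(diff), q = unname(q), p = unname(p))
    }))
    tab$significant <- tab$p < alpha
    rownames(tab) <- NULL
    new("RateComparison", groups = groups, fStatistic = fstat,
        fPValue = fp, table = tab, alpha = alpha)
}
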