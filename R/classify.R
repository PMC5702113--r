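#' Classification thresholds
#'
#' Two user-tunable thresholds steer the category prediction:
#'
#' * `plateauRangeFraction` — tolerated coverage variation, as a fraction
#'   of the locus's overall coverage range, within which a point beyond an
#'   extremum counts as plateau fluctuation rather than genuine change
#'   (default 0.1, i.e. 10% of the range).
#' * `leadingTrailingMin` — number of genuine (non-plateau) points beyond
#'   an extremum that must be *exceeded* to promote a locus from single-
#'   to double-sigmoid (hill/valley) modeling (default 1, so at least two
#'   genuine trailing points are needed; set 0 to let a single genuine
#'   point trigger a hill, as needed when hills emerge as early as the
#'   second time point).
#'
#' @param plateauRangeFraction real in `[0, 1]`.
#' @param leadingTrailingMin non-negative integer.
#' @return a named list of thresholds.
#' @export
turnoverThresholds <- function(plateauRangeFraction = 0.1,
                               leadingTrailingMin = 1L) {
    if (plateauRangeFraction < 0 || plateauRangeFraction > 1)
        stop("plateauRangeFraction must lie in [0, 1]")
    if (leadingTrailingMin < 0)
        stop("leadingTrailingMin must be non-negative")
    list(plateauRangeFraction = plateauRangeFraction,
         leadingTrailingMin = as.integer(leadingTrailingMin))
}

#' Locate the absolute extrema of a coverage series
#'
#' Indices (1-based) of the absolute minimum and maximum; the earliest
#' index wins ties (favoring the simpler single-sigmoid path).
#'
#' @param ys numeric coverage series.
#' @return list with `iMin`, `iMax`, and `flat` (`TRUE` for a constant
#'   series, which cannot be classified and is modeled linear-only).
#' @export
locateExtrema <- function(ys) {
    if (diff(range(ys)) == 0)
        return(list(iMin = NA_integer_, iMax = NA_integer_, flat = TRUE))
    list(iMin = which.min(ys), iMax = which.max(ys), flat = FALSE)
}

#' Count genuine (non-plateau) points beyond an extremum
#'
#' Points strictly before (`leading`) or after (`trailing`) the extremum
#' whose deviation from the extremum value exceeds
#' `plateauRangeFraction * (max(ys) - min(ys))` are "changing meaningfully
#' over time" rather than fluctuating around a plateau, and count as
#' genuine.
#'
#' @param ys coverage series.
#' @param extremumIndex 1-based index of the extremum.
#' @param side `"leading"` or `"trailing"`.
#' @param thresholds a [turnoverThresholds()] list.
#' @return integer count.
#' @export
genuinePointCount <- function(ys, extremumIndex,
                              side = c("leading", "trailing"),
                              thresholds = turnoverThresholds()) {
    side <- match.arg(side)
    band <- thresholds$plateauRangeFraction * diff(range(ys))
    idx <- if (side == "leading") seq_len(extremumIndex - 1L)
           else if (extremumIndex < length(ys))
               seq.int(extremumIndex + 1L, length(ys))
           else integer()
    sum(abs(ys[idx] - ys[extremumIndex]) > band)
}

#' Predict the temporal category of a locus
#'
#' Prediction is driven by the order in time of the absolute minimum and
#' maximum coverage.  Minimum first gives a base of `rise`, maximum first
#' a base of `fall`.  A rise is promoted to `hill` when the number of
#' genuine points trailing the maximum (or, symmetrically, leading the
#' minimum) exceeds `leadingTrailingMin`; a fall is promoted to `valley`
#' by the same test around the minimum (trailing) or maximum (leading).
#' Loci whose extrema are adjacent in time with no plateau anchored at
#' either end are demoted to `undefined_rise`/`undefined_fall` (they are
#' still modeled, by a single sigmoid in the direction of their extrema
#' order).  Constant series return `flat`.
#'
#' @inheritParams genuinePointCount
#' @return one of `"rise"`, `"fall"`, `"hill"`, `"valley"`,
#'   `"undefined_rise"`, `"undefined_fall"`, `"flat"`.
#' @export
predictCategory <- function(ys, thresholds = turnoverThresholds()) {
    ex <- locateExtrema(ys)
    if (ex$flat) return("flat")
    tmin <- thresholds$leadingTrailingMin
    band <- thresholds$plateauRangeFraction * diff(range(ys))
    n <- length(ys)
    if (ex$iMin < ex$iMax) {
        base <- "rise"
        dbl <- genuinePointCount(ys, ex$iMax, "trailing", thresholds) > tmin ||
               genuinePointCount(ys, ex$iMin, "leading", thresholds) > tmin
        promoted <- "hill"
        iFirst <- ex$iMin; iLast <- ex$iMax
    } else {
        base <- "fall"
        dbl <- genuinePointCount(ys, ex$iMin, "trailing", thresholds) > tmin ||
               genuinePointCount(ys, ex$iMax, "leading", thresholds) > tmin
        promoted <- "valley"
        iFirst <- ex$iMax; iLast <- ex$iMin
    }
    if (dbl) return(promoted)
    # sanity check: adjacent extrema with no plateau evidence at either end
    if (abs(ex$iMax - ex$iMin) == 1L) {
        plateauStart <- iFirst == 1L ||
            any(abs(ys[seq_len(iFirst - 1L)] - ys[iFirst]) <= band)
        plateauEnd <- iLast == n ||
            any(abs(ys[seq.int(iLast + 1L, n)] - ys[iLast]) <= band)
        if (!(plateauStart && plateauEnd))
            return(paste0("undefined_", base))
    }
    base
}

#' Segment a locus by its predicted category and fit sigmoids
#'
#' Single-category loci (`rise`, `fall`, `undefined_*`) are fit with one
#' sigmoid over all points.  A `hill` is fit with an increasing sigmoid on
#' the points up to and including the absolute maximum and a decreasing
#' sigmoid from the maximum onward (the extremum sample is shared by both
#' segments); a `valley` is the symmetric split about the minimum.  Very
#' short segments are fit with reduced parameter sets: 3 points fix the
#' early plateau at the segment's first value, 2 points fix both plateaus
#' at the segment end values and fit only `b` and `c`.  `flat` loci get
#' the linear fit only.
#'
#' @param times numeric time points.
#' @param ys coverage series.
#' @param predicted category from [predictCategory()].
#' @param objective,fixF passed to [fitSigmoid()].
#' @return a `LocusResult` list: `predicted`, `final` (`NA` until
#'   [verifyOrEliminate()]), `fits` (0, 1 or 2 `SigmoidFit`s), `linear`,
#'   `ttiRise`, `ttiFall`.
#' @export
segmentAndFit <- function(times, ys, predicted,
                          objective = "least_squares", fixF = TRUE) {
    linear <- fitLinear(times, ys)
    out <- list(predicted = predicted, final = NA_character_,
                fits = list(), linear = linear,
                ttiRise = NA_real_, ttiFall = NA_real_)
    if (predicted == "flat") return(out)
    ex <- locateExtrema(ys)
    if (predicted %in% c("hill", "valley")) {
        pivot <- if (predicted == "hill") ex$iMax else ex$iMin
        seg1 <- seq_len(pivot)
        seg2 <- seq.int(pivot, length(ys))
        f1 <- .segmentFit(times[seg1], ys[seg1], objective, fixF)
        f2 <- .segmentFit(times[seg2], ys[seg2], objective, fixF)
        if (is.null(f1) || is.null(f2)) {
            # segment too short even for the reduced fit: fall back to a
            # single sigmoid and call the locus undefined
            out$predicted <- paste0("undefined_",
                                    if (predicted == "hill") "rise"
                                    else "fall")
            out$fits <- list(fitSigmoid(times, ys, objective, fixF))
        } else {
            out$fits <- list(f1, f2)
        }
    } else {
        out$fits <- list(fitSigmoid(times, ys, objective, fixF))
    }
    for (f in out$fits) {
        if (f$direction == "increasing" && is.na(out$ttiRise))
            out$ttiRise <- f$tti
        if (f$direction == "decreasing" && is.na(out$ttiFall))
            out$ttiFall <- f$tti
    }
    out
}

## fit one hill/valley segment, reducing the parameter set when the
## segment is shorter than the 4P model allows; NULL when < 2 points
.segmentFit <- function(times, ys, objective, fixF) {
    n <- length(times)
    if (n >= 4L && diff(range(ys)) > 0)
        return(tryCatch(fitSigmoid(times, ys, objective, fixF),
                        error = function(e) NULL))
    if (n < 2L || diff(range(ys)) == 0) return(NULL)
    # reduced fits: plateaus pinned at the observed segment end values;
    # 'a' sits on the e^{b(x-c)} -> 0 side (late for rises, early for
    # falls), 'd' on the opposite end
    increasing <- ys[n] >= ys[1L]
    aFix <- max(if (increasing) ys[n] else ys[1L], 0)
    dFix <- max(if (increasing) ys[1L] else ys[n], 0)
    span <- diff(range(times))
    if (n == 2L) {
        # both plateaus pinned; midpoint crossing sits between the points
        b <- (if (increasing) -1 else 1) * 4 * diff(range(ys)) / span
        params <- list(a = aFix, b = b, c = mean(times), d = dFix, f = 1)
        rss <- sum((ys - sigmoidEval(params, times))^2)
        return(structure(list(
            params = params,
            stdErrors = stats::setNames(rep(NA_real_, 4),
                                        c("a", "b", "c", "d")),
            rss = rss, objective = objective, converged = TRUE,
            tti = tryCatch(turnoverTimeIndex(params),
                           error = function(e) NA_real_),
            direction = if (b < 0) "increasing" else "decreasing"),
            class = "SigmoidFit"))
    }
    # n == 3: fix the early plateau, fit a, b, c by bounded least squares
    obj <- function(th) {
        p <- list(a = th[1L], b = th[2L], c = th[3L], d = dFix, f = 1)
        sum((ys - sigmoidEval(p, times))^2)
    }
    b0 <- (if (increasing) -1 else 1) * 4 * diff(range(ys)) / span
    op <- tryCatch(stats::optim(
        c(aFix, b0, mean(times)), obj, method = "L-BFGS-B",
        lower = c(0, -1e3, min(times) - span),
        upper = c(3 * max(ys), 1e3, max(times) + span)),
        error = function(e) NULL)
    if (is.null(op)) return(NULL)
    params <- list(a = op$par[1L], b = op$par[2L], c = op$par[3L],
                   d = dFix, f = 1)
    structure(list(
        params = params,
        stdErrors = stats::setNames(rep(NA_real_, 4),
                                    c("a", "b", "c", "d")),
        rss = op$value, objective = objective,
        converged = op$convergence == 0,
        tti = tryCatch(turnoverTimeIndex(params),
                       error = function(e) NA_real_),
        direction = if (params$b < 0) "increasing" else "decreasing"),
        class = "SigmoidFit")
}

#' Verify a predicted category against the fitted directions
#'
#' The final category equals the prediction only when every fitted
#' segment's direction (the sign of its incorporation rate index) matches
#' what the prediction demands and the fit converged; otherwise the locus
#' is `eliminated`.  This two-fold verification removes false positives:
#' e.g. a locus predicted to rise but actually fit by a falling sigmoid is
#' eliminated from downstream analysis (the row is retained for audit).
#'
#' @param result a `LocusResult` from [segmentAndFit()].
#' @return the result with `final` set.
#' @export
verifyOrEliminate <- function(result) {
    pred <- result$predicted
    if (pred == "flat") {
        result$final <- "flat"
        return(result)
    }
    expected <- switch(pred,
        rise = "increasing",
        undefined_rise = "increasing",
        fall = "decreasing",
        undefined_fall = "decreasing",
        hill = c("increasing", "decreasing"),
        valley = c("decreasing", "increasing"),
        stop("unknown predicted category: ", pred))
    got <- vapply(result$fits, function(f) f$direction, character(1))
    conv <- vapply(result$fits, function(f) isTRUE(f$converged), logical(1))
    ok <- length(got) == length(expected) && all(got == expected) &&
        all(conv)
    result$final <- if (ok) pred else "eliminated"
    result
}
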