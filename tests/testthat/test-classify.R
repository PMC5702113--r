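test_that("extrema are located with earliest-tie rules", {
    expect_identical(locateExtrema(c(1, 5, 2)),
                     list(iMin = 1L, iMax = 2L, flat = FALSE))
    ex <- locateExtrema(c(5, 1, 1, 7))
    expect_identical(ex$iMin, 2L)   # earliest tie wins
    expect_identical(ex$iMax, 4L)
    expect_true(locateExtrema(c(3, 3, 3))$flat)
})

test_that("genuine point counts apply the plateau range band", {
    thr <- turnoverThresholds(plateauRangeFraction = 0.1)
    # trailing deviations {0.1, 0.2} inside the band 0.1 * 10 = 1
    expect_identical(
        genuinePointCount(c(0, 2, 10, 9.9, 9.8), 3L, "trailing", thr), 0L)
    # trailing deviations {3, 5} exceed the band
    expect_identical(
        genuinePointCount(c(0, 2, 10, 7, 5), 3L, "trailing", thr), 2L)
    # extremum at the boundary leaves an empty side
    expect_identical(
        genuinePointCount(c(0, 2, 10), 3L, "trailing", thr), 0L)
    expect_identical(
        genuinePointCount(c(10, 2, 0), 1L, "leading", thr), 0L)
    # leading side of a minimum
    expect_identical(
        genuinePointCount(c(9, 4, 0, 1, 8), 3L, "leading", thr), 2L)
})

test_that("categories are predicted from extrema order and genuine points", {
    thr <- turnoverThresholds()
    tt <- 0:10
    rise <- sigmoidEval(list(a = 10, b = -2, c = 5, d = 0, f = 1), tt)
    fall <- sigmoidEval(list(a = 10, b = 2, c = 5, d = 0, f = 1), tt)
    expect_identical(predictCategory(rise, thr), "rise")
    expect_identical(predictCategory(fall, thr), "fall")
    # two genuine trailing points after the max exceed the default of 1
    expect_identical(predictCategory(c(0, 1, 8, 9, 3, 1), thr), "hill")
    # trailing fluctuations inside the plateau band keep it a rise
    expect_identical(predictCategory(c(0, 1, 8, 9, 8.9, 8.8), thr),
                     "rise")
    expect_identical(predictCategory(10 - c(0, 1, 8, 9, 3, 1), thr),
                     "valley")
    expect_identical(predictCategory(rep(4, 11), thr), "flat")
})

test_that("noise-free shapes of all four categories are recovered intact", {
    tt <- 0:10
    thr <- turnoverThresholds()
    shapes <- list(
        rise = sigmoidEval(list(a = 10, b = -2, c = 5, d = 0, f = 1), tt),
        fall = sigmoidEval(list(a = 10, b = 2, c = 5, d = 0, f = 1), tt),
        hill = makeHillSeries(tt),
        valley = makeValleySeries(tt))
    for (nm in names(shapes)) {
        pred <- predictCategory(shapes[[nm]], thr)
        expect_identical(pred, nm)
        lr <- verifyOrEliminate(segmentAndFit(tt, shapes[[nm]], pred))
        expect_identical(lr$final, nm)
    }
})

test_that("hills are segmented about the maximum with a shared extremum", {
    tt <- 0:10
    ys <- makeHillSeries(tt, cRise = 2.5, cFall = 7.5)
    lr <- segmentAndFit(tt, ys, "hill")
    expect_length(lr$fits, 2L)
    expect_identical(lr$fits[[1]]$direction, "increasing")
    expect_identical(lr$fits[[2]]$direction, "decreasing")
    # both segment TTIs recovered within 2% of truth
    expect_lt(abs(lr$ttiRise - 2.5) / 2.5, 0.02)
    expect_lt(abs(lr$ttiFall - 7.5) / 7.5, 0.02)
    # a rise gets a single fit, no fall-segment TTI
    rise <- sigmoidEval(list(a = 10, b = -2, c = 5, d = 0, f = 1), tt)
    lrR <- segmentAndFit(tt, rise, "rise")
    expect_length(lrR$fits, 1L)
    expect_true(is.na(lrR$ttiFall))
})

test_that("a hill peaking at the second time point still fits two segments", {
    tt <- 0:10
    # sharp early rise, then decay: max at index 2 leaves a 2-point rise
    # segment, fit with both plateaus pinned
    ys <- c(0, 10, 8, 6, 4, 3, 2, 1.5, 1.2, 1.1, 1)
    thr <- turnoverThresholds(leadingTrailingMin = 0L)
    expect_identical(predictCategory(ys, thr), "hill")
    lr <- verifyOrEliminate(segmentAndFit(tt, ys, "hill"))
    expect_identical(lr$final, "hill")
    expect_length(lr$fits, 2L)
    expect_true(is.finite(lr$ttiRise))
    expect_true(lr$ttiRise >= 0 && lr$ttiRise <= 1)
})

test_that("verification eliminates direction mismatches", {
    tt <- 0:10
    ys <- sigmoidEval(list(a = 10, b = -2, c = 5, d = 0, f = 1), tt)
    lr <- segmentAndFit(tt, ys, "rise")
    expect_identical(verifyOrEliminate(lr)$final, "rise")
    # forge a wrong-direction fit: predicted rise, fitted fall
    lrBad <- lr
    lrBad$fits[[1]]$direction <- "decreasing"
    expect_identical(verifyOrEliminate(lrBad)$final, "eliminated")
    # hill with a correct rise segment but unconverged fall segment
    hill <- segmentAndFit(tt, makeHillSeries(tt), "hill")
    hill$fits[[2]]$converged <- FALSE
    expect_identical(verifyOrEliminate(hill)$final, "eliminated")
})

test_that("raising either threshold monotonically removes hills and valleys", {
    spec <- defaultSimulationSpec("both", nPerLevel = 3)
    sim <- simulateTrueCoverage(spec)
    noisy <- addNoise(sim$coverage, 1, seed = 202)
    vals <- covValues(noisy)
    nDouble <- function(thr) {
        preds <- apply(vals, 1L, predictCategory, thresholds = thr)
        sum(preds %in% c("hill", "valley"))
    }
    fracs <- c(0.02, 0.05, 0.1, 0.2, 0.4)
    byFrac <- vapply(fracs, function(fr)
        nDouble(turnoverThresholds(plateauRangeFraction = fr)),
        numeric(1))
    expect_true(all(diff(byFrac) <= 0))
    mins <- 0:4
    byMin <- vapply(mins, function(m)
        nDouble(turnoverThresholds(leadingTrailingMin = m)), numeric(1))
    expect_true(all(diff(byMin) <= 0))
})

test_that("every locus ends verified, eliminated or flat", {
    spec <- defaultSimulationSpec("both", nPerLevel = 2)
    sim <- simulateTrueCoverage(spec)
    noisy <- addNoise(sim$coverage, 2, seed = 77)
    rs <- analyzeTimeCourse(noisy)
    final <- finalCategories(rs)
    expect_length(final, nrow(covValues(noisy)))
    verified <- sum(final %in% c("rise", "fall", "hill", "valley",
                                 "undefined_rise", "undefined_fall",
                                 "flat"))
    expect_identical(verified + sum(final == "eliminated"),
                     length(final))
})
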