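test_that("sigmoid evaluation matches direct substitution and limits", {
    # symmetric curve crosses the midpoint at x = c
    expect_equal(sigmoidEval(list(a = 0, b = -1, c = 0, d = 1, f = 1), 0),
                 0.5)
    # a is the plateau on the e^{b(x-c)} -> 0 side
    p <- list(a = 0, b = -1, c = 0, d = 1, f = 1)
    expect_equal(sigmoidEval(p, 1e4), 0)
    expect_equal(sigmoidEval(p, -1e4), 1)
    # asymmetric direct substitution: 1 + (0 - 1)/(2^2)
    expect_equal(sigmoidEval(list(a = 0, b = 1, c = 2, d = 1, f = 2), 2),
                 0.75)
    # overflow guard: extreme |b (x - c)| saturates without NaN
    expect_equal(sigmoidEval(list(a = 3, b = 50, c = 0, d = 7, f = 1),
                             c(-100, 100)), c(3, 7))
})

test_that("inflection point closed form matches the stated examples", {
    expect_identical(
        inflectionPoint(list(a = 0, b = -2, c = 3, d = 1, f = 1)), 3)
    expect_equal(inflectionPoint(list(a = 0, b = 1, c = 0, d = 1, f = 2)),
                 -log(2))
    expect_equal(
        inflectionPoint(list(a = 0, b = -2, c = 5, d = 1, f = 0.5)),
        5 + log(0.5) / 2)
    expect_error(inflectionPoint(list(a = 0, b = 0, c = 1, d = 1, f = 1)),
                 "b = 0")
})

test_that("turnover time index has its defining midpoint property", {
    expect_identical(
        turnoverTimeIndex(list(a = 0, b = -1, c = 7, d = 1, f = 1)), 7)
    expect_equal(
        turnoverTimeIndex(list(a = 0, b = 2, c = 5, d = 1, f = 0.5)),
        5 + log(3) / 2)
    for (p in randomValidParams(25, seed = 11)) {
        tti <- turnoverTimeIndex(p)
        expect_equal(sigmoidEval(p, tti), (p$a + p$d) / 2,
                     tolerance = 1e-9)
    }
    expect_error(turnoverTimeIndex(list(a = 2, b = 1, c = 0, d = 2,
                                        f = 1)), "flat")
    expect_error(turnoverTimeIndex(list(a = 0, b = 0, c = 0, d = 2,
                                        f = 1)), "b = 0")
})

test_that("closed forms agree with independent numeric oracles", {
    draws <- randomValidParams(300, seed = 7)
    for (p in draws) {
        expect_equal(turnoverTimeIndex(p), ttiBisectionOracle(p),
                     tolerance = 1e-8)
        expect_equal(inflectionPoint(p), inflectionFdOracle(p),
                     tolerance = 1e-6)
    }
    # for f = 1, TTI = c = inflection point exactly
    p1 <- list(a = 1, b = -0.7, c = 4.2, d = 9, f = 1)
    expect_identical(turnoverTimeIndex(p1), p1$c)
    expect_identical(inflectionPoint(p1), p1$c)
})

test_that("least-squares fit recovers noise-free parameters", {
    tt <- 0:10
    truth <- list(a = 10, b = -2, c = 5, d = 0, f = 1)
    fit <- fitSigmoid(tt, sigmoidEval(truth, tt))
    expect_true(fit$converged)
    expect_equal(fit$params$a, 10, tolerance = 1e-4)
    expect_equal(fit$params$b, -2, tolerance = 1e-3)
    expect_equal(fit$params$c, 5, tolerance = 1e-4)
    expect_lt(fit$rss, 1e-8)
    expect_equal(fit$tti, 5, tolerance = 1e-4)
    expect_identical(fit$direction, "increasing")
    # falls carry a positive incorporation rate index
    fall <- fitSigmoid(tt, sigmoidEval(list(a = 10, b = 2, c = 5, d = 0,
                                            f = 1), tt))
    expect_identical(fall$direction, "decreasing")
    expect_gt(fall$params$b, 0)
})

test_that("plateaus are constrained to non-negative values", {
    tt <- 0:10
    # generator pushes the lower plateau to -3; fit must clamp at 0
    ys <- pmax(sigmoidEval(list(a = 10, b = -2, c = 5, d = -3, f = 1),
                           tt), 0)
    fit <- fitSigmoid(tt, ys)
    expect_gte(fit$params$a, 0)
    expect_gte(fit$params$d, 0)
})

test_that("fit is time-shift and scale equivariant", {
    tt <- 0:10
    truth <- list(a = 8, b = -1.5, c = 4, d = 1, f = 1)
    ys <- sigmoidEval(truth, tt)
    base <- fitSigmoid(tt, ys)
    shifted <- fitSigmoid(tt + 3.5, ys)
    expect_equal(shifted$params$c, base$params$c + 3.5, tolerance = 1e-4)
    expect_equal(shifted$tti, base$tti + 3.5, tolerance = 1e-4)
    expect_equal(shifted$params$b, base$params$b, tolerance = 1e-3)
    scaled <- fitSigmoid(tt, 4 * ys)
    expect_equal(scaled$params$a, 4 * base$params$a, tolerance = 1e-3)
    expect_equal(scaled$params$d, 4 * base$params$d, tolerance = 1e-2)
    expect_equal(scaled$params$b, base$params$b, tolerance = 1e-3)
    expect_equal(scaled$params$c, base$params$c, tolerance = 1e-3)
})

test_that("fit input contracts are enforced", {
    expect_error(fitSigmoid(0:2, c(1, 2, 3)), "at least 4")
    expect_error(fitSigmoid(0:3, rep(2, 4)), "flat")
    expect_error(fitSigmoid(0:3, sigmoidEval(list(a = 5, b = -1, c = 2,
                                                  d = 0, f = 1), 0:3),
                            fixF = FALSE), "at least 5")
    # Poisson objective rejects continuous normalized coverage
    expect_error(fitSigmoid(0:10, seq(0.1, 1.1, by = 0.1),
                            objective = "poisson"), "integer-like")
})

test_that("Poisson fit recovers the inflection near a grid-search oracle", {
    tt <- 0:10
    truth <- list(a = 40, b = -1.5, c = 5, d = 2, f = 1)
    mu <- sigmoidEval(truth, tt)
    set.seed(99)
    ys <- rpois(length(tt), mu)
    fit <- fitSigmoid(tt, ys, objective = "poisson")
    # coarse independent grid search over (b, c) with plateaus pinned at
    # the observed ends
    aHat <- mean(tail(ys, 2)); dHat <- mean(head(ys, 2))
    grid <- expand.grid(b = seq(-5, -0.1, length.out = 100),
                        c = seq(0, 10, length.out = 100))
    ll <- vapply(seq_len(nrow(grid)), function(i) {
        m <- pmax(sigmoidEval(list(a = aHat, b = grid$b[i], c = grid$c[i],
                                   d = dHat, f = 1), tt), 1e-9)
        sum(ys * log(m) - m)
    }, numeric(1))
    cOracle <- grid$c[which.max(ll)]
    expect_lt(abs(fit$params$c - cOracle), 0.5)
    expect_equal(fit$objective, "poisson")
    expect_true(all(is.finite(fit$stdErrors)))
})

test_that("standard errors shrink as noise shrinks", {
    tt <- 0:10
    truth <- list(a = 10, b = -2, c = 5, d = 0, f = 1)
    mu <- sigmoidEval(truth, tt)
    set.seed(5)
    loud <- fitSigmoid(tt, pmax(mu + rnorm(11, 0, 1), 0))
    quiet <- fitSigmoid(tt, pmax(mu + rnorm(11, 0, 0.05), 0))
    expect_true(all(is.finite(loud$stdErrors)))
    expect_lt(quiet$stdErrors[["c"]], loud$stdErrors[["c"]])
})

test_that("linear comparison fit behaves as ordinary least squares", {
    lf <- fitLinear(0:2, c(1, 2, 3))
    expect_equal(lf$slope, 1)
    expect_equal(lf$intercept, 1)
    expect_equal(lf$rss, 0)
    flat <- fitLinear(0:5, rep(2.5, 6))
    expect_equal(flat$slope, 0)
    expect_equal(flat$rss, 0)
    # sigmoid-shaped data: the line fits worse than the sigmoid
    tt <- 0:10
    ys <- sigmoidEval(list(a = 10, b = -3, c = 5, d = 0, f = 1), tt)
    expect_gt(fitLinear(tt, ys)$rss, fitSigmoid(tt, ys)$rss)
    expect_error(fitLinear(1, 1), "at least 2")
})
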