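# Independent oracles and fixture builders shared across the test files.

# Bisection solution of sigmoidEval(params, x) = (a + d) / 2, independent
# of the closed-form TTI.
ttiBisectionOracle <- function(params, tol = 1e-12) {
    target <- (params$a + params$d) / 2
    g <- function(x) sigmoidEval(params, x) - target
    # bracket around c, widening until the sign changes
    w <- max(1, 10 / abs(params$b))
    lo <- params$c - w; hi <- params$c + w
    while (sign(g(lo)) == sign(g(hi)) && w < 1e6) {
        w <- w * 2; lo <- params$c - w; hi <- params$c + w
    }
    uniroot(g, c(lo, hi), tol = tol)$root
}

# Root of the numerically differentiated second derivative.
inflectionFdOracle <- function(params, tol = 1e-10) {
    h <- 1e-3
    d2 <- function(x) {
        # 5-point central stencil, O(h^4) truncation error
        (-sigmoidEval(params, x + 2 * h) +
         16 * sigmoidEval(params, x + h) -
         30 * sigmoidEval(params, x) +
         16 * sigmoidEval(params, x - h) -
         sigmoidEval(params, x - 2 * h)) / (12 * h^2)
    }
    ctr <- params$c - log(params$f) / params$b
    w <- max(1, 5 / abs(params$b))
    lo <- ctr - w; hi <- ctr + w
    while (sign(d2(lo)) == sign(d2(hi)) && w < 1e6) {
        w <- w * 2; lo <- ctr - w; hi <- ctr + w
    }
    uniroot(d2, c(lo, hi), tol = tol)$root
}

# Random valid parameter draws (distinct plateaus, b != 0, f > 0).
randomValidParams <- function(n, seed = 20260920) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
        repeat {
            a <- runif(1, 0, 50); d <- runif(1, 0, 50)
            if (abs(a - d) > 0.5) break
        }
        b <- sample(c(-1, 1), 1) * runif(1, 0.2, 5)
        list(a = a, b = b, c = runif(1, -5, 15), d = d,
             f = runif(1, 0.3, 3))
    })
}

# Write a BAM (via SAM text) holding the given reads; returns the BAM
# path.  reads: data.frame(chrom, pos (1-based leftmost), len).
writeBamFixture <- function(reads, chromLens, dir = NULL,
                            name = "fixture") {
    if (is.null(dir)) {
        dir <- tempfile("bamfix")
        dir.create(dir)
    }
    sam <- file.path(dir, paste0(name, ".sam"))
    con <- file(sam, "w")
    writeLines("@HD\tVN:1.6\tSO:coordinate", con)
    for (ch in names(chromLens))
        writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch,
                           as.integer(chromLens[[ch]])), con)
    if (nrow(reads)) {
        ord <- order(reads$chrom, reads$pos)
        writeLines(sprintf("r%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                           seq_len(nrow(reads)), reads$chrom[ord],
                           reads$pos[ord], reads$len[ord]), con)
    }
    close(con)
    bam <- Rsamtools::asBam(sam, file.path(dir, name), overwrite = TRUE,
                            indexDestination = TRUE)
    bam
}

# Brute-force per-base pileup over a 0-based half-open interval.
bruteForceMeanDepth <- function(reads, chrom, start0, end0) {
    depth <- 0
    for (base in seq.int(start0 + 1L, end0)) {  # 1-based positions
        hit <- reads$chrom == chrom & reads$pos <= base &
            (reads$pos + reads$len - 1L) >= base
        depth <- depth + sum(hit)
    }
    depth / (end0 - start0)
}

# Noise-free hill / valley series built from two sigmoid segments that
# share the extremum time.
makeHillSeries <- function(tt, cRise = 2.5, cFall = 7.5, upper = 10,
                           b = 2, peak = NULL) {
    if (is.null(peak)) peak <- tt[which.min(abs(tt - mean(c(cRise, cFall))))]
    rise <- sigmoidEval(list(a = upper, b = -b, c = cRise, d = 0, f = 1), tt)
    fall <- sigmoidEval(list(a = upper, b = b, c = cFall, d = 0, f = 1), tt)
    ifelse(tt <= peak, rise, fall)
}

makeValleySeries <- function(tt, ...) {
    args <- list(...)
    upper <- if (is.null(args$upper)) 10 else args$upper
    upper - makeHillSeries(tt, ...)
}
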