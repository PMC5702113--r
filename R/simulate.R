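#' Default synthetic time-course specification
#'
#' Builds the benchmark design used throughout: sigmoidal loci on three
#' chromosome groups of a toy genome, sampled at 11 time points (0-10,
#' relative units).
#'
#' * group `2L.1` — inflection fixed at 5, incorporation rate index (IRI)
#'   grid `{-0.5, -0.75, -1.0, -1.5, -2.0, -3.0}` for rises (the
#'   corresponding absolute values for falls);
#' * group `2L.2` — inflections `{1, ..., 9}`, IRI -3 (|-3| for falls);
#' * group `2R`  — inflection fixed at 4.5, IRI -1.5, peak-length grid
#'   varied (`{250, 500, 1000, 2000, 4000}` bp);
#' * group `3R`  — inflection fixed at 5.5, IRI -1.5, upper-asymptote
#'   grid varied (`{2, 5, 10, 20, 50}` coverage units).
#'
#' Where a group does not vary a dimension, peak length defaults to 500
#' bp and the upper asymptote to 10 coverage units; the lower plateau is 0
#' (falls mirror rises: they start at the upper value and decay to 0).
#'
#' @param direction `"rise"`, `"fall"`, or `"both"`.
#' @param nPerLevel loci simulated per grid level in each group
#'   (default 20; raise for full-scale runs).
#' @param timePoints sampled times (default `0:10`).
#' @param meanBackground mean of the additive Poisson background noise
#'   (default 1, approximating 1X random background coverage).
#' @return a `SimulationSpec` list with one entry per (direction x group).
#' @export
defaultSimulationSpec <- function(direction = c("rise", "fall", "both"),
                                  nPerLevel = 20L, timePoints = 0:10,
                                  meanBackground = 1) {
    direction <- match.arg(direction)
    dirs <- if (direction == "both") c("rise", "fall") else direction
    iriGrid <- c(-0.5, -0.75, -1.0, -1.5, -2.0, -3.0)
    lenGrid <- c(250L, 500L, 1000L, 2000L, 4000L)
    upperGrid <- c(2, 5, 10, 20, 50)
    groups <- list()
    for (dd in dirs) {
        sgn <- if (dd == "rise") 1 else -1  # rises keep the negative IRIs
        groups <- c(groups, list(
            list(groupId = paste0("2L.1_", dd), direction = dd,
                 inflection = 5, iri = sgn * iriGrid,
                 peakLength = 500L, upper = 10),
            list(groupId = paste0("2L.2_", dd), direction = dd,
                 inflection = 1:9, iri = sgn * -3,
                 peakLength = 500L, upper = 10),
            list(groupId = paste0("2R_", dd), direction = dd,
                 inflection = 4.5, iri = sgn * -1.5,
                 peakLength = lenGrid, upper = 10),
            list(groupId = paste0("3R_", dd), direction = dd,
                 inflection = 5.5, iri = sgn * -1.5,
                 peakLength = 500L, upper = upperGrid)))
    }
    structure(list(groups = groups, nPerLevel = as.integer(nPerLevel),
                   timePoints = as.numeric(timePoints),
                   noise = list(model = "poisson",
                                meanBackground = meanBackground)),
              class = "SimulationSpec")
}

#' Expand a simulation spec into a per-locus truth table
#'
#' One row per simulated locus with its true sigmoid parameters (`f = 1`
#' throughout), group id and peak interval on the toy genome.  Under the
#' sign convention of the fitter, rises have `b < 0` (early plateau
#' `d = 0`, late plateau `a = upper`) and falls have `b > 0`.
#'
#' @param spec a [defaultSimulationSpec()] list.
#' @return a `data.frame` truth table.
#' @export
simulationTruthTable <- function(spec) {
    rows <- list()
    offset <- c()  # running end coordinate per chromosome
    gap <- 1000L
    for (g in spec$groups) {
        grid <- expand.grid(inflection = g$inflection, iri = g$iri,
                            peakLength = g$peakLength, upper = g$upper)
        grid <- grid[rep(seq_len(nrow(grid)), each = spec$nPerLevel), ,
                     drop = FALSE]
        chrom <- sub("_.*$", "", g$groupId)
        cur <- if (chrom %in% names(offset)) offset[[chrom]] else 0L
        start <- cur + gap +
            cumsum(c(0L, utils::head(grid$peakLength + gap, -1L)))
        end <- start + grid$peakLength
        offset[chrom] <- end[length(end)]
        rise <- g$direction == "rise"
        rows[[length(rows) + 1L]] <- data.frame(
            locus = sprintf("%s_%04d", g$groupId, seq_len(nrow(grid))),
            group = g$groupId,
            direction = g$direction,
            chrom = chrom,
            start = start, end = end,
            # under this parameterization a is the plateau the curve
            # attains on the e^{b(x-c)} -> 0 side: the late plateau for
            # rises (b < 0) and the early plateau for falls (b > 0), so
            # a = upper and d = lower for both directions
            a = grid$upper,
            b = if (rise) -abs(grid$iri) else abs(grid$iri),
            c = grid$inflection,
            d = 0,
            f = 1,
            stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

#' Noise-free coverage from the true sigmoid parameters
#'
#' `values[i, t] = sigmoidEval(truth[i], time[t])`; deterministic.
#'
#' @param spec a [defaultSimulationSpec()] list.
#' @return list with `coverage` (a [TimeCourseCoverage-class], stage
#'   `user_supplied`) and `truth` (the [simulationTruthTable()]).
#' @export
simulateTrueCoverage <- function(spec) {
    truth <- simulationTruthTable(spec)
    tt <- spec$timePoints
    if (length(tt) < 2L) stop("at least 2 time points are required")
    vals <- t(vapply(seq_len(nrow(truth)), function(i)
        sigmoidEval(truth[i, c("a", "b", "c", "d", "f")], tt),
        numeric(length(tt))))
    rownames(vals) <- truth$locus
    loci <- GRanges(truth$chrom,
                    IRanges(start = truth$start + 1L, end = truth$end))
    names(loci) <- truth$locus
    list(coverage = TimeCourseCoverage(vals, tt, loci,
                                       stage = "user_supplied"),
         truth = truth)
}

#' Add background noise to a coverage matrix
#'
#' Adds independent Poisson draws with the given mean to every cell
#' (per-time-point independent streams), emulating random background
#' sequencing merged into each time point.  `meanBackground = 0` is the
#' identity.  Reproducible under `seed`.
#'
#' @param tcc a [TimeCourseCoverage-class].
#' @param meanBackground non-negative Poisson mean.
#' @param seed integer seed.
#' @return a [TimeCourseCoverage-class] of the same stage.
#' @export
addNoise <- function(tcc, meanBackground = 1, seed = 1L) {
    if (meanBackground < 0) stop("meanBackground must be non-negative")
    vals <- covValues(tcc)
    if (meanBackground > 0) {
        set.seed(seed)
        for (t in seq_len(ncol(vals)))
            vals[, t] <- vals[, t] + stats::rpois(nrow(vals),
                                                  meanBackground)
    }
    TimeCourseCoverage(vals, timePoints(tcc), rowRanges(tcc),
                       stage = coverageStage(tcc))
}

#' Emit BED and per-time-point BAM fixtures realizing a simulation
#'
#' Writes the peak intervals as a BED file on the toy genome and, per
#' time point, a coordinate-sorted indexed BAM whose per-base depth over
#' each locus equals the (rounded) simulated coverage: `round(coverage)`
#' identical reads spanning the whole locus are stacked, so the
#' depth-quantization error is at most 0.5.
#'
#' @param sim output of [simulateTrueCoverage()] (optionally after
#'   [addNoise()] by replacing `sim$coverage`).
#' @param outdir output directory (created if needed).
#' @return list with `bed`, `bamFiles`, `truthFile` paths.
#' @export
emitFixtureFiles <- function(sim, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    truth <- sim$truth
    vals <- covValues(sim$coverage)
    tt <- timePoints(sim$coverage)
    bed <- file.path(outdir, "loci.bed")
    utils::write.table(
        data.frame(truth$chrom, truth$start, truth$end, truth$locus),
        bed, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    chromLen <- tapply(truth$end + 1000L, truth$chrom, max)
    bamFiles <- character(length(tt))
    for (t in seq_along(tt)) {
        sam <- file.path(outdir, sprintf("time_%02d.sam", t))
        con <- file(sam, "w")
        writeLines("@HD\tVN:1.6\tSO:coordinate", con)
        for (ch in names(chromLen))
            writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch,
                               as.integer(chromLen[[ch]])), con)
        ord <- order(truth$chrom, truth$start)
        for (i in ord) {
            nReads <- round(vals[i, t])
            if (nReads < 1) next
            L <- truth$end[i] - truth$start[i]
            writeLines(sprintf(
                "%s_r%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                truth$locus[i], seq_len(nReads), truth$chrom[i],
                truth$start[i] + 1L, L), con)
        }
        close(con)
        bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam),
                                overwrite = TRUE, indexDestination = TRUE)
        unlink(sam)
        bamFiles[t] <- bam
    }
    truthFile <- file.path(outdir, "truth.tsv")
    utils::write.table(truth, truthFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(bed = bed, bamFiles = bamFiles, truthFile = truthFile)
}

#' Score recovery of the true inflection point and categories
#'
#' Per-locus percent deviation `100 * |TTI_fit - c_true| / c_true`
#' between the fitted turnover time index and the true inflection point,
#' plus a confusion table of true direction vs. final category.  The TTI
#' of the segment matching the true direction is used (rise-segment TTI
#' for true rises); eliminated and flat loci contribute `NA` deviation
#' but are counted in the confusion table.
#'
#' @param resultSet a [TurnoverResultSet-class] from
#'   [analyzeTimeCourse()] on the simulated coverage.
#' @param truth the matching truth table.
#' @return list with `perLocus` (data.frame: locus, group, cTrue,
#'   ttiFit, deviationPct, final) and `confusion` (a table).
#' @export
evaluateRecovery <- function(resultSet, truth) {
    res <- locusResults(resultSet)
    if (!all(res$locus == truth$locus))
        stop("locus ids of results and truth table do not match")
    ttiFit <- ifelse(truth$direction == "rise", res$ttiRise, res$ttiFall)
    ttiFit[res$final %in% c("eliminated", "flat")] <- NA_real_
    dev <- 100 * abs(ttiFit - truth$c) / truth$c
    perLocus <- data.frame(locus = truth$locus, group = truth$group,
                           cTrue = truth$c, ttiFit = ttiFit,
                           deviationPct = dev, final = res$final,
                           stringsAsFactors = FALSE)
    confusion <- table(true = truth$direction, final = res$final)
    list(perLocus = perLocus, confusion = confusion)
}
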