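#' Classify and fit every locus of a coverage matrix
#'
#' The core driver: for each locus, predict the temporal category from
#' the extrema timing ([predictCategory()]), segment and fit sigmoids
#' ([segmentAndFit()]), fit the linear comparison, and verify or
#' eliminate ([verifyOrEliminate()]).  Loci are processed independently
#' in input order, so results are order-stable.
#'
#' @param tcc a normalized (or `user_supplied`) [TimeCourseCoverage-class].
#' @param thresholds a [turnoverThresholds()] list.
#' @param objective,fixF passed to [fitSigmoid()].
#' @return a [TurnoverResultSet-class].
#' @examples
#' spec <- defaultSimulationSpec("rise", nPerLevel = 1)
#' sim <- simulateTrueCoverage(spec)
#' rs <- analyzeTimeCourse(sim$coverage)
#' table(finalCategories(rs))
#' @export
analyzeTimeCourse <- function(tcc, thresholds = turnoverThresholds(),
                              objective = "least_squares", fixF = TRUE) {
    vals <- covValues(tcc)
    tt <- timePoints(tcc)
    n <- nrow(vals)
    fits <- vector("list", n)
    ids <- rownames(vals)
    for (i in seq_len(n)) {
        ys <- vals[i, ]
        pred <- predictCategory(ys, thresholds)
        lr <- segmentAndFit(tt, ys, pred, objective, fixF)
        fits[[i]] <- verifyOrEliminate(lr)
    }
    getp <- function(lr, nm) {
        if (length(lr$fits)) lr$fits[[1L]]$params[[nm]] else NA_real_
    }
    res <- DataFrame(
        locus = ids,
        predicted = vapply(fits, function(x) x$predicted, character(1)),
        final = vapply(fits, function(x) x$final, character(1)),
        ttiRise = vapply(fits, function(x) x$ttiRise, numeric(1)),
        ttiFall = vapply(fits, function(x) x$ttiFall, numeric(1)),
        a = vapply(fits, getp, numeric(1), nm = "a"),
        b = vapply(fits, getp, numeric(1), nm = "b"),
        c = vapply(fits, getp, numeric(1), nm = "c"),
        d = vapply(fits, getp, numeric(1), nm = "d"),
        f = vapply(fits, getp, numeric(1), nm = "f"),
        rss = vapply(fits, function(x)
            if (length(x$fits)) sum(vapply(x$fits, `[[`, numeric(1),
                                           "rss")) else NA_real_,
            numeric(1)),
        linearSlope = vapply(fits, function(x) x$linear$slope, numeric(1)),
        linearIntercept = vapply(fits, function(x) x$linear$intercept,
                                 numeric(1)),
        linearRss = vapply(fits, function(x) x$linear$rss, numeric(1)))
    new("TurnoverResultSet", coverage = tcc, results = res, fits = fits,
        thresholds = thresholds)
}

#' Run the full pipeline from files
#'
#' Orchestrates the chain: read BED loci; per replicate, extract raw
#' coverage from the BAM folder (one coordinate-sorted indexed BAM per
#' time point, lexicographic file order = time order) and scale each
#' time point by its background maximum; optionally subtract scaled
#' input; average replicates; classify/fit; write the results table.
#' Alternatively a pre-normalized counts table replaces the whole
#' normalization chain.
#'
#' @param bedPath BED file of loci (required with `bamDirs`).
#' @param bamDirs character vector of replicate folders of BAMs.
#' @param inputDirs optional folders of input-control BAMs.
#' @param countsPath optional pre-normalized counts table; mutually
#'   exclusive with `bamDirs`.
#' @param timePoints numeric time labels (required with `bamDirs`;
#'   defaults to `0, 1, 2, ...` over the files found).
#' @param scalePath optional two-column scale-value file (overrides
#'   background scaling).
#' @param thresholds,objective,fixF see [analyzeTimeCourse()].
#' @param nBackground,backgroundLength,seed background sampling controls
#'   (see [makeBackgroundIntervals()]); defaults: 10000 intervals of the
#'   median peak length.
#' @param outDir optional output directory for `results.tsv`.
#' @return a [TurnoverResultSet-class].
#' @export
runPipeline <- function(bedPath = NULL, bamDirs = NULL, inputDirs = NULL,
                        countsPath = NULL, timePoints = NULL,
                        scalePath = NULL,
                        thresholds = turnoverThresholds(),
                        objective = "least_squares", fixF = TRUE,
                        nBackground = 10000L, backgroundLength = NULL,
                        seed = 1L, outDir = NULL) {
    if (is.null(countsPath) == is.null(bamDirs) &&
        is.null(countsPath))
        stop("supply exactly one coverage source: bamDirs or countsPath")
    if (!is.null(countsPath) && !is.null(bamDirs))
        stop("supply exactly one coverage source: bamDirs or countsPath")
    if (!is.null(countsPath)) {
        tcc <- readCountsTable(countsPath)
    } else {
        if (is.null(bedPath)) stop("bedPath is required with bamDirs")
        loci <- readBedLoci(bedPath)
        if (length(loci) == 0L) stop("no loci in ", bedPath)
        reps <- list()
        for (r in seq_along(bamDirs)) {
            bams <- sort(list.files(bamDirs[r], pattern = "\\.bam$",
                                    full.names = TRUE))
            if (!length(bams)) stop("no BAM files in ", bamDirs[r])
            tt <- if (is.null(timePoints)) seq_along(bams) - 1
                  else timePoints
            if (length(tt) != length(bams))
                stop("need one BAM per time point in ", bamDirs[r])
            raw <- buildCoverageMatrix(bams, tt, loci)
            bgSet <- NULL
            if (!is.null(scalePath)) {
                scales <- readScaleValues(scalePath, tt)
            } else {
                genomeSizes <- .bamGenomeSizes(bams[1L])
                bgLen <- if (is.null(backgroundLength))
                    as.integer(stats::median(width(loci)))
                    else backgroundLength
                bgSet <- makeBackgroundIntervals(genomeSizes, loci,
                                                 n = nBackground,
                                                 length = bgLen,
                                                 seed = seed)
                scales <- vapply(bams, backgroundScale, numeric(1),
                                 background = bgSet)
            }
            scaled <- normalizeMatrix(raw, scales)
            if (!is.null(inputDirs)) {
                inBams <- sort(list.files(
                    inputDirs[min(r, length(inputDirs))],
                    pattern = "\\.bam$", full.names = TRUE))
                if (length(inBams) != length(bams))
                    stop("input folder must hold one BAM per time point")
                inRaw <- buildCoverageMatrix(inBams, tt, loci)
                # input has no expected peaks: scale by its maximum over
                # the sampled background plus the peak loci (a cheap
                # stand-in for the genome-wide maximum)
                inRegions <- if (is.null(bgSet)) loci
                             else c(GenomicRanges::granges(bgSet),
                                    GenomicRanges::granges(loci))
                inScales <- vapply(inBams, backgroundScale, numeric(1),
                                   background = inRegions)
                inScaled <- normalizeMatrix(inRaw, inScales)
                scaled <- subtractInput(scaled, inScaled)
            }
            reps[[r]] <- scaled
        }
        tcc <- averageReplicates(reps)
    }
    rs <- analyzeTimeCourse(tcc, thresholds, objective, fixF)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeResultsTable(rs, file.path(outDir, "results.tsv"))
    }
    rs
}

.bamGenomeSizes <- function(bam) {
    si <- GenomeInfoDb::seqinfo(Rsamtools::BamFile(bam))
    stats::setNames(GenomeInfoDb::seqlengths(si),
                    GenomeInfoDb::seqnames(si))
}

#' Per-locus 0-1 normalized heatmap matrix
#'
#' Min-max scales every locus's coverage row to `[0, 1]` (0 = the locus's
#' absolute minimum coverage, 1 = its absolute maximum) so loci of very
#' different depth can be compared by eye.  Constant rows map to all
#' zeros with a warning.
#'
#' @param resultSet a [TurnoverResultSet-class] (or a
#'   [TimeCourseCoverage-class]).
#' @return numeric matrix, loci x time points, in `[0, 1]`.
#' @export
heatmapMatrix <- function(resultSet) {
    vals <- covValues(resultSet)
    rng <- apply(vals, 1L, function(v) diff(range(v)))
    if (any(rng == 0))
        warning(sum(rng == 0), " constant loci mapped to all-zero rows")
    mins <- apply(vals, 1L, min)
    out <- (vals - mins) / ifelse(rng == 0, 1, rng)
    out[rng == 0, ] <- 0
    out
}

#' Category proportions and extrema-time incidence
#'
#' Proportion of loci per final category (sums to 1) and, per time point,
#' the incidence of the absolute minimum and maximum coverage (each
#' vector sums to 1; earliest index wins ties).
#'
#' @param resultSet a [TurnoverResultSet-class].
#' @return list with `proportions`, `minIncidence`, `maxIncidence`.
#' @export
categorySummary <- function(resultSet) {
    res <- locusResults(resultSet)
    if (!nrow(res)) stop("empty result set")
    vals <- covValues(resultSet)
    prop <- table(res$final) / nrow(res)
    iMin <- apply(vals, 1L, which.min)
    iMax <- apply(vals, 1L, which.max)
    tt <- timePoints(resultSet)
    inc <- function(idx) {
        v <- tabulate(idx, nbins = length(tt)) / length(idx)
        stats::setNames(v, as.character(tt))
    }
    list(proportions = prop, minIncidence = inc(iMin),
         maxIncidence = inc(iMax))
}

#' Histogram of turnover time indices
#'
#' Bins the TTI values of verified loci; with `byCategory = TRUE` the
#' counts are additionally split by final category (hills contribute
#' their rise-segment TTI, so signal-increase histograms compare hills
#' and rises on the same footing).
#'
#' @param resultSet a [TurnoverResultSet-class].
#' @param breaks bin breaks as for [base::cut()] (left-closed).
#' @param byCategory split by final category?
#' @return a table (or matrix of category x bin counts).
#' @export
ttiHistogram <- function(resultSet, breaks, byCategory = FALSE) {
    res <- locusResults(resultSet)
    tti <- ttiValues(resultSet)
    keep <- !is.na(tti)
    if (!any(keep)) {
        warning("no verified loci with a TTI; empty histogram")
        return(table(cut(numeric(), breaks, right = FALSE)))
    }
    bins <- cut(tti[keep], breaks, right = FALSE)
    if (byCategory)
        table(category = res$final[keep], bin = bins)
    else
        table(bins)
}

#' TTI distributions over genome features
#'
#' Intersects the loci with feature BED files (half-open interval
#' overlap, >= 1 bp); a locus contributes its TTI to every feature it
#' overlaps.
#'
#' @param resultSet a [TurnoverResultSet-class].
#' @param featureBeds named character vector (or list) of BED paths,
#'   `name = path`.
#' @return named list of numeric TTI samples, one per feature.
#' @export
featureTtiDistributions <- function(resultSet, featureBeds) {
    loci <- rowRanges(resultSet@coverage)
    tti <- ttiValues(resultSet)
    out <- list()
    for (nm in names(featureBeds)) {
        feat <- tryCatch(readBedLoci(featureBeds[[nm]]),
                         error = function(e) stop(
                             "cannot read feature '", nm, "': ",
                             conditionMessage(e)))
        hits <- GenomicRanges::findOverlaps(loci, feat)
        idx <- unique(S4Vectors::queryHits(hits))
        out[[nm]] <- tti[idx][!is.na(tti[idx])]
    }
    out
}

#' Per-locus log2 TTI ratio across two replicates
#'
#' For loci verified (non-eliminated, finite TTI) in both replicate
#' analyses, `log2(TTI_1 / TTI_2)`; a ratio distribution centered at 0
#' supports replicate reproducibility.
#'
#' @param rs1,rs2 [TurnoverResultSet-class] objects analyzed with the
#'   same loci and configuration.
#' @return list with `ratios` (named numeric) and `nExcluded` (loci
#'   dropped because eliminated or TTI-less in either replicate).
#' @export
replicateTtiRatio <- function(rs1, rs2) {
    id1 <- locusResults(rs1)$locus
    id2 <- locusResults(rs2)$locus
    common <- intersect(id1, id2)
    if (!length(common)) stop("replicates share no loci")
    t1 <- ttiValues(rs1)[match(common, id1)]
    t2 <- ttiValues(rs2)[match(common, id2)]
    ok <- is.finite(t1) & is.finite(t2) & t1 > 0 & t2 > 0
    list(ratios = stats::setNames(log2(t1[ok] / t2[ok]), common[ok]),
         nExcluded = sum(!ok))
}

#' Genomic TTI cluster bins
#'
#' Tiles the genome into fixed-width bins, assigns each verified locus to
#' the bin containing its midpoint, and reports per-bin locus count, mean
#' TTI and TTI standard deviation.  Bins holding at least `minLoci` loci
#' are flagged as clusters.
#'
#' @param resultSet a [TurnoverResultSet-class].
#' @param genomeSizes named vector of chromosome lengths.
#' @param binSize bin width in bp (default 200000).
#' @param minLoci cluster threshold (default 30).
#' @return data.frame: chrom, binStart, binEnd, count, meanTti, sdTti,
#'   isCluster.
#' @export
ttiClusterBins <- function(resultSet, genomeSizes, binSize = 200000L,
                           minLoci = 30L) {
    if (binSize <= 0) stop("binSize must be positive")
    loci <- rowRanges(resultSet@coverage)
    tti <- ttiValues(resultSet)
    keep <- !is.na(tti)
    mid <- (start(loci) + end(loci)) %/% 2L
    chrom <- as.character(seqnames(loci))
    bin <- mid %/% binSize
    key <- paste(chrom, bin)[keep]
    if (!any(keep))
        return(data.frame(chrom = character(), binStart = integer(),
                          binEnd = integer(), count = integer(),
                          meanTti = numeric(), sdTti = numeric(),
                          isCluster = logical()))
    agg <- split(tti[keep], key)
    parts <- strsplit(names(agg), " ")
    out <- data.frame(
        chrom = vapply(parts, `[`, character(1), 1L),
        binStart = as.integer(vapply(parts, `[`, character(1), 2L)) *
            binSize,
        count = lengths(agg),
        meanTti = vapply(agg, mean, numeric(1)),
        sdTti = vapply(agg, function(v)
            if (length(v) > 1L) stats::sd(v) else NA_real_, numeric(1)),
        stringsAsFactors = FALSE)
    out$binEnd <- out$binStart + binSize
    out$isCluster <- out$count >= minLoci
    rownames(out) <- NULL
    out[order(out$chrom, out$binStart),
        c("chrom", "binStart", "binEnd", "count", "meanTti", "sdTti",
          "isCluster")]
}
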