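#' Background-based depth scale for one time point
#'
#' The scale is the maximum mean read depth over a set of non-peak
#' ("background") intervals in the same sample; dividing a time point's
#' coverage by it corrects for sequencing-depth differences across the
#' time course while anchoring to true background signal rather than peak
#' signal.  If every background interval has zero depth the scale falls
#' back to 1 with a warning (no rescaling).
#'
#' @param alignmentFile BAM file for one time point.
#' @param background `GRanges` of non-peak intervals (must not overlap the
#'   peaks; see [makeBackgroundIntervals()]).
#' @param peaks optional `GRanges` of peak loci; when given, overlap with
#'   the background set is rejected.
#' @return a positive scalar.
#' @export
backgroundScale <- function(alignmentFile, background, peaks = NULL) {
    if (length(background) == 0L) stop("empty background interval set")
    if (!is.null(peaks) &&
        length(GenomicRanges::findOverlaps(background, peaks)) > 0L)
        stop("background intervals overlap peak loci")
    mx <- max(locusCoverage(alignmentFile, background))
    if (mx == 0) {
        warning("all background intervals have zero coverage; scale 1 used")
        return(1)
    }
    mx
}

#' Sample background (non-peak) intervals from a genome
#'
#' Draws `n` fixed-length intervals uniformly from the genome complement
#' of the peak set, reproducibly under `seed`.
#'
#' @param genomeSizes named integer vector of chromosome lengths.
#' @param peaks `GRanges` of peak loci to avoid.
#' @param n number of intervals to draw (default 10000).
#' @param length interval length in bp (a common choice is the median
#'   peak length).
#' @param seed integer seed for reproducibility.
#' @return a `GRanges` of `n` intervals disjoint from `peaks`.
#' @export
makeBackgroundIntervals <- function(genomeSizes, peaks, n = 10000L,
                                    length = 500L, seed = 1L) {
    genome <- GRanges(names(genomeSizes),
                      IRanges(1L, unname(as.integer(genomeSizes))))
    gaps <- GenomicRanges::setdiff(genome, peaks, ignore.strand = TRUE)
    gaps <- gaps[width(gaps) >= length]
    if (length(gaps) == 0L)
        stop("peak complement too small to host background intervals of ",
             length, " bp")
    # every admissible start position across all gaps, sampled uniformly
    nStarts <- width(gaps) - length + 1L
    total <- sum(as.numeric(nStarts))
    if (total < 1) stop("no admissible background start positions")
    set.seed(seed)
    pos <- sort(sample.int(total, n, replace = TRUE))
    cum <- cumsum(as.numeric(nStarts))
    gapIdx <- findInterval(pos - 1, cum) + 1L
    offset <- pos - c(0, cum)[gapIdx] - 1
    out <- GRanges(seqnames(gaps)[gapIdx],
                   IRanges(start = start(gaps)[gapIdx] + offset,
                           width = length))
    names(out) <- sprintf("bg_%d", seq_along(out))
    out
}

#' Scale a coverage matrix by per-time-point factors
#'
#' Divides each column by its scale factor; stage advances to `scaled`.
#'
#' @param tcc a [TimeCourseCoverage-class].
#' @param scales positive numeric vector, one factor per time point.
#' @return a scaled [TimeCourseCoverage-class].
#' @export
normalizeMatrix <- function(tcc, scales) {
    if (length(scales) != ncol(tcc))
        stop("one scale factor per time point is required")
    if (any(!is.finite(scales)) || any(scales <= 0))
        stop("scale factors must be positive")
    vals <- sweep(covValues(tcc), 2L, scales, "/")
    TimeCourseCoverage(vals, timePoints(tcc), rowRanges(tcc),
                       stage = "scaled")
}

#' Read per-time-point scale values from a two-column file
#'
#' Supports spike-in style normalization where the user supplies the
#' factors: a TSV with time label in column 1 and a positive factor in
#' column 2.
#'
#' @param path file path.
#' @param timePoints the experiment's time labels, used to check and
#'   order the factors.
#' @return numeric vector of factors in `timePoints` order.
#' @export
readScaleValues <- function(path, timePoints) {
    df <- utils::read.table(path, header = FALSE, sep = "\t")
    if (ncol(df) < 2L) stop("scale file needs 2 columns: time, factor")
    tt <- as.numeric(df[[1L]]); ff <- as.numeric(df[[2L]])
    idx <- match(as.numeric(timePoints), tt)
    if (any(is.na(idx)))
        stop("scale file missing factors for time points: ",
             paste(timePoints[is.na(idx)], collapse = ", "))
    out <- ff[idx]
    if (any(!is.finite(out)) || any(out <= 0))
        stop("scale factors must be positive")
    out
}

#' Subtract an input control, floored at zero
#'
#' Elementwise `max(experiment - input, 0)` of two scaled matrices of the
#' same shape; stage advances to `input_subtracted`.  (The floor can
#' produce zero inflation with poor-quality input files; no remedy is
#' applied — supply a pre-normalized counts table to use a different
#' strategy.)
#'
#' @param exp experiment [TimeCourseCoverage-class] (scaled).
#' @param input input-control [TimeCourseCoverage-class] (scaled by its
#'   genome-wide maximum, since input has no expected peaks).
#' @return an input-subtracted [TimeCourseCoverage-class].
#' @export
subtractInput <- function(exp, input) {
    if (!all(dim(exp) == dim(input)))
        stop("experiment and input matrices differ in shape")
    vals <- pmax(covValues(exp) - covValues(input), 0)
    TimeCourseCoverage(vals, timePoints(exp), rowRanges(exp),
                       stage = "input_subtracted")
}

#' Average replicate coverage matrices
#'
#' Elementwise arithmetic mean of any number of same-shape matrices;
#' stage advances to `replicate_mean`.
#'
#' @param tccList list of [TimeCourseCoverage-class] objects.
#' @return the mean [TimeCourseCoverage-class].
#' @export
averageReplicates <- function(tccList) {
    if (!length(tccList)) stop("no replicates supplied")
    d1 <- dim(tccList[[1L]])
    for (m in tccList)
        if (!all(dim(m) == d1)) stop("replicate matrices differ in shape")
    vals <- Reduce(`+`, lapply(tccList, covValues)) / length(tccList)
    TimeCourseCoverage(vals, timePoints(tccList[[1L]]),
                       rowRanges(tccList[[1L]]), stage = "replicate_mean")
}
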