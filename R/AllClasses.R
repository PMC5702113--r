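#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowRanges
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
NULL

.COVERAGE_STAGES <- c("raw", "scaled", "input_subtracted", "replicate_mean",
                      "user_supplied")

#' Time-course coverage container
#'
#' A loci x time-points matrix of non-negative sequencing coverage, carried
#' as a [SummarizedExperiment::RangedSummarizedExperiment] whose rows are the
#' loci (a `GRanges`) and whose columns are the ordered time points.  The
#' `stage` slot records the provenance of the values along the normalization
#' chain `raw -> scaled -> input_subtracted -> replicate_mean`; matrices read
#' from a pre-normalized counts table carry stage `user_supplied` and skip
#' the chain entirely.
#'
#' @slot stage character(1), one of `raw`, `scaled`, `input_subtracted`,
#'   `replicate_mean`, `user_supplied`.
#'
#' @seealso [TimeCourseCoverage()] for the constructor,
#'   [normalizeMatrix()], [subtractInput()], [averageReplicates()].
#' @export
setClass("TimeCourseCoverage",
    contains = "RangedSummarizedExperiment",
    slots = c(stage = "character"))

setValidity("TimeCourseCoverage", function(object) {
    msg <- character()
    if (length(object@stage) != 1L || !object@stage %in% .COVERAGE_STAGES)
        msg <- c(msg, sprintf("'stage' must be one of: %s",
                              paste(.COVERAGE_STAGES, collapse = ", ")))
    if (!"coverage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'coverage' is required")
    else {
        v <- SummarizedExperiment::assay(object, "coverage")
        if (any(!is.finite(v)) || any(v < 0))
            msg <- c(msg, "coverage values must be finite and non-negative")
    }
    if (!"time" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'time' is required")
    else {
        tt <- object$time
        if (!is.numeric(tt) || any(diff(tt) <= 0))
            msg <- c(msg, "time points must be numeric and strictly increasing")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TimeCourseCoverage object
#'
#' @param values numeric matrix, loci in rows and time points in columns;
#'   all entries must be finite and non-negative.
#' @param timePoints strictly increasing numeric vector, one entry per
#'   column of `values` (units as supplied by the experiment, e.g. minutes).
#' @param loci optional `GRanges` of the loci (one range per row).  When
#'   omitted, placeholder single-base ranges on chromosome `"unknown"` are
#'   used so that purely matrix-based workflows (pre-normalized counts)
#'   still fit in the container.
#' @param stage provenance label, see [TimeCourseCoverage-class].
#'
#' @return a [TimeCourseCoverage-class] object.
#' @examples
#' m <- matrix(runif(12), nrow = 3)
#' tcc <- TimeCourseCoverage(m, timePoints = c(0, 1, 2, 4))
#' covValues(tcc)
#' @export
TimeCourseCoverage <- function(values, timePoints, loci = NULL,
                               stage = "raw") {
    values <- as.matrix(values)
    if (length(timePoints) != ncol(values))
        stop("length(timePoints) must equal ncol(values)")
    if (is.null(loci)) {
        loci <- GRanges(rep("unknown", nrow(values)),
                        IRanges(start = seq_len(nrow(values)), width = 1L))
        if (!is.null(rownames(values)))
            names(loci) <- rownames(values)
    }
    if (length(loci) != nrow(values))
        stop("length(loci) must equal nrow(values)")
    if (is.null(rownames(values))) {
        rn <- names(loci)
        if (is.null(rn))
            rn <- sprintf("%s:%d-%d", as.character(seqnames(loci)),
                          start(loci) - 1L, end(loci))
        rownames(values) <- rn
    }
    colnames(values) <- as.character(timePoints)
    se <- SummarizedExperiment(
        assays = list(coverage = values),
        rowRanges = loci,
        colData = DataFrame(time = as.numeric(timePoints)))
    new("TimeCourseCoverage", se, stage = stage)
}

#' Result container for a time-course turnover analysis
#'
#' Holds one row of modeling results per input locus (category prediction,
#' verification outcome, fitted sigmoid parameters with standard errors,
#' turnover time indices, and the linear comparison fit), together with the
#' coverage matrix the analysis ran on and the thresholds applied.
#'
#' @slot coverage the [TimeCourseCoverage-class] analyzed.
#' @slot results a `DataFrame` with one row per locus (see
#'   [locusResults()]).
#' @slot fits list parallel to the rows of `results`; each element is the
#'   full per-locus result list as returned by [segmentAndFit()].
#' @slot thresholds the [turnoverThresholds()] list used.
#' @export
setClass("TurnoverResultSet",
    slots = c(coverage = "TimeCourseCoverage",
              results = "DataFrame",
              fits = "list",
              thresholds = "list"))

setValidity("TurnoverResultSet", function(object) {
    msg <- character()
    if (nrow(object@results) != length(object@fits))
        msg <- c(msg, "results rows and fits length differ")
    if (nrow(object@results) != nrow(object@coverage))
        msg <- c(msg, "one result row per coverage locus is required")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TimeCourseCoverage", function(object) {
    cat(sprintf("TimeCourseCoverage: %d loci x %d time points [stage: %s]\n",
                nrow(object), ncol(object), object@stage))
    tt <- object$time
    cat("  time points:", paste(format(tt, trim = TRUE), collapse = ", "),
        "\n")
})

setMethod("show", "TurnoverResultSet", function(object) {
    cat(sprintf("TurnoverResultSet: %d loci\n", nrow(object@results)))
    tab <- table(object@results$final)
    for (nm in names(tab))
        cat(sprintf("  %-16s %d\n", nm, tab[[nm]]))
})
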