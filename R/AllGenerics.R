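#' Accessors for coverage and result containers
#'
#' `covValues()` returns the coverage matrix, `timePoints()` the ordered
#' numeric time labels, `coverageStage()` the provenance label,
#' `locusResults()` the per-locus results `DataFrame`, `locusFits()` the
#' list of full per-locus fit objects, `finalCategories()` the verified
#' category per locus, and `ttiValues()` the turnover time index per locus
#' (the rise-segment TTI for hills, the fall-segment TTI for valleys, `NA`
#' for eliminated or flat loci).
#'
#' @param x a [TimeCourseCoverage-class] or [TurnoverResultSet-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("covValues", function(x) standardGeneric("covValues"))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname accessors
#' @export
setGeneric("coverageStage", function(x) standardGeneric("coverageStage"))

#' @rdname accessors
#' @export
setGeneric("locusResults", function(x) standardGeneric("locusResults"))

#' @rdname accessors
#' @export
setGeneric("locusFits", function(x) standardGeneric("locusFits"))

#' @rdname accessors
#' @export
setGeneric("finalCategories", function(x) standardGeneric("finalCategories"))

#' @rdname accessors
#' @export
setGeneric("ttiValues", function(x) standardGeneric("ttiValues"))

#' @rdname accessors
#' @export
setMethod("covValues", "TimeCourseCoverage",
    function(x) SummarizedExperiment::assay(x, "coverage"))

#' @rdname accessors
#' @export
setMethod("timePoints", "TimeCourseCoverage", function(x) x$time)

#' @rdname accessors
#' @export
setMethod("coverageStage", "TimeCourseCoverage", function(x) x@stage)

#' @rdname accessors
#' @export
setMethod("covValues", "TurnoverResultSet",
    function(x) covValues(x@coverage))

#' @rdname accessors
#' @export
setMethod("timePoints", "TurnoverResultSet",
    function(x) timePoints(x@coverage))

#' @rdname accessors
#' @export
setMethod("locusResults", "TurnoverResultSet", function(x) x@results)

#' @rdname accessors
#' @export
setMethod("locusFits", "TurnoverResultSet", function(x) x@fits)

#' @rdname accessors
#' @export
setMethod("finalCategories", "TurnoverResultSet",
    function(x) x@results$final)

#' @rdname accessors
#' @export
setMethod("ttiValues", "TurnoverResultSet", function(x) {
    res <- x@results
    fallFirst <- res$final %in% c("fall", "undefined_fall", "valley")
    out <- ifelse(fallFirst, res$ttiFall, res$ttiRise)
    out[is.na(out)] <- ifelse(fallFirst, res$ttiRise, res$ttiFall)[is.na(out)]
    out[res$final == "eliminated"] <- NA_real_
    out
})
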