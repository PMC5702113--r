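#' Read loci of interest from a BED file
#'
#' Accepts standard BED with three or more whitespace/tab-separated
#' columns, 0-based half-open coordinates.  `track`, `browser` and `#`
#' comment lines are skipped.  The optional 4th column becomes the locus
#' name; unnamed loci get `"chrom:start-end"`.  Malformed lines
#' (non-integer coordinates, `end <= start`, negative start) raise an
#' error naming the offending line number.
#'
#' @param path path to a BED file.
#' @return a `GRanges`, in file order, with names.  Note `GRanges` uses
#'   1-based closed coordinates internally; the BED convention is restored
#'   on output (see [writeResultsTable()]).
#' @export
readBedLoci <- function(path) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
    idx <- which(keep)
    if (!length(idx))
        return(GRanges())
    chrom <- character(length(idx)); s <- integer(length(idx))
    e <- integer(length(idx)); nm <- character(length(idx))
    for (k in seq_along(idx)) {
        i <- idx[k]
        f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
        if (length(f) < 3L)
            stop(sprintf("BED line %d: fewer than 3 columns", i))
        st <- suppressWarnings(as.integer(f[2L]))
        en <- suppressWarnings(as.integer(f[3L]))
        if (is.na(st) || is.na(en))
            stop(sprintf("BED line %d: non-integer coordinates", i))
        if (st < 0L)
            stop(sprintf("BED line %d: negative start", i))
        if (en <= st)
            stop(sprintf("BED line %d: end <= start", i))
        chrom[k] <- f[1L]; s[k] <- st; e[k] <- en
        nm[k] <- if (length(f) >= 4L) f[4L] else
            sprintf("%s:%d-%d", f[1L], st, en)
    }
    gr <- GRanges(chrom, IRanges(start = s + 1L, end = e))
    names(gr) <- nm
    gr
}

#' Per-locus mean read depth from a BAM file
#'
#' Mean per-base depth over each locus (sum of per-base depths divided by
#' the locus length; bases without reads contribute zero).  Reads are
#' counted CIGAR-aware from their aligned spans; secondary, supplementary
#' and unmapped records are excluded; strand is ignored.
#'
#' @param alignmentFile path to a coordinate-sorted, indexed BAM file.
#' @param loci a `GRanges` of loci (any length >= 1).
#' @return numeric vector of mean depths, one per locus.  Loci on
#'   chromosomes absent from the BAM header get 0 with a warning (a signal
#'   of a genome-assembly mismatch).
#' @export
locusCoverage <- function(alignmentFile, loci) {
    bf <- Rsamtools::BamFile(alignmentFile)
    if (!file.exists(paste0(alignmentFile, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", alignmentFile)))
        stop("BAM index not found for ", alignmentFile)
    hdr <- GenomeInfoDb::seqinfo(bf)
    known <- as.character(seqnames(loci)) %in%
        GenomeInfoDb::seqnames(hdr)
    out <- numeric(length(loci))
    if (any(!known))
        warning(sprintf(
            "%d loci on chromosomes absent from the BAM header (%s): %s",
            sum(!known), alignmentFile,
            paste(unique(as.character(seqnames(loci))[!known]),
                  collapse = ", ")))
    if (!any(known)) return(out)
    q <- loci[known]
    GenomeInfoDb::seqlevels(q) <- GenomeInfoDb::seqlevelsInUse(q)
    flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE,
                                   isUnmappedQuery = FALSE)
    param <- Rsamtools::ScanBamParam(which = range(q), flag = flag)
    aln <- GenomicAlignments::readGAlignments(bf, param = param)
    cov <- GenomicAlignments::coverage(aln)
    for (k in seq_along(q)) {
        chr <- as.character(seqnames(q))[k]
        rle <- cov[[chr]]
        lo <- start(q)[k]; hi <- min(end(q)[k], length(rle))
        # window sum over the coverage Rle; bases past the last read are 0
        tot <- if (hi >= lo)
            sum(as.numeric(IRanges::Views(rle, lo, hi)[[1L]])) else 0
        out[which(known)[k]] <- tot / width(q)[k]
    }
    out
}

#' Build a raw coverage matrix across a time course
#'
#' Computes [locusCoverage()] for every locus against one BAM per time
#' point, yielding a `raw`-stage [TimeCourseCoverage-class].
#'
#' @param bamFiles character vector of BAM paths, one per time point, in
#'   time order.
#' @param timePoints strictly increasing numeric times (same length).
#' @param loci a `GRanges` of loci (non-empty).
#' @return a [TimeCourseCoverage-class] with stage `raw`.
#' @export
buildCoverageMatrix <- function(bamFiles, timePoints, loci) {
    if (length(loci) == 0L) stop("no loci supplied")
    if (length(bamFiles) != length(timePoints))
        stop("one BAM file per time point is required")
    vals <- matrix(0, nrow = length(loci), ncol = length(bamFiles))
    for (t in seq_along(bamFiles)) {
        vals[, t] <- tryCatch(
            locusCoverage(bamFiles[t], loci),
            error = function(e) stop(sprintf(
                "coverage extraction failed at time point %s (%s): %s",
                timePoints[t], bamFiles[t], conditionMessage(e))))
    }
    TimeCourseCoverage(vals, timePoints, loci, stage = "raw")
}

#' Read a pre-normalized counts table
#'
#' A delimited table whose header row holds numeric time labels and whose
#' first column holds locus ids.  Matrices read this way carry stage
#' `user_supplied`; the normalization chain is skipped for them, so users
#' can apply DiffBind/DESeq2/edgeR-style normalization upstream.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator (default tab; `","` for CSV).
#' @return a [TimeCourseCoverage-class] with stage `user_supplied`.
#' @export
readCountsTable <- function(path, sep = "\t") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, row.names = 1L)
    tt <- suppressWarnings(as.numeric(colnames(df)))
    if (any(is.na(tt)))
        stop("counts table header must hold numeric time labels; got: ",
             paste(colnames(df)[is.na(tt)], collapse = ", "))
    m <- as.matrix(df)
    if (any(!is.finite(m)))
        stop("counts table contains non-numeric or missing values")
    if (any(m < 0)) {
        bad <- which(m < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("negative count at locus '%s', time %s",
                     rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
    }
    TimeCourseCoverage(m, tt, stage = "user_supplied")
}

#' Write the per-locus modeling results table
#'
#' Tab-separated, one row per locus and per fitted sigmoid segment (so
#' verified hills and valleys contribute two rows sharing a locus id, one
#' per segment).  Columns: locus id, BED coordinates (0-based half-open,
#' echoing the input convention), predicted and final category, segment
#' (`rise`/`fall`), the sigmoid parameters `a`, `b` (IRI), `c`, `d`, `f`
#' with per-parameter standard errors, TTI, residual sum of squares, the
#' linear comparison fit (slope, intercept, rss) and the eliminated flag.
#' Eliminated loci are retained (auditability) with final category
#' `eliminated`.
#'
#' @param resultSet a [TurnoverResultSet-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeResultsTable <- function(resultSet, path) {
    df <- resultsLongTable(resultSet)
    ok <- tryCatch({
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        TRUE
    }, error = function(e) stop("cannot write results table to ", path,
                                ": ", conditionMessage(e)))
    invisible(path)
}

#' Long-format results table (one row per fitted segment)
#'
#' @inheritParams writeResultsTable
#' @return a `data.frame`, see [writeResultsTable()] for the columns.
#' @export
resultsLongTable <- function(resultSet) {
    res <- locusResults(resultSet)
    fits <- locusFits(resultSet)
    gr <- rowRanges(resultSet@coverage)
    rows <- vector("list", length(fits))
    for (i in seq_along(fits)) {
        lf <- fits[[i]]
        segs <- lf$fits
        if (length(segs) == 0L) {
            rows[[i]] <- .resultRow(res, gr, i, NULL, NA_character_)
            next
        }
        segRows <- vector("list", length(segs))
        for (s in seq_along(segs)) {
            segName <- if (segs[[s]]$direction == "increasing")
                "rise" else "fall"
            segRows[[s]] <- .resultRow(res, gr, i, segs[[s]], segName)
        }
        rows[[i]] <- do.call(rbind, segRows)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.resultRow <- function(res, gr, i, fit, segment) {
    se <- if (is.null(fit)) stats::setNames(rep(NA_real_, 4),
                                            c("a", "b", "c", "d"))
          else fit$stdErrors
    seGet <- function(nm) if (nm %in% names(se)) unname(se[nm]) else NA_real_
    data.frame(
        locus = res$locus[i],
        chrom = as.character(seqnames(gr))[i],
        start = start(gr)[i] - 1L,    # back to BED 0-based
        end = end(gr)[i],
        predicted = res$predicted[i],
        final = res$final[i],
        segment = if (is.null(fit)) NA_character_ else segment,
        a = if (is.null(fit)) NA_real_ else fit$params$a,
        b = if (is.null(fit)) NA_real_ else fit$params$b,
        c = if (is.null(fit)) NA_real_ else fit$params$c,
        d = if (is.null(fit)) NA_real_ else fit$params$d,
        f = if (is.null(fit)) NA_real_ else fit$params$f,
        se_a = seGet("a"), se_b = seGet("b"), se_c = seGet("c"),
        se_d = seGet("d"),
        tti = if (is.null(fit)) NA_real_ else fit$tti,
        rss = if (is.null(fit)) NA_real_ else fit$rss,
        linear_slope = res$linearSlope[i],
        linear_intercept = res$linearIntercept[i],
        linear_rss = res$linearRss[i],
        eliminated = res$final[i] == "eliminated",
        stringsAsFactors = FALSE)
}
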