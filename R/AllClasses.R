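#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqnames seqlengths
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges rowRanges<-
#'   colData colData<- assay assay<- assayNames
NULL

#' Fixed-width genomic bin grid
#'
#' A \code{BinSet} is a \linkS4class{GRanges} holding an ordered grid of
#' non-overlapping, fixed-width genomic bins -- the counting unit of the whole
#' pipeline -- together with two metadata columns: \code{gc}, the fraction of
#' G/C bases among unambiguous bases in the bin (\code{NA} until computed), and
#' \code{masked}, a logical flag marking bins excluded from every regression
#' and test (e.g. bins with too many ambiguous reference bases).
#'
#' Bins within a chromosome are sorted, contiguous from position 0 and all of
#' identical width (terminal partial bins are never emitted). Externally --
#' in the BED-like bin table -- coordinates are 0-based half-open; internally
#' the usual 1-based closed \code{GRanges} convention is used, and the
#' conversion happens only at the I/O boundary.
#'
#' @slot binWidth integer(1), the common bin width in bp.
#' @seealso \code{\link{makeBins}}, \code{\link{gcPerBin}}
#' @export
setClass("BinSet",
    contains = "GRanges",
    representation(binWidth = "integer"))

.validBinSet <- function(object) {
    msg <- NULL
    w <- object@binWidth
    if (length(w) != 1L || is.na(w) || w < 1L)
        msg <- c(msg, "binWidth must be a single positive integer")
    mc <- mcols(object)
    if (!all(c("gc", "masked") %in% colnames(mc)))
        return(c(msg, "metadata columns 'gc' and 'masked' are required"))
    gc <- mc$gc
    if (!is.numeric(gc) || any(gc < 0 | gc > 1, na.rm = TRUE))
        msg <- c(msg, "'gc' must be numeric in [0, 1] or NA")
    if (!is.logical(mc$masked) || anyNA(mc$masked))
        msg <- c(msg, "'masked' must be logical without NA")
    if (length(object)) {
        if (!all(GenomicRanges::width(object) == w))
            msg <- c(msg, "all bins must have width == binWidth")
        ss <- split(GenomicRanges::start(object),
                    as.character(seqnames(object)))
        bad <- vapply(ss, function(s)
            is.unsorted(s, strictly = TRUE) ||
            s[1L] != 1L || any(diff(s) != w), logical(1))
        if (any(bad))
            msg <- c(msg, paste0("bins must be sorted, contiguous from 0 and ",
                "non-overlapping on: ",
                paste(names(ss)[bad], collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("BinSet", .validBinSet)

#' Binned count matrix with library metadata
#'
#' A \code{MinkCountSet} extends
#' \linkS4class{RangedSummarizedExperiment}: rows are the bins of a
#' \linkS4class{BinSet} (available through \code{rowRanges}), columns are
#' sequencing libraries, and the \code{"counts"} assay holds non-negative
#' read counts (raw counts are integers; a GC-corrected assay
#' \code{"corrected"} holds reals). Column data carries the per-library
#' metadata the caller needs:
#' \describe{
#'   \item{\code{sample_id}}{plasma sample the library was prepared from
#'     (several libraries may share one sample).}
#'   \item{\code{karyotype}}{cytogenetic label, e.g. \code{"46,XY"} or
#'     \code{"47,XX,+21"}; trisomies are parsed from \code{"+<chrom>"} tokens.}
#'   \item{\code{role}}{\code{"reference"} (karyotypically normal panel
#'     member) or \code{"test"}.}
#'   \item{\code{fetal_fraction}}{fraction of fetal cell-free DNA in [0, 1],
#'     or \code{NA} when unknown.}
#' }
#'
#' @seealso \code{\link{MinkCountSet}} (constructor), \code{\link{callCohort}}
#' @export
setClass("MinkCountSet",
    contains = "RangedSummarizedExperiment")

.validMinkCountSet <- function(object) {
    msg <- NULL
    if (!is(rowRanges(object), "BinSet"))
        msg <- c(msg, "rowRanges must be a BinSet")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return(c(msg, "an assay named 'counts' is required"))
    cnt <- assay(object, "counts")
    if (any(cnt < 0, na.rm = TRUE))
        msg <- c(msg, "counts must be non-negative")
    cd <- colData(object)
    need <- c("sample_id", "karyotype", "role", "fetal_fraction")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "library ids (colnames) must be present and unique")
    if ("role" %in% colnames(cd) &&
        !all(cd$role %in% c("reference", "test")))
        msg <- c(msg, "role must be 'reference' or 'test'")
    if ("fetal_fraction" %in% colnames(cd)) {
        ff <- cd$fetal_fraction
        if (any(ff < 0 | ff > 1, na.rm = TRUE))
            msg <- c(msg, "fetal_fraction must lie in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("MinkCountSet", .validMinkCountSet)

#' Construct a MinkCountSet
#'
#' Bundle a bins-by-libraries count matrix, its \linkS4class{BinSet} and the
#' per-library metadata into a validated container.
#'
#' @param counts numeric matrix, bins in rows (matching \code{bins}) and
#'   libraries in columns; column names are the library ids.
#' @param bins a \linkS4class{BinSet} with one range per count row.
#' @param meta a \code{data.frame} (or \code{DataFrame}) with one row per
#'   library, rownames (or a \code{library_id} column) matching
#'   \code{colnames(counts)}, and columns \code{sample_id}, \code{karyotype},
#'   \code{role}, \code{fetal_fraction}; missing optional columns are filled
#'   with defaults (\code{sample_id = library_id}, \code{karyotype = NA},
#'   \code{role = "test"}, \code{fetal_fraction = NA}). Extra columns are kept
#'   as covariates.
#'
#' @return A \linkS4class{MinkCountSet}.
#' @examples
#' bins <- makeBins(c(chr1 = 200000), width = 50000)
#' binGC(bins) <- rep(0.4, 4)
#' m <- matrix(5L, nrow = 4, ncol = 2, dimnames = list(NULL, c("L1", "L2")))
#' mcs <- MinkCountSet(m, bins)
#' mcs
#' @export
MinkCountSet <- function(counts, bins, meta = NULL) {
    counts <- as.matrix(counts)
    rownames(counts) <- NULL
    if (is.null(colnames(counts)))
        stop("'counts' must have column names (library ids)")
    if (nrow(counts) != length(bins))
        stop(sprintf("count matrix has %d rows but the bin set has %d bins",
                     nrow(counts), length(bins)))
    ids <- colnames(counts)
    if (is.null(meta)) {
        meta <- data.frame(row.names = ids)
    } else {
        meta <- as.data.frame(meta)
        if ("library_id" %in% colnames(meta)) {
            rownames(meta) <- meta$library_id
            meta$library_id <- NULL
        }
        if (!all(ids %in% rownames(meta)))
            stop("metadata rows missing for library id(s): ",
                 paste(setdiff(ids, rownames(meta)), collapse = ", "))
        meta <- meta[ids, , drop = FALSE]
    }
    if (is.null(meta$sample_id)) meta$sample_id <- ids
    if (is.null(meta$karyotype)) meta$karyotype <- NA_character_
    if (is.null(meta$role)) meta$role <- "test"
    if (is.null(meta$fetal_fraction)) meta$fetal_fraction <- NA_real_
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowRanges = bins,
        colData = DataFrame(meta))
    new("MinkCountSet", se)
}

setMethod("show", "BinSet", function(object) {
    cat(sprintf("BinSet: %d bins of %d bp on %d sequence(s)\n",
                length(object), object@binWidth,
                length(unique(as.character(seqnames(object))))))
    gc <- mcols(object)$gc
    cat(sprintf("  gc: %s; masked bins: %d\n",
                if (all(is.na(gc))) "not computed" else
                    sprintf("median %.3f (%d NA)", stats::median(gc, na.rm = TRUE),
                            sum(is.na(gc))),
                sum(mcols(object)$masked)))
    invisible(callNextMethod())
})

setMethod("show", "MinkCountSet", function(object) {
    cat(sprintf("MinkCountSet: %d bins x %d libraries\n",
                nrow(object), ncol(object)))
    cat(sprintf("  roles: %d reference, %d test; assays: %s\n",
                sum(colData(object)$role == "reference"),
                sum(colData(object)$role == "test"),
                paste(SummarizedExperiment::assayNames(object),
                      collapse = ", ")))
    invisible(NULL)
})
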