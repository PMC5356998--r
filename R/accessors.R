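#' Accessors for BinSet and MinkCountSet
#'
#' Small accessor functions so downstream code never touches slots directly.
#'
#' @param x a \linkS4class{BinSet} or \linkS4class{MinkCountSet}.
#' @param value replacement value.
#' @return \code{binWidth}: the bin width in bp. \code{binGC},
#'   \code{binMasked}: per-bin GC fraction / mask flag. \code{binSet}: the
#'   \linkS4class{BinSet} behind a \linkS4class{MinkCountSet}.
#'   \code{libraryMeta}: the per-library metadata as a \code{DataFrame}.
#'   \code{countsMatrix}: the raw counts assay, bins x libraries.
#'   \code{correctedMatrix}: the GC-corrected assay (error if absent).
#' @name accessors
NULL

#' @rdname accessors
#' @export
binWidth <- function(x) {
    if (is(x, "MinkCountSet")) x <- rowRanges(x)
    x@binWidth
}

#' @rdname accessors
#' @export
binGC <- function(x) {
    if (is(x, "MinkCountSet")) x <- rowRanges(x)
    mcols(x)$gc
}

#' @rdname accessors
#' @export
`binGC<-` <- function(x, value) {
    mcols(x)$gc <- value
    validObject(x)
    x
}

#' @rdname accessors
#' @export
binMasked <- function(x) {
    if (is(x, "MinkCountSet")) x <- rowRanges(x)
    mcols(x)$masked
}

#' @rdname accessors
#' @export
`binMasked<-` <- function(x, value) {
    mcols(x)$masked <- value
    validObject(x)
    x
}

#' @rdname accessors
#' @export
binSet <- function(x) rowRanges(x)

#' @rdname accessors
#' @export
libraryMeta <- function(x) colData(x)

#' @rdname accessors
#' @export
countsMatrix <- function(x) assay(x, "counts")

#' @rdname accessors
#' @export
correctedMatrix <- function(x) {
    if (!"corrected" %in% SummarizedExperiment::assayNames(x))
        stop("no 'corrected' assay; run gcCorrect() first")
    assay(x, "corrected")
}

#' Bin ids in "chrom:start-end" form (0-based half-open, as in the bin table)
#' @param bins a \linkS4class{BinSet}.
#' @return character vector of bin identifiers.
#' @export
binIds <- function(bins) {
    sprintf("%s:%d-%d", as.character(seqnames(bins)),
            GenomicRanges::start(bins) - 1L, GenomicRanges::end(bins))
}

#' Chromosomes carrying an extra copy according to a karyotype label
#'
#' Parses cytogenetic labels of the form \code{"47,XX,+21"}: every
#' \code{"+<name>"} token marks a trisomic chromosome. Labels without such
#' tokens (e.g. \code{"46,XY"}) are karyotypically normal. \code{NA} labels
#' yield \code{NA}.
#'
#' @param karyotype character vector of labels.
#' @param prefix chromosome-name prefix used by the bin grid (default
#'   \code{"chr"}), so \code{"+21"} maps to \code{"chr21"}.
#' @return A list (one element per label) of character vectors of trisomic
#'   chromosome names (possibly empty), or \code{NA} for \code{NA} labels.
#' @examples
#' karyotypeTrisomies(c("46,XY", "47,XX,+21", NA))
#' @export
karyotypeTrisomies <- function(karyotype, prefix = "chr") {
    lapply(karyotype, function(k) {
        if (is.na(k)) return(NA_character_)
        tok <- regmatches(k, gregexpr("\\+[0-9XY]+", k))[[1]]
        if (!length(tok)) return(character(0))
        paste0(prefix, sub("^\\+", "", tok))
    })
}

#' Is a library trisomic for a given chromosome?
#' @param karyotype character vector of karyotype labels.
#' @param chrom single chromosome name (e.g. \code{"chr21"}).
#' @param prefix chromosome-name prefix (see \code{\link{karyotypeTrisomies}}).
#' @return logical vector (\code{NA} where the label is \code{NA}).
#' @export
isTrisomic <- function(karyotype, chrom, prefix = "chr") {
    vapply(karyotypeTrisomies(karyotype, prefix = prefix),
           function(tr) if (length(tr) == 1L && is.na(tr[1L])) NA
                        else chrom %in% tr,
           logical(1))
}
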