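#' Count aligned reads into bins for one library
#'
#' Consumes alignment position records and produces one column of a bin count
#' matrix. Records flagged non-unique or carrying any mismatch are discarded
#' ("aligned uniquely and exactly"); optional duplicate removal keeps at most
#' one record per (chromosome, position, strand) -- the standard single-end
#' duplicate criterion. A read is assigned to the bin containing its 0-based
#' leftmost position (input positions are 1-based, SAM convention; the
#' conversion happens here and only here). Records on chromosomes absent from
#' the bin grid, or beyond the last complete bin of their chromosome, are
#' tallied in the report rather than causing an error. Input order is
#' irrelevant.
#'
#' @param records a \code{data.frame} of alignment records with columns
#'   \code{chrom}, \code{pos} (1-based leftmost mapped position),
#'   \code{strand} (\code{"+"}/\code{"-"}); optional columns
#'   \code{mismatches} (integer, default 0) and \code{unique} (logical,
#'   default \code{TRUE}).
#' @param bins a \linkS4class{BinSet}.
#' @param dedupe remove duplicates (default \code{TRUE}).
#' @return A list with \code{counts} (integer vector, one entry per bin) and
#'   \code{report}, a named integer vector with components \code{total},
#'   \code{nonunique}, \code{mismatched}, \code{duplicate},
#'   \code{unknown_chrom}, \code{outside_bins} and \code{retained};
#'   \code{sum(counts) == report["retained"]} always holds.
#' @examples
#' bins <- makeBins(c(chr1 = 100000), width = 50000)
#' rec <- data.frame(chrom = "chr1", pos = c(100, 100, 50001),
#'                   strand = c("+", "+", "-"))
#' countLibrary(rec, bins)
#' @export
countLibrary <- function(records, bins, dedupe = TRUE) {
    records <- as.data.frame(records)
    need <- c("chrom", "pos", "strand")
    miss <- setdiff(need, colnames(records))
    if (length(miss))
        stop("records lack column(s): ", paste(miss, collapse = ", "))
    if (any(records$pos < 1))
        stop("alignment positions must be >= 1 (1-based)")
    n0 <- nrow(records)
    if (is.null(records$mismatches)) records$mismatches <- 0L
    if (is.null(records$unique)) records$unique <- TRUE

    rep_ <- c(total = n0, nonunique = 0L, mismatched = 0L, duplicate = 0L,
              unknown_chrom = 0L, outside_bins = 0L, retained = 0L)

    keep <- records$unique
    rep_["nonunique"] <- sum(!keep)
    rec <- records[keep, , drop = FALSE]
    ok <- rec$mismatches == 0L
    rep_["mismatched"] <- sum(!ok)
    rec <- rec[ok, , drop = FALSE]
    if (dedupe && nrow(rec)) {
        key <- paste(rec$chrom, rec$pos, rec$strand, sep = "\r")
        dup <- duplicated(key)
        rep_["duplicate"] <- sum(dup)
        rec <- rec[!dup, , drop = FALSE]
    }

    width <- binWidth(bins)
    chr <- as.character(seqnames(bins))
    nbins_per <- table(factor(chr, levels = unique(chr)))
    offset <- c(0L, cumsum(as.integer(nbins_per)))[seq_along(nbins_per)]
    names(offset) <- names(nbins_per)

    counts <- integer(length(bins))
    if (nrow(rec)) {
        known <- rec$chrom %in% names(offset)
        rep_["unknown_chrom"] <- sum(!known)
        rec <- rec[known, , drop = FALSE]
        if (nrow(rec)) {
            local_bin <- (rec$pos - 1L) %/% width          # 0-based start
            inside <- local_bin < as.integer(nbins_per[rec$chrom])
            rep_["outside_bins"] <- sum(!inside)
            idx <- offset[rec$chrom[inside]] + local_bin[inside] + 1L
            tab <- tabulate(idx, nbins = length(bins))
            counts <- counts + tab
        }
    }
    rep_["retained"] <- sum(counts)
    list(counts = counts, report = rep_)
}

#' Alignment records from a BAM file
#'
#' Optional adapter turning a coordinate-indexed BAM into the plain record
#' stream \code{\link{countLibrary}} consumes; the counting core never
#' depends on it. Mapping quality > 0 stands in for "aligned uniquely" and an
#' \code{NM} tag of 0 for "without mismatch".
#'
#' @param path path to a BAM file.
#' @return A \code{data.frame} of records (\code{chrom}, \code{pos},
#'   \code{strand}, \code{mismatches}, \code{unique}).
#' @export
alignmentsFromBam <- function(path) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
        stop("alignmentsFromBam() needs the Rsamtools package")
    param <- Rsamtools::ScanBamParam(
        what = c("rname", "pos", "strand", "mapq"),
        tag = "NM",
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    b <- Rsamtools::scanBam(path, param = param)[[1]]
    nm <- b$tag$NM
    if (is.null(nm)) nm <- rep(0L, length(b$pos))
    nm[is.na(nm)] <- 0L
    data.frame(
        chrom = as.character(b$rname),
        pos = b$pos,
        strand = as.character(b$strand),
        mismatches = nm,
        unique = b$mapq > 0L)
}
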