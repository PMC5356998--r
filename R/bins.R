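#' Divide chromosomes into non-overlapping fixed-width bins
#'
#' Each chromosome is tiled with non-overlapping windows of \code{width} bp
#' starting at position 0; a terminal stretch shorter than \code{width} is
#' dropped, not truncated, so every bin has identical width (unequal bins
#' would bias both the GC regression and the count expectations). Bins are
#' ordered by the input chromosome order, then by start; no natural-sort
#' reordering is applied.
#'
#' @param seqlens named numeric vector of chromosome lengths in bp.
#' @param width bin width in bp (default 50000, i.e. the 50 kb windows used
#'   for maternal-plasma read counting).
#' @return A \linkS4class{BinSet} with \code{gc = NA} and
#'   \code{masked = FALSE} for every bin; chromosomes contributing no
#'   complete bin are kept as seqlevels but contribute no ranges.
#' @examples
#' makeBins(c(chr1 = 125000, chr2 = 49999), width = 50000)
#' @export
makeBins <- function(seqlens, width = 50000) {
    if (length(width) != 1L || !is.finite(width) || width < 1)
        stop("'width' must be a single positive number")
    if (is.null(names(seqlens)) || any(!nzchar(names(seqlens))))
        stop("'seqlens' must be a named vector of chromosome lengths")
    if (anyDuplicated(names(seqlens)))
        stop("duplicated chromosome names in 'seqlens'")
    if (any(seqlens < 0)) stop("chromosome lengths must be >= 0")
    width <- as.integer(width)
    nb <- as.integer(seqlens %/% width)
    chrom <- rep(names(seqlens), nb)
    k <- unlist(lapply(nb, function(n) seq_len(n) - 1L), use.names = FALSE)
    if (is.null(k)) k <- integer(0)
    gr <- GRanges(
        seqnames = factor(chrom, levels = names(seqlens)),
        ranges = IRanges(start = k * width + 1L, width = width),
        gc = rep(NA_real_, length(chrom)),
        masked = logical(length(chrom)),
        seqlengths = structure(floor(seqlens), names = names(seqlens)))
    new("BinSet", gr, binWidth = width)
}

#' Compute per-bin GC content from reference sequence
#'
#' GC is the fraction (G + C) / (A + C + G + T) over the bin, case-insensitive.
#' Ambiguous bases (N and IUPAC codes) are excluded from the denominator; a
#' bin whose fraction of ambiguous bases exceeds \code{maxNFraction} is
#' flagged \code{masked} and excluded from all downstream regressions and
#' tests. A bin consisting entirely of ambiguous bases gets \code{gc = NA}
#' and is masked.
#'
#' @param seqs reference sequences: a \code{\link[Biostrings]{DNAStringSet}},
#'   a named character vector of sequences, or the path to a FASTA file
#'   (read with \code{\link[Biostrings]{readDNAStringSet}}).
#' @param bins a \linkS4class{BinSet}; every chromosome with bins must be
#'   covered by a sequence at least as long as its last bin.
#' @param maxNFraction maximum tolerated fraction of ambiguous bases per bin
#'   before masking (default 0.1).
#' @return \code{bins} with \code{gc} filled and \code{masked} updated
#'   (existing masks are kept).
#' @examples
#' bins <- makeBins(c(chrA = 16), width = 8)
#' gcPerBin(c(chrA = "GGCCGGCCATATATAT"), bins)
#' @export
gcPerBin <- function(seqs, bins, maxNFraction = 0.1) {
    if (is.character(seqs) && length(seqs) == 1L && is.null(names(seqs)) &&
        file.exists(seqs))
        seqs <- Biostrings::readDNAStringSet(seqs)
    if (is.character(seqs))
        seqs <- Biostrings::DNAStringSet(seqs)
    nm <- sub("\\s.*$", "", names(seqs))  # FASTA headers: keep first word
    names(seqs) <- nm
    gc <- rep(NA_real_, length(bins))
    nfrac <- rep(NA_real_, length(bins))
    chroms <- unique(as.character(seqnames(bins)))
    for (ch in chroms) {
        i <- which(as.character(seqnames(bins)) == ch)
        if (!length(i)) next
        if (!ch %in% names(seqs))
            stop("no reference sequence for chromosome '", ch, "'")
        s <- seqs[[ch]]
        if (max(GenomicRanges::end(bins)[i]) > length(s))
            stop(sprintf("bins on '%s' extend past the sequence end (%d > %d)",
                         ch, max(GenomicRanges::end(bins)[i]), length(s)))
        v <- Biostrings::Views(s, start = GenomicRanges::start(bins)[i],
                               end = GenomicRanges::end(bins)[i])
        f <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
        acgt <- rowSums(f)
        gc[i] <- ifelse(acgt > 0, (f[, "C"] + f[, "G"]) / acgt, NA_real_)
        nfrac[i] <- 1 - acgt / binWidth(bins)
    }
    mcols(bins)$gc <- gc
    mcols(bins)$masked <- binMasked(bins) | is.na(gc) |
        (nfrac > maxNFraction)
    validObject(bins)
    bins
}
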