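#' Read and write the on-disk tables
#'
#' Three TSV dialects cover the pipeline's persistent state; all three
#' round-trip exactly (write then read gives back the same object) and accept
#' leading \code{#} comment lines, which the CLI uses to echo the effective
#' configuration into every output.
#'
#' \describe{
#'   \item{bin table}{BED-like: \code{chrom}, \code{start} (0-based),
#'     \code{end} (exclusive), \code{gc} (\code{NA} allowed), \code{masked}
#'     (0/1).}
#'   \item{count table}{first column \code{bin} holds
#'     \code{chrom:start-end} keys (0-based half-open), remaining columns are
#'     libraries; a \code{# values=real} header line marks corrected
#'     (real-valued) matrices, \code{# values=integer} raw counts.}
#'   \item{metadata table}{\code{library_id}, \code{sample_id},
#'     \code{karyotype}, \code{role}, \code{fetal_fraction}, plus any
#'     covariate columns.}
#' }
#'
#' @param bins a \linkS4class{BinSet}.
#' @param path file path.
#' @param comments character vector of lines to write as leading
#'   \code{# } comments (e.g. a config echo).
#' @return The readers return the corresponding object (\code{readBinTable}:
#'   a \linkS4class{BinSet}; \code{readCountTable}: a matrix with library
#'   columns; \code{readLibraryMeta}: a \code{data.frame}); the writers
#'   return \code{path} invisibly.
#' @name table_io
NULL

.writeTsv <- function(df, path, comments = character(0)) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (length(comments))
        writeLines(paste0("# ", comments), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

.readTsv <- function(path, ...) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE, ...)
}

.readComments <- function(path) {
    lines <- readLines(path, n = 50L)
    sub("^#\\s?", "", lines[startsWith(lines, "#")])
}

#' @rdname table_io
#' @export
writeBinTable <- function(bins, path, comments = character(0)) {
    df <- data.frame(
        chrom = as.character(seqnames(bins)),
        start = GenomicRanges::start(bins) - 1L,
        end = GenomicRanges::end(bins),
        gc = binGC(bins),
        masked = as.integer(binMasked(bins)))
    .writeTsv(df, path, comments)
}

#' @rdname table_io
#' @export
readBinTable <- function(path) {
    df <- .readTsv(path)
    need <- c("chrom", "start", "end", "gc", "masked")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("bin table ", path, " lacks column(s): ",
             paste(miss, collapse = ", "))
    w <- unique(df$end - df$start)
    if (length(w) > 1L)
        stop("bin table ", path, " mixes bin widths: ",
             paste(w, collapse = ", "))
    chrom_order <- unique(df$chrom)
    seqlens <- vapply(split(df$end, factor(df$chrom, levels = chrom_order)),
                      max, numeric(1))
    gr <- GRanges(
        seqnames = factor(df$chrom, levels = chrom_order),
        ranges = IRanges(start = df$start + 1L, end = df$end),
        gc = as.numeric(df$gc),
        masked = as.logical(df$masked),
        seqlengths = seqlens)
    new("BinSet", gr, binWidth = as.integer(w))
}

#' @rdname table_io
#' @param counts matrix of counts, bins x libraries, aligned to \code{bins}.
#' @export
writeCountTable <- function(counts, bins, path, comments = character(0)) {
    counts <- as.matrix(counts)
    if (nrow(counts) != length(bins))
        stop("count matrix rows do not match the bin set")
    real_valued <- !all(counts == floor(counts), na.rm = TRUE) ||
        is.double(counts) && any(counts != round(counts), na.rm = TRUE)
    comments <- c(comments,
                  paste0("values=", if (real_valued) "real" else "integer"))
    df <- data.frame(bin = binIds(bins), check.names = FALSE)
    for (j in seq_len(ncol(counts))) df[[colnames(counts)[j]]] <- counts[, j]
    .writeTsv(df, path, comments)
}

#' @rdname table_io
#' @param binsRef optional \linkS4class{BinSet} to validate the table against:
#'   every row key must match the corresponding bin, in order.
#' @export
readCountTable <- function(path, binsRef = NULL) {
    df <- .readTsv(path)
    if (colnames(df)[1L] != "bin")
        stop("count table ", path, " must have 'bin' as its first column")
    ids <- df$bin
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- NULL
    if (!is.null(binsRef)) {
        want <- binIds(binsRef)
        if (length(ids) != length(want))
            stop(sprintf("count table %s has %d bins but the bin table has %d",
                         path, length(ids), length(want)))
        bad <- which(ids != want)
        if (length(bad))
            stop(sprintf(
                "count table %s row %d: bin '%s' not in the bin table (expected '%s')",
                path, bad[1L], ids[bad[1L]], want[bad[1L]]))
    }
    hdr <- .readComments(path)
    if (!any(startsWith(hdr, "values=real")))
        storage.mode(m) <- "integer"
    rownames(m) <- ids
    m
}

#' @rdname table_io
#' @param meta a \code{data.frame} of per-library metadata (rownames or a
#'   \code{library_id} column give the library ids).
#' @export
writeLibraryMeta <- function(meta, path, comments = character(0)) {
    meta <- as.data.frame(meta)
    if (!"library_id" %in% colnames(meta))
        meta <- cbind(library_id = rownames(meta), meta)
    rownames(meta) <- NULL
    .writeTsv(meta, path, comments)
}

#' @rdname table_io
#' @export
readLibraryMeta <- function(path) {
    df <- .readTsv(path)
    if (!"library_id" %in% colnames(df))
        stop("metadata table ", path, " lacks a 'library_id' column")
    if (anyDuplicated(df$library_id))
        stop("metadata table ", path, " has duplicated library ids")
    rownames(df) <- df$library_id
    df
}

#' Assemble a MinkCountSet from its three on-disk tables
#' @param countPath,binPath,metaPath paths to a count table, bin table and
#'   metadata table written by the \code{\link{table_io}} writers.
#' @return A \linkS4class{MinkCountSet}.
#' @export
readMinkCountSet <- function(countPath, binPath, metaPath = NULL) {
    bins <- readBinTable(binPath)
    counts <- readCountTable(countPath, binsRef = bins)
    meta <- if (is.null(metaPath)) NULL else readLibraryMeta(metaPath)
    MinkCountSet(counts, bins, meta)
}

#' Write a MinkCountSet to its three on-disk tables
#' @param x a \linkS4class{MinkCountSet}.
#' @param countPath,binPath,metaPath output paths.
#' @param comments comment lines echoed into each file.
#' @export
writeMinkCountSet <- function(x, countPath, binPath, metaPath,
                              comments = character(0)) {
    writeBinTable(binSet(x), binPath, comments)
    writeCountTable(countsMatrix(x), binSet(x), countPath, comments)
    writeLibraryMeta(as.data.frame(libraryMeta(x)), metaPath, comments)
    invisible(NULL)
}
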