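test_that("makeBins tiles chromosomes with fixed-width bins and drops partials", {
    b <- makeBins(c(chr1 = 125000), width = 50000)
    expect_s4_class(b, "BinSet")
    expect_equal(length(b), 2L)
    expect_equal(GenomicRanges::start(b), c(1L, 50001L))
    expect_equal(GenomicRanges::end(b), c(50000L, 100000L))

    expect_equal(length(makeBins(c(chrA = 100000), 50000)), 2L)
    expect_equal(length(makeBins(c(chrB = 49999), 50000)), 0L)

    # exact bin count over a random genome plan
    set.seed(3)
    lens <- setNames(sample.int(1e6, 8), paste0("c", 1:8))
    expect_equal(length(makeBins(lens, 7000)), sum(lens %/% 7000))

    expect_error(makeBins(c(chr1 = 1e5), width = 0), "positive")
    expect_error(makeBins(setNames(1e5, "")), "named")
})

test_that("gcPerBin matches a brute-force tally and masks ambiguous bins", {
    b <- gcPerBin(c(chrA = "GGCCGGCCATATATAT"), makeBins(c(chrA = 16), 8))
    expect_equal(binGC(b), c(1, 0))

    seq25 <- paste0(strrep("G", 5), strrep("C", 5), strrep("A", 8),
                    strrep("T", 7))
    b2 <- gcPerBin(setNames(seq25, "c"), makeBins(c(c = 25), 25))
    expect_equal(binGC(b2), 0.4)

    # oracle: character tally on random sequences with Ns
    set.seed(11)
    s <- paste(sample(c("A", "C", "G", "T", "N", "a", "c", "g", "t"),
                      400, replace = TRUE), collapse = "")
    bins <- makeBins(c(chrR = 400), width = 40)
    got <- gcPerBin(setNames(s, "chrR"), bins, maxNFraction = 0.15)
    chars <- toupper(strsplit(s, "")[[1]])
    for (i in 1:10) {
        win <- chars[((i - 1) * 40 + 1):(i * 40)]
        acgt <- sum(win %in% c("A", "C", "G", "T"))
        expect_equal(binGC(got)[i], sum(win %in% c("G", "C")) / acgt)
        expect_equal(binMasked(got)[i], (1 - acgt / 40) > 0.15)
    }

    # bin past the end of the sequence is a coordinate error
    expect_error(gcPerBin(c(chrA = "ACGT"), makeBins(c(chrA = 16), 8)),
                 "past the sequence end")
})

test_that("countLibrary filters, dedupes and converts coordinates correctly", {
    bins <- makeBins(c(chr1 = 100000), width = 50000)
    rec <- data.frame(chrom = "chr1", pos = c(100, 100, 100), strand = "+")
    res <- countLibrary(rec, bins)
    expect_equal(res$counts, c(1L, 0L))
    expect_equal(res$report[["duplicate"]], 2L)

    # a mismatch or a non-unique flag discards the record
    rec2 <- data.frame(chrom = "chr1", pos = c(5, 6, 7),
                       strand = "+", mismatches = c(0, 1, 0),
                       unique = c(TRUE, TRUE, FALSE))
    res2 <- countLibrary(rec2, bins)
    expect_equal(sum(res2$counts), 1L)
    expect_equal(res2$report[["mismatched"]], 1L)
    expect_equal(res2$report[["nonunique"]], 1L)

    # 1-based positions 50000 and 50001 straddle the first bin boundary
    rec3 <- data.frame(chrom = "chr1", pos = c(50000, 50001), strand = "+")
    expect_equal(countLibrary(rec3, bins)$counts, c(1L, 1L))

    # unknown chromosome and out-of-grid positions are reported, not fatal
    rec4 <- data.frame(chrom = c("chrZ", "chr1"), pos = c(10, 999999),
                       strand = "+")
    res4 <- countLibrary(rec4, bins)
    expect_equal(sum(res4$counts), 0L)
    expect_equal(res4$report[["unknown_chrom"]], 1L)
    expect_equal(res4$report[["outside_bins"]], 1L)

    # row sum always equals retained count (property over random records)
    set.seed(5)
    recR <- data.frame(
        chrom = sample(c("chr1", "chrX"), 500, TRUE),
        pos = sample.int(120000, 500, TRUE),
        strand = sample(c("+", "-"), 500, TRUE),
        mismatches = rpois(500, 0.2),
        unique = runif(500) > 0.1)
    resR <- countLibrary(recR, bins)
    expect_equal(sum(resR$counts), unname(resR$report[["retained"]]))
    tallies <- resR$report
    expect_equal(tallies[["total"]], 500L)
})

test_that("order of records does not change the counts", {
    bins <- makeBins(c(chr1 = 200000, chr2 = 150000), width = 50000)
    set.seed(9)
    rec <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                      pos = sample.int(190000, 300, TRUE),
                      strand = sample(c("+", "-"), 300, TRUE))
    a <- countLibrary(rec, bins)$counts
    b <- countLibrary(rec[sample.int(300), ], bins)$counts
    expect_identical(a, b)
})

test_that("bin, count and metadata tables round-trip exactly", {
    bins <- tinyBins(c(chr1 = 150000, chr2 = 100000), gcSeed = 7)
    binMasked(bins) <- c(FALSE, TRUE, FALSE, FALSE, FALSE)
    tf <- tempfile()
    writeBinTable(bins, tf, comments = "width=50000")
    b2 <- readBinTable(tf)
    expect_equal(as.character(seqnames(b2)), as.character(seqnames(bins)))
    expect_equal(GenomicRanges::start(b2), GenomicRanges::start(bins))
    expect_equal(binGC(b2), binGC(bins))
    expect_identical(binMasked(b2), binMasked(bins))

    m <- matrix(c(0L, 5L, 2L, 7L, 1L, 3L, 8L, 0L, 4L, 9L), nrow = 5,
                dimnames = list(NULL, c("L1", "L2")))
    cf <- tempfile()
    writeCountTable(m, bins, cf)
    m2 <- readCountTable(cf, binsRef = bins)
    expect_identical(unname(m2[, ]), unname(m))
    expect_identical(colnames(m2), colnames(m))

    # real-valued tables keep their values and type
    mr <- m * 1.5
    writeCountTable(mr, bins, cf)
    m3 <- readCountTable(cf, binsRef = bins)
    expect_equal(unname(m3[, ]), unname(mr))
    expect_type(m3, "double")

    meta <- data.frame(library_id = c("L1", "L2"), sample_id = c("S1", "S1"),
                       karyotype = c("46,XY", "47,XX,+21"),
                       role = c("reference", "test"),
                       fetal_fraction = c(NA, 0.1))
    mf <- tempfile()
    writeLibraryMeta(meta, mf)
    meta2 <- readLibraryMeta(mf)
    expect_equal(meta2$karyotype, meta$karyotype)
    expect_equal(meta2$fetal_fraction, meta$fetal_fraction)

    # empty library list: header-only table reads back to 0 columns
    writeCountTable(m[, 0, drop = FALSE], bins, cf)
    expect_equal(ncol(readCountTable(cf, binsRef = bins)), 0L)

    # assembled object round-trips through the three files
    mcs <- MinkCountSet(m, bins, meta)
    writeMinkCountSet(mcs, cf, tf, mf)
    mcs2 <- readMinkCountSet(cf, tf, mf)
    expect_identical(unname(countsMatrix(mcs2)), unname(countsMatrix(mcs)))
    expect_equal(libraryMeta(mcs2)$role, libraryMeta(mcs)$role)
})

test_that("count/bin table mismatches raise format errors naming the row", {
    bins <- tinyBins(c(chr1 = 150000), gcSeed = 2)
    other <- tinyBins(c(chr9 = 150000), gcSeed = 2)
    m <- matrix(1L, 3, 1, dimnames = list(NULL, "L1"))
    cf <- tempfile()
    writeCountTable(m, other, cf)
    expect_error(readCountTable(cf, binsRef = bins), "row 1.*chr9")
    expect_error(readCountTable(tempfile()), "not found")
})

test_that("MinkCountSet validates its pieces", {
    bins <- tinyBins(c(chr1 = 150000), gcSeed = 3)
    m <- matrix(1L, 3, 2, dimnames = list(NULL, c("A", "B")))
    mcs <- MinkCountSet(m, bins)
    expect_s4_class(mcs, "MinkCountSet")
    expect_equal(libraryMeta(mcs)$role, c("test", "test"))
    expect_error(MinkCountSet(m[1:2, ], bins), "2 rows")
    bad <- data.frame(library_id = c("A", "B"), role = c("reference", "boss"))
    expect_error(MinkCountSet(m, bins, bad), "role")
})

test_that("karyotype labels parse into per-chromosome truth", {
    expect_equal(karyotypeTrisomies(c("46,XY", "47,XX,+21"))[[2]], "chr21")
    expect_equal(karyotypeTrisomies("48,XX,+13,+18")[[1]],
                 c("chr13", "chr18"))
    expect_identical(isTrisomic(c("47,XY,+18", "46,XX", NA), "chr18"),
                     c(TRUE, FALSE, NA))
})

test_that("the BAM adapter feeds countLibrary the same counts as plain records", {
    # build a tiny SAM in code, convert, and compare both ingestion routes
    sam <- c(
        "@HD\tVN:1.6\tSO:coordinate",
        "@SQ\tSN:chr1\tLN:100000",
        "r1\t0\tchr1\t100\t30\t10M\t*\t0\t0\tACGTACGTAC\t**********\tNM:i:0",
        "r2\t0\tchr1\t100\t30\t10M\t*\t0\t0\tACGTACGTAC\t**********\tNM:i:0",
        "r3\t16\tchr1\t50005\t30\t10M\t*\t0\t0\tACGTACGTAC\t**********\tNM:i:0",
        "r4\t0\tchr1\t200\t30\t10M\t*\t0\t0\tACGTACGTAC\t**********\tNM:i:1",
        "r5\t0\tchr1\t300\t0\t10M\t*\t0\t0\tACGTACGTAC\t**********\tNM:i:0")
    sf <- tempfile(fileext = ".sam")
    writeLines(sam, sf)
    bam <- Rsamtools::asBam(sf, tempfile(), overwrite = TRUE)
    rec <- alignmentsFromBam(bam)
    expect_equal(nrow(rec), 5L)
    bins <- makeBins(c(chr1 = 100000), width = 50000)
    res <- countLibrary(rec, bins)
    # r1/r2 duplicates -> 1; r3 second bin; r4 mismatched; r5 mapq 0
    expect_equal(res$counts, c(1L, 1L))
    expect_equal(res$report[["retained"]], 2L)
    expect_equal(res$report[["duplicate"]], 1L)
})
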