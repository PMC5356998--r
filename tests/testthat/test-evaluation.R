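test_that("confusionCounts tallies hand-checkable calls correctly", {
    truth <- data.frame(library_id = c("a", "b", "c"),
                        sample_id = c("a", "b", "c"),
                        karyotype = c("47,XX,+21", "46,XY", "46,XY"))
    calls <- data.frame(
        library_id = rep(c("a", "b", "c"), 2),
        sample_id = rep(c("a", "b", "c"), 2),
        chrom = rep(c("chr21", "chr13"), each = 3),
        call = c("trisomy", "normal", "ambiguous",
                 "normal", "trisomy", "normal"))
    cc <- confusionCounts(calls, truth, unit = "library")
    c21 <- cc[cc$chrom == "chr21", ]
    expect_equal(c21$TP, 1); expect_equal(c21$TN, 1)
    expect_equal(c21$neg_ambiguous, 1)
    c13 <- cc[cc$chrom == "chr13", ]
    expect_equal(c13$FP, 1); expect_equal(c13$TN, 2)
    all_ <- cc[cc$chrom == "all", ]
    expect_equal(all_$TP + all_$FN + all_$pos_ambiguous, all_$n_true_pos)
    expect_equal(all_$TN + all_$FP + all_$neg_ambiguous, all_$n_true_neg)

    # ambiguous-as-negative folds the ambiguous call into TN here
    cc2 <- confusionCounts(calls, truth, unit = "library",
                           ambiguous = "negative")
    expect_equal(cc2[cc2$chrom == "chr21", "TN"], 2)
})

test_that("confusion identities hold on a randomised calls table", {
    set.seed(70)
    n <- 60
    kary <- sample(c("46,XY", "47,XX,+21", "47,XY,+18"), n, TRUE)
    ids <- sprintf("L%02d", 1:n)
    truth <- data.frame(library_id = ids, sample_id = ids, karyotype = kary)
    calls <- expand.grid(library_id = ids, chrom = c("chr18", "chr21"),
                         stringsAsFactors = FALSE)
    calls$sample_id <- calls$library_id
    calls$call <- sample(c("trisomy", "normal", "ambiguous", "no_call"),
                         nrow(calls), TRUE)
    cc <- confusionCounts(calls, truth, unit = "library")
    for (i in seq_len(nrow(cc))) {
        expect_equal(cc$TP[i] + cc$FP[i] + cc$TN[i] + cc$FN[i] +
                     cc$pos_ambiguous[i] + cc$neg_ambiguous[i] +
                     cc$no_call[i],
                     cc$n_true_pos[i] + cc$n_true_neg[i])
    }
})

test_that("binomialMetrics matches exact binomial intervals", {
    m <- binomialMetrics(2, 3)
    expect_equal(m$estimate, 2 / 3, tolerance = 1e-10)

    m1 <- binomialMetrics(5, 5)
    expect_equal(m1$estimate, 1)
    expect_equal(m1$ci_hi, 1)

    # Clopper-Pearson against binom.test (independent closed form)
    for (kn in list(c(47, 48), c(0, 10), c(3, 7), c(60, 61))) {
        got <- binomialMetrics(kn[1], kn[2])
        want <- binom.test(kn[1], kn[2])$conf.int
        expect_equal(c(got$ci_lo, got$ci_hi), as.numeric(want),
                     tolerance = 1e-9)
        # the interval always contains k/n
        expect_true(got$ci_lo <= got$estimate && got$estimate <= got$ci_hi)
    }

    # width shrinks as n grows at fixed proportion
    w <- vapply(c(10, 40, 160, 640), function(n) {
        m <- binomialMetrics(round(0.8 * n), n)
        m$ci_hi - m$ci_lo
    }, numeric(1))
    expect_true(all(diff(w) < 0))

    # alternative methods differ from the exact interval but stay ordered
    cp <- binomialMetrics(47, 48)
    wl <- binomialMetrics(47, 48, method = "wilson")
    jf <- binomialMetrics(47, 48, method = "jeffreys")
    expect_false(isTRUE(all.equal(cp$ci_lo, wl$ci_lo)))
    expect_false(isTRUE(all.equal(cp$ci_lo, jf$ci_lo)))
    expect_error(binomialMetrics(0, 0), "n must be")
})

test_that("metricsTable computes SEN/SPC/PPV from confusion counts", {
    conf <- data.frame(chrom = c("chr21", "all"), TP = c(47, 60),
                       FP = c(0, 1), TN = c(368, 1602), FN = c(1, 1),
                       pos_ambiguous = 0, neg_ambiguous = 0, no_call = 0,
                       n_true_pos = c(48, 61), n_true_neg = c(368, 1603))
    mt <- metricsTable(conf)
    sen21 <- mt[mt$chrom == "chr21" & mt$metric == "SEN", ]
    expect_equal(sen21$estimate, 47 / 48, tolerance = 1e-10)
    ppv21 <- mt[mt$chrom == "chr21" & mt$metric == "PPV", ]
    expect_equal(ppv21$estimate, 1)
})

test_that("twoProportionTest agrees with the classical z formula and is symmetric", {
    # equal proportions: p = 1
    expect_equal(twoProportionTest(5, 50, 5, 50)$p, 1)

    # continuity off, large n: hand-coded pooled z
    x1 <- 120; n1 <- 3000; x2 <- 90; n2 <- 2800
    got <- twoProportionTest(x1, n1, x2, n2, continuity = FALSE)
    ph <- (x1 + x2) / (n1 + n2)
    z <- (x1 / n1 - x2 / n2) / sqrt(ph * (1 - ph) * (1 / n1 + 1 / n2))
    expect_equal(got$p, 2 * pnorm(-abs(z)), tolerance = 1e-6)
    expect_equal(got$chisq, z^2, tolerance = 1e-6)

    # swapping the groups leaves the p value unchanged
    expect_equal(twoProportionTest(1, 60, 3, 60)$p,
                 twoProportionTest(3, 60, 1, 60)$p, tolerance = 1e-12)

    # degenerate pooled proportion
    dg <- twoProportionTest(0, 10, 0, 20)
    expect_true(dg$degenerate)
    expect_equal(dg$p, 1)
})

test_that("downsampleCounts draws exact totals with hypergeometric moments", {
    expect_identical(downsampleCounts(c(10L, 20L), 30), c(10L, 20L))
    expect_identical(downsampleCounts(c(10L, 20L), 0), c(0L, 0L))
    expect_error(downsampleCounts(c(10L, 20L), 31), "must lie in")

    set.seed(33)
    reps <- 400
    draws <- replicate(reps, downsampleCounts(c(100L, 300L), 200)[1])
    expect_true(all(draws + replicate(1, 0) >= 0))
    # exact total every time
    tots <- replicate(50, sum(downsampleCounts(c(100L, 300L), 200)))
    expect_true(all(tots == 200))
    # hypergeometric mean 50 and variance within 3 SE over the replicates
    hv <- 200 * (100 / 400) * (300 / 400) * (400 - 200) / (400 - 1)
    expect_lt(abs(mean(draws) - 50), 3 * sqrt(hv / reps))
    expect_lt(abs(var(draws) - hv), 3 * hv * sqrt(2 / (reps - 1)))

    # thinning a -> b equals thinning directly to b in first moments
    set.seed(34)
    two_step <- replicate(reps,
        downsampleCounts(downsampleCounts(c(100L, 300L), 300), 150)[1])
    one_step <- replicate(reps, downsampleCounts(c(100L, 300L), 150)[1])
    se <- sqrt(var(one_step) / reps + var(two_step) / reps)
    expect_lt(abs(mean(two_step) - mean(one_step)), 3 * se)

    # binomial mode keeps the expected total
    set.seed(35)
    btot <- replicate(reps, sum(downsampleCounts(c(100L, 300L), 200,
                                                 mode = "binomial")))
    expect_lt(abs(mean(btot) - 200), 3 * sd(btot) / sqrt(reps))

    # a seed makes the draw reproducible without touching the global stream
    a <- downsampleCounts(c(1000L, 2000L), 500, seed = 9)
    b <- downsampleCounts(c(1000L, 2000L), 500, seed = 9)
    expect_identical(a, b)
})

test_that("external call tables are ingested as data and validated", {
    tf <- tempfile()
    writeLines(c("library_id\tchrom\tcall",
                 "L1\tchr21\ttrisomy",
                 "L2\tchr21\tnormal",
                 "L3\tchr21\tambiguous"), tf)
    calls <- ingestExternalCalls(tf)
    truth <- data.frame(library_id = c("L1", "L2", "L3"),
                        karyotype = c("47,XX,+21", "46,XY", "46,XY"))
    cc <- confusionCounts(calls, truth, unit = "library")
    c21 <- cc[cc$chrom == "chr21", ]
    expect_equal(c(c21$TP, c21$TN, c21$neg_ambiguous), c(1, 1, 1))

    writeLines(c("library_id\tchrom\tcall", "L1\tchr21\tmaybe"), tf)
    expect_error(ingestExternalCalls(tf), "unknown call label.*maybe")

    writeLines("library_id\tchrom\tcall", tf)
    expect_equal(nrow(ingestExternalCalls(tf)), 0L)
})

test_that("titration at full depth reproduces the plain cohort call", {
    cfg <- simConfig(nReference = 6, nTestNormal = 2, nTestTrisomy = 2,
                     seqlens = setNames(rep(2.5e6, 8),
                                        paste0("chr", c(1:7, 21))),
                     refSizeRange = c(4e6, 8e6),
                     testSizeRange = c(5e6, 5e6),
                     fetalRange = c(0.12, 0.15))
    mcs <- simulateCohort(cfg, seed = 26)
    # equalise the test-library totals so one depth is exactly full depth
    raw <- countsMatrix(mcs)
    testIdx <- 7:10
    T0 <- min(colSums(raw[, testIdx]))
    for (j in testIdx)
        raw[, j] <- downsampleCounts(raw[, j], T0, seed = 100 + j)
    mcs <- MinkCountSet(raw, binSet(mcs), as.data.frame(libraryMeta(mcs)))
    # depth equal to every test library total: thinning is the identity
    tt <- titration(mcs, depths = T0, seed = 1)
    mcsC <- gcCorrect(mcs)
    calls <- callCohort(mcsC, minkConfig(targetChroms = "chr21"),
                        testIds = colnames(mcs)[7:10])
    want <- table(factor(calls$call, c("trisomy", "normal", "ambiguous")))
    expect_equal(tt$TP + tt$FP, unname(want["trisomy"]))
    expect_equal(tt$TN + tt$FN, unname(want["normal"]))
    expect_equal(tt$ambiguous, unname(want["ambiguous"]))
    expect_equal(tt$no_call, 0L)
})
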