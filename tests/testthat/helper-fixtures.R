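# Shared fixture builders; everything is generated in code.

# A small bin grid with reproducible GC values.
tinyBins <- function(seqlens = c(chr1 = 50000 * 40, chr21 = 50000 * 10),
                     width = 50000, gcSeed = 404) {
    bins <- makeBins(seqlens, width = width)
    set.seed(gcSeed)
    binGC(bins) <- runif(length(bins), 0.3, 0.6)
    bins
}

# Independent per-point weighted-least-squares oracle for the local
# regression: full distance sort, tricube on d/dmax with dmax the q-th
# smallest distance, polynomial solve via normal equations.
wlsOracle <- function(x, y, span, degree, rw, e) {
    n <- length(x)
    d <- abs(x - e)
    q <- ceiling(span * n)
    dmax <- sort(d)[q]
    w <- ifelse(d < dmax, (1 - (d / dmax)^3)^3, 0)
    if (dmax == 0) w <- as.numeric(d == 0)
    w <- w * rw
    X <- outer(x - e, 0:degree, "^")
    beta <- solve(crossprod(X, w * X), crossprod(X, w * y))
    beta[1]
}

# Full robustness loop built on the oracle (independent of the C++ path).
localRegressionOracle <- function(x, y, span, degree, robustIters) {
    n <- length(x)
    rw <- rep(1, n)
    for (it in 0:robustIters) {
        fit <- vapply(x, function(e) wlsOracle(x, y, span, degree, rw, e),
                      numeric(1))
        if (it == robustIters) break
        r <- y - fit
        s <- 6 * median(abs(r))
        rw <- if (s <= 0) rep(1, n)
              else ifelse(abs(r) < s, (1 - (r / s)^2)^2, 0)
    }
    list(fitted = fit, rw = rw)
}

# From-scratch pairwise regression + one-sample t, used as the oracle for
# fitDiploidModel + testTarget.
minkTestOracle <- function(training, target, direction = "gain") {
    X <- cbind(1, training$gc)
    beta <- solve(crossprod(X), crossprod(X, training$r))
    rhat <- cbind(1, target$gc) %*% beta
    d <- target$r - rhat
    m <- length(d)
    tstat <- mean(d) / (sd(d) / sqrt(m))
    p <- switch(direction,
        gain = pt(tstat, m - 1, lower.tail = FALSE),
        loss = pt(tstat, m - 1),
        `two-sided` = 2 * pt(-abs(tstat), m - 1))
    list(t = tstat, p = p)
}

# The published cohort composition (416 samples; trisomy counts per
# chromosome) with a given set of call errors, as a sample-level call table
# plus matching truth.
paperCohortCalls <- function() {
    n <- 416
    kary <- c(rep("47,XX,+13", 2), rep("47,XX,+14", 1),
              rep("47,XX,+18", 10), rep("47,XX,+21", 48),
              rep("46,XY", 355))
    ids <- sprintf("S%03d", seq_len(n))
    truth <- data.frame(library_id = ids, sample_id = ids, karyotype = kary)
    chroms <- c("chr13", "chr14", "chr18", "chr21")
    calls <- expand.grid(sample_id = ids, chrom = chroms,
                         stringsAsFactors = FALSE)
    calls$library_id <- calls$sample_id
    tri <- vapply(seq_len(nrow(calls)), function(i)
        isTrisomic(kary[match(calls$sample_id[i], ids)], calls$chrom[i]),
        logical(1))
    calls$call <- ifelse(tri, "trisomy", "normal")
    # the two reported errors: one chr21 false negative, one chr13 false
    # positive (on a normal sample)
    fn <- which(calls$chrom == "chr21" &
                calls$sample_id == ids[14])  # a trisomy-21 sample
    stopifnot(calls$call[fn] == "trisomy")
    calls$call[fn] <- "normal"
    fp <- which(calls$chrom == "chr13" & calls$sample_id == ids[400])
    stopifnot(calls$call[fp] == "normal")
    calls$call[fp] <- "trisomy"
    list(calls = calls, truth = truth)
}
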