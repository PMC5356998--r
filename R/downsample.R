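#' Downsample a bin-count vector to a target total
#'
#' Emulates read-level subsampling on the count vector. The default mode
#' draws exactly \code{targetTotal} reads without replacement across bins --
#' a multivariate hypergeometric draw, realised by sequential conditional
#' \code{\link[stats]{rhyper}} draws -- so the thinned total is exact, as
#' when reads are subsampled from an alignment file. The alternative
#' binomial mode thins each bin independently with keep probability
#' \code{targetTotal / sum(x)} (expected, not exact, total).
#'
#' @param x non-negative integer vector of bin counts.
#' @param targetTotal desired total (0 <= targetTotal <= sum(x)).
#' @param mode \code{"hypergeometric"} (default, exact total) or
#'   \code{"binomial"}.
#' @param seed optional integer; when given, the draw is made reproducible
#'   by seeding a local RNG state (the caller's RNG state is restored).
#' @return Integer vector of thinned counts, same length as \code{x}.
#' @examples
#' set.seed(7)
#' downsampleCounts(c(100L, 300L), 200)
#' @export
downsampleCounts <- function(x, targetTotal,
                             mode = c("hypergeometric", "binomial"),
                             seed = NULL) {
    mode <- match.arg(mode)
    if (any(x < 0) || any(x != floor(x))) stop("counts must be non-negative integers")
    total <- sum(x)
    if (targetTotal < 0 || targetTotal > total)
        stop(sprintf("targetTotal (%s) must lie in [0, %s]",
                     format(targetTotal, scientific = FALSE),
                     format(total, scientific = FALSE)))
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    if (targetTotal == total) return(as.integer(x))
    out <- integer(length(x))
    if (targetTotal == 0) return(out)
    if (mode == "binomial")
        return(stats::rbinom(length(x), as.integer(x), targetTotal / total))
    remaining <- total
    draw <- targetTotal
    for (i in seq_along(x)) {
        if (draw == 0) break
        xi <- x[i]
        remaining <- remaining - xi
        if (remaining == 0) { out[i] <- draw; draw <- 0; break }
        got <- stats::rhyper(1, xi, remaining, draw)
        out[i] <- got
        draw <- draw - got
    }
    out
}

#' Read-depth titration of the caller on a cohort
#'
#' Repeats the aneuploidy call for one target chromosome while the test
#' libraries are downsampled to a ladder of read depths; the reference
#' libraries are never downsampled. Each (library, depth) combination is
#' thinned from the library's full raw counts (exact-total hypergeometric),
#' GC-corrected, and called against the corrected reference panel; the calls
#' are tallied against karyotype truth at library level. Libraries shallower
#' than a requested depth, or failing the call, enter the \code{no_call}
#' column. Fully deterministic given \code{seed}.
#'
#' @param x a \linkS4class{MinkCountSet} with roles assigned.
#' @param depths read totals to titrate, largest first by convention
#'   (default 20, 15, 10, 8, 6, 4, 2, 1 million).
#' @param config a \code{\link{minkConfig}}.
#' @param targetChrom chromosome tested (default \code{"chr21"}).
#' @param seed integer seed driving all thinning randomness (default 1).
#' @param correct apply GC correction after thinning (default \code{TRUE}).
#' @return A \code{data.frame} with one row per depth: \code{depth},
#'   \code{TP}, \code{TN}, \code{FP}, \code{FN}, \code{ambiguous},
#'   \code{no_call}, plus \code{pos_median_p} and \code{neg_median_p} -- the
#'   median over the truly trisomic (resp. truly normal) test libraries of
#'   their median p values, a depth-resolved measure of detection margin.
#' @export
titration <- function(x, depths = c(20, 15, 10, 8, 6, 4, 2, 1) * 1e6,
                      config = minkConfig(), targetChrom = "chr21",
                      seed = 1, correct = TRUE) {
    stopifnot(is(x, "MinkCountSet"))
    bins <- binSet(x)
    meta <- libraryMeta(x)
    raw <- countsMatrix(x)
    refIds <- colnames(x)[meta$role == "reference"]
    testIds <- colnames(x)[meta$role == "test"]
    if (!length(refIds) || !length(testIds))
        stop("titration needs both reference and test libraries")
    refValues <- if (correct)
        gcCorrect(raw[, refIds, drop = FALSE], bins, span = config$span,
                  degree = config$degreeLoess,
                  robustIters = config$robustIters)
    else raw[, refIds, drop = FALSE]
    truthPos <- isTrisomic(meta[testIds, "karyotype"], targetChrom)
    set.seed(seed)
    rows <- lapply(depths, function(depth) {
        tally <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L,
                   ambiguous = 0L, no_call = 0L)
        medp <- rep(NA_real_, length(testIds))
        for (j in seq_along(testIds)) {
            lib <- testIds[j]
            res <- tryCatch({
                thin <- downsampleCounts(raw[, lib], depth)
                val <- if (correct)
                    gcCorrect(thin, bins, span = config$span,
                              degree = config$degreeLoess,
                              robustIters = config$robustIters)
                else thin
                values <- cbind(refValues, val)
                colnames(values)[ncol(values)] <- lib
                rawm <- cbind(raw[, refIds, drop = FALSE], thin)
                colnames(rawm)[ncol(rawm)] <- lib
                cl <- minkCall(values, bins, lib, refIds, targetChrom,
                               config, raw = rawm)
                medp[j] <- cl$medianP
                cl$call
            }, error = function(e) "no_call")
            tally <- tally + c(
                TP = res == "trisomy" && truthPos[j],
                TN = res == "normal" && !truthPos[j],
                FP = res == "trisomy" && !truthPos[j],
                FN = res == "normal" && truthPos[j],
                ambiguous = res == "ambiguous",
                no_call = res == "no_call")
        }
        data.frame(depth = depth, t(tally),
                   pos_median_p = stats::median(medp[truthPos], na.rm = TRUE),
                   neg_median_p = stats::median(medp[!truthPos], na.rm = TRUE))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
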