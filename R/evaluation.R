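#' Confusion counts of aneuploidy calls against karyotype truth
#'
#' Tallies true/false positives and negatives per target chromosome and
#' overall. A unit (sample or library) counts as positive-called only when
#' its call is \code{"trisomy"}; ambiguous calls are tallied separately and
#' excluded from TP/FP/TN/FN by default (they "need further investigation"),
#' or folded into the negative calls with \code{ambiguous = "negative"}.
#' Units without any call are counted in \code{no_call}.
#'
#' @param calls data frame of calls with columns \code{chrom}, \code{call}
#'   and \code{library_id} and/or \code{sample_id} (as from
#'   \code{\link{callCohort}}, \code{\link{sampleRollup}} or
#'   \code{\link{ingestExternalCalls}}).
#' @param truth data frame with one row per library: \code{library_id},
#'   \code{sample_id} (optional; defaults to \code{library_id}) and
#'   \code{karyotype}. A \linkS4class{MinkCountSet} may be given instead.
#' @param unit \code{"sample"} (default) or \code{"library"}. At sample
#'   level, library calls are first aggregated with
#'   \code{\link{sampleRollup}} (unless \code{calls} already has one row per
#'   sample and chromosome) and truth comes from each sample's libraries.
#' @param ambiguous \code{"exclude"} (default) or \code{"negative"}.
#' @param prefix chromosome-name prefix for karyotype parsing.
#' @return A \code{data.frame} with one row per chromosome plus an
#'   \code{"all"} row: \code{chrom}, \code{TP}, \code{FP}, \code{TN},
#'   \code{FN}, \code{pos_ambiguous}, \code{neg_ambiguous}, \code{no_call},
#'   \code{n_true_pos}, \code{n_true_neg}. The identities
#'   \code{TP + FN + pos_ambiguous (+ positive no-calls) = n_true_pos} and
#'   \code{TN + FP + neg_ambiguous (+ negative no-calls) = n_true_neg} hold
#'   by construction.
#' @export
confusionCounts <- function(calls, truth, unit = c("sample", "library"),
                            ambiguous = c("exclude", "negative"),
                            prefix = "chr") {
    unit <- match.arg(unit)
    ambiguous <- match.arg(ambiguous)
    if (is(truth, "MinkCountSet")) {
        cd <- as.data.frame(libraryMeta(truth))
        truth <- data.frame(library_id = colnames(truth),
                            sample_id = cd$sample_id,
                            karyotype = cd$karyotype)
    }
    truth <- as.data.frame(truth)
    if (is.null(truth$sample_id)) truth$sample_id <- truth$library_id
    calls <- as.data.frame(calls)
    if (unit == "sample") {
        if (!"sample_id" %in% colnames(calls))
            stop("sample-level confusion needs a 'sample_id' column in calls")
        if (anyDuplicated(calls[c("sample_id", "chrom")]))
            calls <- sampleRollup(calls)
        id <- calls$sample_id
        tr_kary <- vapply(split(truth$karyotype, truth$sample_id),
                          function(k) k[1L], character(1))
    } else {
        id <- calls$library_id
        tr_kary <- stats::setNames(truth$karyotype, truth$library_id)
    }
    if (!all(id %in% names(tr_kary)))
        stop("no karyotype truth for unit(s): ",
             paste(utils::head(setdiff(id, names(tr_kary)), 5), collapse = ", "))
    chroms <- unique(calls$chrom)
    one <- function(chrom) {
        d <- calls[calls$chrom == chrom, ]
        uid <- if (unit == "sample") d$sample_id else d$library_id
        pos <- isTrisomic(tr_kary[uid], chrom, prefix = prefix)
        cl <- d$call
        if (ambiguous == "negative") cl[cl == "ambiguous"] <- "normal"
        data.frame(chrom = chrom,
            TP = sum(pos & cl == "trisomy"),
            FP = sum(!pos & cl == "trisomy"),
            TN = sum(!pos & cl == "normal"),
            FN = sum(pos & cl == "normal"),
            pos_ambiguous = sum(pos & cl == "ambiguous"),
            neg_ambiguous = sum(!pos & cl == "ambiguous"),
            no_call = sum(cl == "no_call"),
            n_true_pos = sum(pos), n_true_neg = sum(!pos))
    }
    per <- do.call(rbind, lapply(chroms, one))
    all_row <- per[1L, ]
    all_row$chrom <- "all"
    for (cc in colnames(per)[-1L]) all_row[[cc]] <- sum(per[[cc]])
    out <- rbind(per, all_row)
    attr(out, "unit") <- unit
    rownames(out) <- NULL
    out
}

#' Binomial proportion estimate with confidence interval
#'
#' Point estimate \code{k/n} with a 95\% (by default) confidence interval:
#' exact Clopper-Pearson (beta quantiles, the default), Wilson score, or
#' Jeffreys (beta(k + 1/2, n - k + 1/2) quantiles).
#'
#' @param k number of successes (vectorised).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @param method \code{"clopper-pearson"}, \code{"wilson"} or
#'   \code{"jeffreys"}.
#' @return A \code{data.frame} with columns \code{estimate}, \code{ci_lo},
#'   \code{ci_hi}.
#' @examples
#' binomialMetrics(47, 48)
#' @export
binomialMetrics <- function(k, n, level = 0.95,
                            method = c("clopper-pearson", "wilson",
                                       "jeffreys")) {
    method <- match.arg(method)
    if (length(n) == 1L) n <- rep(n, length(k))
    stopifnot(length(k) == length(n))
    if (any(n < 1)) stop("undefined metric: n must be >= 1")
    if (any(k < 0 | k > n)) stop("k must lie in [0, n]")
    a <- 1 - level
    est <- k / n
    if (method == "clopper-pearson") {
        lo <- ifelse(k == 0, 0, stats::qbeta(a / 2, k, n - k + 1))
        hi <- ifelse(k == n, 1, stats::qbeta(1 - a / 2, k + 1, n - k))
    } else if (method == "jeffreys") {
        lo <- ifelse(k == 0, 0, stats::qbeta(a / 2, k + 0.5, n - k + 0.5))
        hi <- ifelse(k == n, 1, stats::qbeta(1 - a / 2, k + 0.5, n - k + 0.5))
    } else {
        z <- stats::qnorm(1 - a / 2)
        ctr <- (est + z^2 / (2 * n)) / (1 + z^2 / n)
        hw <- z * sqrt(est * (1 - est) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
        lo <- pmax(0, ctr - hw)
        hi <- pmin(1, ctr + hw)
    }
    data.frame(estimate = est, ci_lo = lo, ci_hi = hi)
}

#' Sensitivity, specificity and PPV table from confusion counts
#'
#' Produces the standard performance table: one row per (chromosome, metric)
#' with the binomial point estimate and confidence interval. Sensitivity is
#' \code{TP / (TP + FN)}, specificity \code{TN / (TN + FP)} and positive
#' predictive value \code{TP / (TP + FP)}; rows whose denominator is zero
#' are reported as \code{NA}.
#'
#' @param conf a confusion table from \code{\link{confusionCounts}}.
#' @param level,method passed to \code{\link{binomialMetrics}}.
#' @return A \code{data.frame} with columns \code{chrom}, \code{metric}
#'   (\code{SEN}/\code{SPC}/\code{PPV}), \code{k}, \code{n},
#'   \code{estimate}, \code{ci_lo}, \code{ci_hi}.
#' @export
metricsTable <- function(conf, level = 0.95, method = "clopper-pearson") {
    rows <- do.call(rbind, lapply(seq_len(nrow(conf)), function(i) {
        d <- conf[i, ]
        data.frame(chrom = d$chrom,
                   metric = c("SEN", "SPC", "PPV"),
                   k = c(d$TP, d$TN, d$TP),
                   n = c(d$TP + d$FN, d$TN + d$FP, d$TP + d$FP))
    }))
    est <- data.frame(estimate = rep(NA_real_, nrow(rows)),
                      ci_lo = NA_real_, ci_hi = NA_real_)
    ok <- rows$n >= 1
    est[ok, ] <- binomialMetrics(rows$k[ok], rows$n[ok], level = level,
                                 method = method)
    cbind(rows, est)
}

#' Two-sample proportion test with continuity correction
#'
#' Pooled two-sample test of \code{x1/n1} vs \code{x2/n2}: the
#' continuity-corrected z statistic
#' \code{z = (|p1 - p2| - c) / sqrt(p(1-p)(1/n1 + 1/n2))} with pooled
#' \code{p} and \code{c = (1/n1 + 1/n2)/2} (applied only when smaller than
#' \code{|p1 - p2|}); the two-sided p value comes from the chi-square(1)
#' tail of \code{z^2}. This is exactly the classical test computed by
#' \code{\link[stats]{prop.test}}, which does the work here.
#'
#' @param x1,n1,x2,n2 successes and trials of the two groups.
#' @param continuity apply the continuity correction (default \code{TRUE}).
#' @return An object of class \code{"propTest"}: list with \code{x1},
#'   \code{n1}, \code{x2}, \code{n2}, \code{z}, \code{chisq}, \code{p},
#'   \code{continuity}, \code{degenerate} (TRUE when the pooled proportion
#'   is 0 or 1, in which case \code{p = 1}).
#' @examples
#' twoProportionTest(1, 1188, 11, 1188)
#' @export
twoProportionTest <- function(x1, n1, x2, n2, continuity = TRUE) {
    stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
    pooled <- (x1 + x2) / (n1 + n2)
    if (pooled %in% c(0, 1)) {
        out <- list(x1 = x1, n1 = n1, x2 = x2, n2 = n2, z = 0, chisq = 0,
                    p = 1, continuity = continuity, degenerate = TRUE)
        return(structure(out, class = "propTest"))
    }
    ht <- suppressWarnings(
        stats::prop.test(c(x1, x2), c(n1, n2), correct = continuity))
    chisq <- unname(ht$statistic)
    structure(list(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
                   z = sqrt(chisq) * sign(x1 / n1 - x2 / n2),
                   chisq = chisq, p = ht$p.value,
                   continuity = continuity, degenerate = FALSE),
              class = "propTest")
}

#' @export
print.propTest <- function(x, ...) {
    cat(sprintf(
        "two-sample proportion test%s: %d/%d vs %d/%d, chi-sq = %.4f, p = %.4g%s\n",
        if (x$continuity) " (continuity-corrected)" else "",
        x$x1, x$n1, x$x2, x$n2, x$chisq, x$p,
        if (x$degenerate) " [degenerate]" else ""))
    invisible(x)
}

#' Read a table of calls produced by an external caller
#'
#' Third-party callers are consumed as data: a TSV with columns
#' \code{library_id} (or \code{sample_id}), \code{chrom} and \code{call},
#' labels restricted to \code{trisomy}, \code{normal}, \code{ambiguous} and
#' \code{no_call}. The result feeds \code{\link{confusionCounts}} and
#' \code{\link{twoProportionTest}} exactly like the package's own calls.
#'
#' @param path TSV path (leading \code{#} comment lines allowed).
#' @return A calls \code{data.frame} with \code{library_id},
#'   \code{sample_id}, \code{chrom}, \code{call}; an empty file body yields
#'   a zero-row frame.
#' @export
ingestExternalCalls <- function(path) {
    df <- .readTsv(path, colClasses = "character")
    if (!"chrom" %in% colnames(df) || !"call" %in% colnames(df))
        stop("external call table ", path,
             " needs 'chrom' and 'call' columns")
    if (is.null(df$library_id)) {
        if (is.null(df$sample_id))
            stop("external call table ", path,
                 " needs 'library_id' or 'sample_id'")
        df$library_id <- df$sample_id
    }
    if (is.null(df$sample_id)) df$sample_id <- df$library_id
    ok <- c("trisomy", "normal", "ambiguous", "no_call")
    bad <- setdiff(unique(df$call), ok)
    if (length(bad))
        stop("external call table ", path, ": unknown call label(s) ",
             paste(sQuote(bad), collapse = ", "),
             " (expected ", paste(ok, collapse = "/"), ")")
    df[c("library_id", "sample_id", "chrom", "call")]
}
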