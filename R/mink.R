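#' Caller configuration
#'
#' Bundle of every tunable of the MINK caller with its default. The
#' defaults are the documented design choices of the pipeline; any field can
#' be overridden by name.
#'
#' @param eps pseudocount added to size-scaled counts before the log2 ratio
#'   (default 0.5); together with \code{minCount} it keeps zero-inflated bins
#'   from generating infinite ratios.
#' @param minCount bins with a raw count below this in either library of a
#'   pair are dropped from both ratio vectors (default 1).
#' @param tLo,tHi median-p call thresholds: trisomy when the median p is
#'   <= \code{tLo} (default 0.05), normal when >= \code{tHi} (default 0.1),
#'   ambiguous in between.
#' @param form regression form for the pairwise GC model: \code{"linear"}
#'   (default) or \code{"quadratic"}.
#' @param direction alternative for the target test: \code{"gain"} (default,
#'   trisomy inflates the target), \code{"loss"} or \code{"two-sided"}.
#' @param targetChroms chromosomes tested for aneuploidy (default
#'   chr13/14/18/21).
#' @param excludeChroms chromosomes never used as diploid training material;
#'   defaults to all potentially aneuploid targets plus the sex chromosomes,
#'   so a trisomy elsewhere cannot contaminate a fit.
#' @param minTraining,minTarget minimum numbers of training / target bins for
#'   a pairwise comparison (defaults 30 and 2).
#' @param span,degreeLoess,robustIters GC-correction (loess) parameters, used
#'   where the caller performs the correction itself.
#' @param useCorrected prefer the \code{"corrected"} assay when present
#'   (default \code{TRUE}).
#' @return A named list of class \code{"minkConfig"}.
#' @export
minkConfig <- function(eps = 0.5, minCount = 1, tLo = 0.05, tHi = 0.1,
                       form = c("linear", "quadratic"),
                       direction = c("gain", "loss", "two-sided"),
                       targetChroms = c("chr13", "chr14", "chr18", "chr21"),
                       excludeChroms = NULL,
                       minTraining = 30L, minTarget = 2L,
                       span = 0.3, degreeLoess = 2, robustIters = 2,
                       useCorrected = TRUE) {
    form <- match.arg(form)
    direction <- match.arg(direction)
    if (tLo > tHi) stop("'tLo' must not exceed 'tHi'")
    if (is.null(excludeChroms))
        excludeChroms <- union(targetChroms,
                               c("chrX", "chrY", "X", "Y"))
    structure(list(eps = eps, minCount = minCount, tLo = tLo, tHi = tHi,
                   form = form, direction = direction,
                   targetChroms = targetChroms,
                   excludeChroms = excludeChroms,
                   minTraining = as.integer(minTraining),
                   minTarget = as.integer(minTarget),
                   span = span, degreeLoess = degreeLoess,
                   robustIters = robustIters,
                   useCorrected = useCorrected),
              class = "minkConfig")
}

.insufficientData <- function(msg) {
    stop(structure(class = c("minkInsufficientData", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

#' Pairwise log2 count ratios between a test and a reference library
#'
#' Both libraries are scaled to a common total over the training bins (their
#' mean training total), removing pure depth differences, and the per-bin
#' ratio \code{r_i = log2((a_i + eps) / (b_i + eps))} is formed from the
#' scaled test (\code{a}) and reference (\code{b}) values. The training
#' vector covers unmasked autosomal bins excluding the target chromosome and
#' every excluded chromosome; the target vector covers unmasked bins of the
#' target chromosome. Bins whose \emph{raw} count falls below
#' \code{minCount} in either library are dropped from both vectors.
#'
#' @param testRow,refRow numeric vectors of (possibly GC-corrected) bin
#'   values aligned to \code{bins}.
#' @param bins a \linkS4class{BinSet}.
#' @param targetChrom the chromosome under test.
#' @param excludeChroms chromosomes excluded from training (the target is
#'   always excluded).
#' @param eps,minCount see \code{\link{minkConfig}}.
#' @param testRaw,refRaw raw integer counts used for the \code{minCount}
#'   filter when \code{testRow}/\code{refRow} hold corrected values
#'   (default: the rows themselves).
#' @param minTraining,minTarget minimum vector sizes; an
#'   insufficient-data error (condition class \code{minkInsufficientData})
#'   is raised below them.
#' @return A list with data frames \code{training} and \code{target}, each
#'   with columns \code{bin} (index into \code{bins}), \code{gc} and
#'   \code{r}.
#' @export
pairwiseLog2Ratios <- function(testRow, refRow, bins, targetChrom,
                               excludeChroms = character(0), eps = 0.5,
                               minCount = 1, testRaw = testRow,
                               refRaw = refRow, minTraining = 30L,
                               minTarget = 2L) {
    stopifnot(length(testRow) == length(bins),
              length(refRow) == length(bins))
    chrom <- as.character(seqnames(bins))
    gc <- binGC(bins)
    usable <- !binMasked(bins) & !is.na(gc) &
        !is.na(testRow) & !is.na(refRow) &
        testRaw >= minCount & refRaw >= minCount
    sex <- c("chrX", "chrY", "X", "Y")
    train <- which(usable & !(chrom %in% c(targetChrom, excludeChroms, sex)))
    targ <- which(usable & chrom == targetChrom)
    if (length(train) < minTraining)
        .insufficientData(sprintf(
            "only %d training bins (need >= %d) for target %s",
            length(train), minTraining, targetChrom))
    if (length(targ) < minTarget)
        .insufficientData(sprintf(
            "only %d target bins (need >= %d) on %s",
            length(targ), minTarget, targetChrom))
    sA <- sum(testRow[train]); sB <- sum(refRow[train])
    if (sA <= 0 || sB <= 0)
        .insufficientData("zero training total in one of the libraries")
    common <- (sA + sB) / 2
    a <- testRow * (common / sA)
    b <- refRow * (common / sB)
    r <- log2((a + eps) / (b + eps))
    list(training = data.frame(bin = train, gc = gc[train], r = r[train]),
         target = data.frame(bin = targ, gc = gc[targ], r = r[targ]))
}

#' Fit the diploid GC model of one pairwise comparison
#'
#' Ordinary least squares of the training log2 ratios on GC content
#' (intercept + GC, plus GC^2 for the quadratic form, plus any covariate
#' columns supplied per bin). The residual standard deviation uses
#' \code{df = n - p} and is floored at 1e-8 so a perfect fit cannot produce
#' a zero-variance prediction downstream.
#'
#' @param training data frame with columns \code{gc} and \code{r} (as
#'   produced by \code{\link{pairwiseLog2Ratios}}); any extra numeric
#'   columns named in \code{covariates} enter the design.
#' @param form \code{"linear"} or \code{"quadratic"}.
#' @param covariates character vector of covariate column names in
#'   \code{training} (default none).
#' @param minTraining minimum training size (default 30).
#' @return An object of class \code{"minkFit"}: list with \code{coef},
#'   \code{s} (residual sd), \code{df}, \code{nTrain}, \code{form},
#'   \code{covariates}.
#' @export
fitDiploidModel <- function(training, form = c("linear", "quadratic"),
                            covariates = character(0), minTraining = 30L) {
    form <- match.arg(form)
    n <- nrow(training)
    if (n < minTraining)
        .insufficientData(sprintf("training size %d < %d", n, minTraining))
    X <- cbind(`(Intercept)` = 1, gc = training$gc)
    if (form == "quadratic") X <- cbind(X, gc2 = training$gc^2)
    for (cv in covariates) {
        if (is.null(training[[cv]]))
            stop("covariate column '", cv, "' not in training data")
        X <- cbind(X, training[[cv]])
        colnames(X)[ncol(X)] <- cv
    }
    fit <- stats::lm.fit(X, training$r)
    if (fit$rank < ncol(X)) {
        dropped <- colnames(X)[is.na(fit$coefficients)]
        stop("rank-deficient GC design; collinear column(s): ",
             paste(dropped, collapse = ", "))
    }
    df <- n - ncol(X)
    s <- sqrt(sum(fit$residuals^2) / df)
    structure(list(coef = fit$coefficients, s = max(s, 1e-8), df = df,
                   nTrain = n, form = form, covariates = covariates),
              class = "minkFit")
}

.predictMinkFit <- function(fit, newdata) {
    X <- cbind(`(Intercept)` = 1, gc = newdata$gc)
    if (fit$form == "quadratic") X <- cbind(X, gc2 = newdata$gc^2)
    for (cv in fit$covariates) X <- cbind(X, newdata[[cv]])
    drop(X %*% fit$coef)
}

#' @export
print.minkFit <- function(x, ...) {
    cat(sprintf("minkFit (%s): n = %d, s = %.4g, df = %d\n",
                x$form, x$nTrain, x$s, x$df))
    print(round(x$coef, 6))
    invisible(x)
}

#' Test the target chromosome of one pairwise comparison
#'
#' The fitted diploid model predicts the log2 ratio expected at each target
#' bin's GC; the one-sample t statistic on the prediction residuals
#' \code{d_i = r_i - rhat_i} is \code{t = mean(d) / (sd(d) / sqrt(m))} with
#' \code{m - 1} degrees of freedom. Under a fetal trisomy the target ratios
#' shift up by about \code{log2(1 + f/2)} (fetal fraction \code{f}), so the
#' default alternative is \code{"gain"} (upper tail).
#'
#' @param fit a \code{"minkFit"} from \code{\link{fitDiploidModel}}.
#' @param target data frame of target bins (columns \code{gc}, \code{r},
#'   plus covariates if the fit uses any), m >= 2 rows.
#' @param direction \code{"gain"}, \code{"loss"} or \code{"two-sided"}.
#' @return An object of class \code{"minkTest"}: list with \code{m},
#'   \code{meanObserved}, \code{meanPredicted}, \code{t}, \code{df},
#'   \code{p}, \code{direction}, \code{degenerate} (TRUE when the residual
#'   sd was exactly zero and the p value was set by the sign of the mean).
#' @export
testTarget <- function(fit, target,
                       direction = c("gain", "loss", "two-sided")) {
    direction <- match.arg(direction)
    m <- nrow(target)
    if (m < 2L) .insufficientData(sprintf("only %d target bins (need >= 2)", m))
    rhat <- .predictMinkFit(fit, target)
    d <- target$r - rhat
    md <- mean(d)
    sdd <- stats::sd(d)
    df <- m - 1L
    degenerate <- FALSE
    if (sdd == 0) {
        degenerate <- md != 0
        tstat <- if (md == 0) 0 else sign(md) * Inf
    } else {
        tstat <- md / (sdd / sqrt(m))
    }
    p <- switch(direction,
        gain = stats::pt(tstat, df, lower.tail = FALSE),
        loss = stats::pt(tstat, df, lower.tail = TRUE),
        `two-sided` = 2 * stats::pt(-abs(tstat), df))
    structure(list(m = m, meanObserved = mean(target$r),
                   meanPredicted = mean(rhat), t = tstat, df = df, p = p,
                   direction = direction, degenerate = degenerate),
              class = "minkTest")
}

#' @export
print.minkTest <- function(x, ...) {
    cat(sprintf(
        "minkTest (%s): m = %d, mean obs %.4g vs pred %.4g, t = %.3f (df %d), p = %.4g%s\n",
        x$direction, x$m, x$meanObserved, x$meanPredicted, x$t, x$df, x$p,
        if (x$degenerate) " [degenerate]" else ""))
    invisible(x)
}

#' Call one library for one target chromosome against a reference panel
#'
#' Runs one pairwise comparison per reference library (the test library is
#' excluded from the panel if present), collects the p values and applies the
#' median-p rule: trisomy when the median p is <= \code{tLo}, normal when
#' >= \code{tHi}, ambiguous in between. References failing with an
#' insufficient-data condition are skipped and counted, never fatal; zero
#' usable references is an error.
#'
#' @param values bins-x-libraries numeric matrix (GC-corrected or raw; the
#'   choice is the caller's and is recorded in the result).
#' @param bins the \linkS4class{BinSet}.
#' @param testId column name of the library under test.
#' @param refIds column names of the reference panel.
#' @param targetChrom chromosome to test.
#' @param config a \code{\link{minkConfig}}.
#' @param raw optional matrix of raw counts for the \code{minCount} filter
#'   (default \code{values}).
#' @return An object of class \code{"aneuploidyCall"}: list with
#'   \code{libraryId}, \code{targetChrom}, \code{p} (named vector, one entry
#'   per usable reference), \code{medianP}, \code{call} (\code{"trisomy"},
#'   \code{"normal"} or \code{"ambiguous"}), \code{nRefsUsed},
#'   \code{nRefsSkipped}, \code{valuesUsed}.
#' @export
minkCall <- function(values, bins, testId, refIds, targetChrom,
                     config = minkConfig(), raw = values) {
    refIds <- setdiff(refIds, testId)
    if (!length(refIds)) stop("no usable reference libraries after self-exclusion")
    if (!testId %in% colnames(values))
        stop("test library '", testId, "' not in the value matrix")
    p <- rep(NA_real_, length(refIds))
    names(p) <- refIds
    skipped <- character(0)
    for (rid in refIds) {
        res <- tryCatch({
            rv <- pairwiseLog2Ratios(
                values[, testId], values[, rid], bins, targetChrom,
                excludeChroms = config$excludeChroms, eps = config$eps,
                minCount = config$minCount, testRaw = raw[, testId],
                refRaw = raw[, rid], minTraining = config$minTraining,
                minTarget = config$minTarget)
            fit <- fitDiploidModel(rv$training, form = config$form,
                                   minTraining = config$minTraining)
            testTarget(fit, rv$target, direction = config$direction)$p
        }, minkInsufficientData = function(e) NA_real_)
        if (is.na(res)) skipped <- c(skipped, rid) else p[rid] <- res
    }
    p <- p[!is.na(p)]
    if (!length(p))
        stop("all ", length(refIds), " references were skipped for '",
             testId, "' on ", targetChrom)
    medp <- stats::median(p)
    call <- callFromMedianP(medp, config$tLo, config$tHi)
    structure(list(libraryId = testId, targetChrom = targetChrom, p = p,
                   medianP = medp, call = call, nRefsUsed = length(p),
                   nRefsSkipped = length(skipped),
                   skippedRefs = skipped,
                   valuesUsed = if (identical(values, raw)) "raw" else "corrected"),
              class = "aneuploidyCall")
}

#' @export
print.aneuploidyCall <- function(x, ...) {
    cat(sprintf("aneuploidyCall: %s on %s -> %s (median p = %.4g over %d refs%s)\n",
                x$libraryId, x$targetChrom, x$call, x$medianP, x$nRefsUsed,
                if (x$nRefsSkipped) sprintf(", %d skipped", x$nRefsSkipped)
                else ""))
    invisible(x)
}

#' Call every test library for every target chromosome
#'
#' Applies \code{\link{minkCall}} over a whole cohort. The reference panel is
#' taken from the \code{role} column of the library metadata; by default
#' every library (including the references themselves, which are then tested
#' against the panel minus themselves) is tested for every target
#' chromosome. Per-library failures become \code{"no_call"} rows; the cohort
#' never aborts.
#'
#' @param x a \linkS4class{MinkCountSet}; when a \code{"corrected"} assay is
#'   present and \code{config$useCorrected} is \code{TRUE} it supplies the
#'   values and the raw counts drive the \code{minCount} filter.
#' @param config a \code{\link{minkConfig}}.
#' @param testIds libraries to test (default: all columns).
#' @param refIds reference panel (default: libraries with
#'   \code{role == "reference"}).
#' @return A \code{data.frame} with one row per (library, target chromosome):
#'   \code{library_id}, \code{sample_id}, \code{chrom}, \code{n_refs},
#'   \code{median_p}, \code{call}.
#' @seealso \code{\link{sampleRollup}} for the per-sample aggregation.
#' @export
callCohort <- function(x, config = minkConfig(), testIds = colnames(x),
                       refIds = NULL) {
    stopifnot(is(x, "MinkCountSet"))
    if (is.null(refIds))
        refIds <- colnames(x)[libraryMeta(x)$role == "reference"]
    if (!length(refIds)) stop("no reference libraries in the cohort")
    raw <- countsMatrix(x)
    values <- if (config$useCorrected &&
                  "corrected" %in% SummarizedExperiment::assayNames(x))
        correctedMatrix(x) else raw
    bins <- binSet(x)
    sample_of <- stats::setNames(libraryMeta(x)$sample_id, colnames(x))
    rows <- vector("list", length(testIds) * length(config$targetChroms))
    k <- 0L
    for (lib in testIds) {
        for (chrom in config$targetChroms) {
            k <- k + 1L
            res <- tryCatch(
                minkCall(values, bins, lib, refIds, chrom, config, raw = raw),
                error = function(e) e)
            rows[[k]] <- if (inherits(res, "error"))
                data.frame(library_id = lib, sample_id = sample_of[[lib]],
                           chrom = chrom, n_refs = 0L, median_p = NA_real_,
                           call = "no_call")
            else
                data.frame(library_id = lib, sample_id = sample_of[[lib]],
                           chrom = chrom, n_refs = res$nRefsUsed,
                           median_p = res$medianP, call = res$call)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' The median-p calling rule
#'
#' A library is called trisomic for the target chromosome when the median of
#' its pairwise p values is at most \code{tLo}, normal when it is at least
#' \code{tHi}, and ambiguous (needing further investigation) in between.
#'
#' @param medianP median pairwise p value(s); vectorised.
#' @param tLo,tHi thresholds (defaults 0.05 and 0.1).
#' @return Character vector: \code{"trisomy"}, \code{"normal"} or
#'   \code{"ambiguous"}.
#' @examples
#' callFromMedianP(c(0.04, 0.55, 0.07))
#' @export
callFromMedianP <- function(medianP, tLo = 0.05, tHi = 0.1) {
    ifelse(medianP <= tLo, "trisomy",
           ifelse(medianP >= tHi, "normal", "ambiguous"))
}

#' Aggregate library-level calls to sample level
#'
#' A sample is called trisomic for a chromosome if any of its libraries is,
#' normal if all are normal, and ambiguous otherwise; samples whose libraries
#' disagree on trisomy vs normal are flagged discordant. Libraries with
#' \code{"no_call"} are ignored for the rollup unless all of a sample's
#' libraries failed, in which case the sample is \code{"no_call"}.
#'
#' @param calls the data frame returned by \code{\link{callCohort}}.
#' @return A \code{data.frame} with columns \code{sample_id}, \code{chrom},
#'   \code{n_libraries}, \code{call}, \code{discordant}.
#' @export
sampleRollup <- function(calls) {
    key <- interaction(calls$sample_id, calls$chrom, drop = TRUE)
    parts <- split(calls, key)
    out <- do.call(rbind, lapply(parts, function(d) {
        cc <- d$call[d$call != "no_call"]
        call <- if (!length(cc)) "no_call"
            else if (any(cc == "trisomy")) "trisomy"
            else if (all(cc == "normal")) "normal"
            else "ambiguous"
        data.frame(sample_id = d$sample_id[1L], chrom = d$chrom[1L],
                   n_libraries = nrow(d), call = call,
                   discordant = any(cc == "trisomy") && any(cc == "normal"))
    }))
    rownames(out) <- NULL
    out[order(out$sample_id, out$chrom), ]
}

#' Power of the MINK test for a given fetal fraction
#'
#' A fetal trisomy shifts the mean target-bin log2 ratio by
#' \code{delta = log2(1 + f/2)} (a loss by \code{-log2(1 - f/2)} in the
#' tested direction). The per-pair power is the noncentral-t probability
#' that the one-sample t on \code{m} target bins with residual sd
#' \code{s} exceeds its level-\code{alpha} critical value, with
#' noncentrality \code{delta / (s / sqrt(m))}. When \code{nRefs} is given,
#' the power of the median-p call is approximated by the binomial
#' probability that more than half of \code{nRefs} pairwise tests reject at
#' \code{alpha}, treating the pairwise tests as independent -- an
#' approximation, since all pairs share the test library's noise.
#'
#' @param f fetal fraction in [0, 1].
#' @param m number of target-chromosome bins.
#' @param s residual standard deviation of the per-bin log2 ratios.
#' @param alpha per-test level (default 0.05, the trisomy threshold of the
#'   median-p rule).
#' @param nRefs optional reference-panel size for the cohort-level
#'   approximation.
#' @param direction \code{"gain"} (default) or \code{"loss"}.
#' @return A list with \code{delta} (expected shift), \code{perTest}
#'   (power of one pairwise test; exactly \code{alpha} at \code{f = 0}) and
#'   \code{cohort} (median-rule approximation, \code{NA} without
#'   \code{nRefs}).
#' @examples
#' powerEstimate(f = 0.1, m = 100, s = 0.15, nRefs = 40)
#' @export
powerEstimate <- function(f, m, s, alpha = 0.05, nRefs = NULL,
                          direction = c("gain", "loss")) {
    direction <- match.arg(direction)
    stopifnot(f >= 0, f <= 1, m >= 2, s > 0, alpha > 0, alpha < 1)
    delta <- if (direction == "gain") log2(1 + f / 2) else -log2(1 - f / 2)
    df <- m - 1
    ncp <- delta / (s / sqrt(m))
    crit <- stats::qt(1 - alpha, df)
    perTest <- if (ncp == 0) alpha
               else stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
    cohort <- NA_real_
    if (!is.null(nRefs)) {
        need <- floor(nRefs / 2) + 1L
        cohort <- stats::pbinom(need - 1L, nRefs, perTest, lower.tail = FALSE)
    }
    list(delta = delta, perTest = perTest, cohort = cohort)
}
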