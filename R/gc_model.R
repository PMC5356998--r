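#' Local (loess-style) regression
#'
#' Tricube-weighted local polynomial regression with bisquare robustness
#' iterations -- the smoother used to model the dependence of bin counts on
#' GC content. At each evaluation point the \code{ceil(span * n)} nearest
#' neighbours (by distance in \code{x}) are fit with a weighted polynomial of
#' the given degree; weights are tricube in \code{d / d_max}, where
#' \code{d_max} is the q-th smallest distance, so points at the window
#' boundary get weight zero and distance ties are inconsequential. Each
#' robustness iteration recomputes the fit with bisquare weights
#' \code{(1 - (r / 6m)^2)^2} on the residuals \code{r} (\code{m} the median
#' absolute residual), which discounts outlying bins.
#'
#' @param x,y numeric vectors of equal length (n >= max(10, degree + 2)); all
#'   values finite.
#' @param span fraction of points in each local window, in (0, 1]; the window
#'   holds \code{ceil(span * n)} points (default 0.3).
#' @param degree polynomial degree, 1 or 2 (default 2).
#' @param robustIters number of bisquare robustness iterations (default 2;
#'   0 gives plain weighted least squares).
#' @param at evaluation abscissae (default \code{x}: a fitted value at every
#'   input point).
#' @return An object of class \code{"localFit"}: a list with \code{x} (the
#'   evaluation abscissae, as given), \code{fitted} (fitted values at
#'   \code{at}), \code{fittedTrain} (fitted values at the training \code{x}),
#'   \code{robustWeights}, \code{span}, \code{degree}, \code{robustIters} and
#'   \code{q} (window size in points).
#' @examples
#' set.seed(1)
#' x <- runif(200); y <- sin(2 * x) + rnorm(200, sd = 0.1)
#' f <- localRegression(x, y, span = 0.4)
#' cor(f$fitted, sin(2 * x))
#' @export
localRegression <- function(x, y, span = 0.3, degree = 2, robustIters = 2,
                            at = x) {
    if (length(x) != length(y))
        stop("'x' and 'y' must have equal length")
    n <- length(x)
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("non-finite values in 'x' or 'y'")
    if (!degree %in% c(1L, 2L)) stop("'degree' must be 1 or 2")
    if (length(span) != 1L || span <= 0 || span > 1)
        stop("'span' must lie in (0, 1]")
    if (n < max(10L, degree + 2L))
        stop(sprintf("need at least %d points, got %d",
                     max(10L, degree + 2L), n))
    q <- ceiling(span * n)
    if (q < degree + 2L)
        stop(sprintf(
            "span %.3g too small for degree %d at n = %d (window %d < %d)",
            span, degree, n, q, degree + 2L))
    if (robustIters < 0) stop("'robustIters' must be >= 0")
    res <- .local_regression_cpp(as.numeric(x), as.numeric(y), span,
                                 as.integer(degree), as.integer(robustIters),
                                 as.numeric(at))
    structure(
        list(x = at, fitted = res$fitted, fittedTrain = res$fitted_train,
             robustWeights = res$robust_weights, span = span,
             degree = as.integer(degree), robustIters = as.integer(robustIters),
             q = res$q),
        class = "localFit")
}

#' @export
print.localFit <- function(x, ...) {
    cat(sprintf(
        "localFit: degree %d, span %.2f (window %d points), %d robustness iteration(s)\n",
        x$degree, x$span, x$q, x$robustIters))
    cat(sprintf("  %d evaluation points, fitted range [%.4g, %.4g]\n",
                length(x$fitted), min(x$fitted), max(x$fitted)))
    invisible(x)
}

#' GC-bias correction of binned counts
#'
#' Removes the library-specific dependence of bin counts on GC content by
#' local regression of counts against per-bin GC. The correction is
#' multiplicative and normalised to the median fitted value:
#' \code{corrected_i = count_i * m / max(f(gc_i), floor)}, with \code{f} the
#' local-regression fit over unmasked autosomal bins, \code{m} the median of
#' \code{f} over those bins, and \code{floor = floorFrac * m} a small guard
#' against division by (near-)zero. This keeps corrected values non-negative
#' and leaves the overall scale comparable across libraries. Sex chromosomes
#' are corrected with the autosomal fit but never used to estimate it: their
#' counts depend on fetal sex, which would distort the bias curve. Masked
#' bins and bins without GC propagate as \code{NA}.
#'
#' Degenerate inputs fall back to the identity with a warning: all GC values
#' equal (no bias curve to fit) or a non-positive median fitted value (e.g.
#' an all-zero library).
#'
#' @param x counts: a numeric vector (one library), a bins-x-libraries
#'   matrix, or a \linkS4class{MinkCountSet}.
#' @param bins the \linkS4class{BinSet} the counts align to (taken from the
#'   object when \code{x} is a \code{MinkCountSet}).
#' @param span,degree,robustIters passed to \code{\link{localRegression}}.
#' @param floorFrac fraction of the median fitted value used as the
#'   denominator floor (default 1e-6).
#' @param sexChroms chromosome names excluded from the fit domain (default
#'   \code{c("chrX", "chrY", "X", "Y")}).
#' @return Same shape as the input: a numeric vector / matrix of corrected
#'   counts, or the \code{MinkCountSet} with a \code{"corrected"} assay
#'   added.
#' @examples
#' bins <- makeBins(c(chr1 = 50000 * 200), width = 50000)
#' binGC(bins) <- runif(200, 0.3, 0.6)
#' cts <- rpois(200, 100 * exp(-2 * (binGC(bins) - 0.45)^2 * 10))
#' cc <- gcCorrect(cts, bins)
#' cor(cc, binGC(bins))
#' @export
setGeneric("gcCorrect", function(x, bins, ...) standardGeneric("gcCorrect"))

.gcCorrectRow <- function(counts, bins, span, degree, robustIters,
                          floorFrac, sexChroms) {
    gc <- binGC(bins)
    chrom <- as.character(seqnames(bins))
    usable <- !binMasked(bins) & !is.na(gc)
    domain <- usable & !(chrom %in% sexChroms)
    out <- rep(NA_real_, length(counts))
    if (sum(domain) < max(10L, degree + 2L))
        stop(sprintf("only %d usable autosomal bins; cannot fit GC model",
                     sum(domain)))
    if (length(unique(gc[domain])) == 1L) {
        warning("all GC values identical; GC correction is the identity")
        out[usable] <- counts[usable]
        return(out)
    }
    fit <- localRegression(gc[domain], counts[domain], span = span,
                           degree = degree, robustIters = robustIters,
                           at = gc[usable])
    m <- stats::median(fit$fittedTrain)
    if (!is.finite(m) || m <= 0) {
        warning("non-positive median fitted count; GC correction is the identity")
        out[usable] <- counts[usable]
        return(out)
    }
    denom <- pmax(fit$fitted, floorFrac * m)
    out[usable] <- counts[usable] * m / denom
    out
}

#' @rdname gcCorrect
#' @export
setMethod("gcCorrect", signature(x = "numeric", bins = "BinSet"),
    function(x, bins, span = 0.3, degree = 2, robustIters = 2,
             floorFrac = 1e-6, sexChroms = c("chrX", "chrY", "X", "Y")) {
        if (length(x) != length(bins))
            stop("counts length does not match the bin set")
        .gcCorrectRow(x, bins, span, degree, robustIters, floorFrac, sexChroms)
    })

#' @rdname gcCorrect
#' @export
setMethod("gcCorrect", signature(x = "matrix", bins = "BinSet"),
    function(x, bins, span = 0.3, degree = 2, robustIters = 2,
             floorFrac = 1e-6, sexChroms = c("chrX", "chrY", "X", "Y")) {
        out <- apply(x, 2L, .gcCorrectRow, bins = bins, span = span,
                     degree = degree, robustIters = robustIters,
                     floorFrac = floorFrac, sexChroms = sexChroms)
        dimnames(out) <- dimnames(x)
        out
    })

#' @rdname gcCorrect
#' @export
setMethod("gcCorrect", signature(x = "MinkCountSet", bins = "missing"),
    function(x, bins, span = 0.3, degree = 2, robustIters = 2,
             floorFrac = 1e-6, sexChroms = c("chrX", "chrY", "X", "Y")) {
        corrected <- gcCorrect(countsMatrix(x), binSet(x), span = span,
                               degree = degree, robustIters = robustIters,
                               floorFrac = floorFrac, sexChroms = sexChroms)
        assay(x, "corrected") <- corrected
        x
    })
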