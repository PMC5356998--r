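#' Configuration of the synthetic-cohort simulator
#'
#' The simulator emulates the statistical structure of binned maternal-plasma
#' shotgun counts with known ground truth: per-bin GC drawn from a beta
#' distribution, a latent per-bin propensity shared by every library
#' (mappability-like), a smooth library-specific GC bias on the log scale,
#' negative-binomial counting noise, and a fetal-trisomy dosage effect that
#' inflates target-chromosome expectations by \code{1 + f/2} at fetal
#' fraction \code{f}.
#'
#' The default genome is scaled down -- 22 autosomes of 5 Mb, i.e. 100 bins
#' of 50 kb each -- so whole-cohort pipelines run in seconds; a
#' \code{"grch37"} preset mirrors the relative chromosome sizes of the human
#' reference at full length.
#'
#' @param seed integer seed; together with the config it fully determines
#'   the cohort.
#' @param seqlens named chromosome lengths (default 22 autosomes x 5 Mb).
#' @param binWidth bin width in bp (default 50000).
#' @param gcMean,gcSd beta-distribution mean and sd of per-bin GC (defaults
#'   0.41 and 0.06, matching the bulk of the human genome).
#' @param maskFraction fraction of bins randomly masked (default 0.02).
#' @param binWeightSd sd of the log-normal per-bin baseline propensity,
#'   drawn once per genome and shared across libraries (default 0.1).
#' @param binJitterSd sd of the log-normal per-bin, per-library rate jitter
#'   (default 0.03): residual technical variation (library prep, residual
#'   mappability effects) that, unlike \code{binWeightSd}, does not cancel in
#'   pairwise ratios. This is what makes the reference side of a pairwise
#'   comparison noisy even for deep libraries and keeps the median-p rule
#'   calibrated on normals.
#' @param nReference,nTestNormal,nTestTrisomy cohort composition (defaults
#'   40 / 10 / 10, the composition of the depth-titration panel).
#' @param targetChrom trisomic chromosome of the affected test libraries
#'   (default \code{"chr21"}).
#' @param fetalRange fetal-fraction range, drawn uniformly per sample
#'   (default \code{c(0.04, 0.15)}, the clinically plausible early-gestation
#'   range).
#' @param libSizeRange aligned-read totals, drawn log-uniformly (default
#'   \code{c(1e6, 40e6)}, spanning small to large plasma libraries).
#' @param refSizeRange,testSizeRange role-specific overrides of
#'   \code{libSizeRange} (defaults \code{c(10e6, 40e6)} for references and
#'   \code{c(20e6, 40e6)} for test libraries, mirroring a titration design
#'   where references are deep and test libraries must survive thinning to
#'   20M).
#' @param biasSlopeSd sd of the linear log-bias coefficient (default 1.5).
#' @param biasCurvRange,biasPeakRange curvature and peak-location ranges of
#'   the quadratic log-bias, drawn uniformly per library (defaults
#'   \code{c(-12, -4)} and \code{c(0.30, 0.55)}).
#' @param phi negative-binomial dispersion: \code{var = mu + phi * mu^2}
#'   (default 5e-4; 0 gives Poisson counts).
#' @return A named list of class \code{"simConfig"}.
#' @export
simConfig <- function(seed = 1,
                      seqlens = NULL,
                      binWidth = 50000,
                      gcMean = 0.41, gcSd = 0.06,
                      maskFraction = 0.02,
                      binWeightSd = 0.1,
                      binJitterSd = 0.03,
                      nReference = 40, nTestNormal = 10, nTestTrisomy = 10,
                      targetChrom = "chr21",
                      fetalRange = c(0.04, 0.15),
                      libSizeRange = c(1e6, 40e6),
                      refSizeRange = c(10e6, 40e6),
                      testSizeRange = c(20e6, 40e6),
                      biasSlopeSd = 1.5,
                      biasCurvRange = c(-12, -4),
                      biasPeakRange = c(0.30, 0.55),
                      phi = 5e-4) {
    if (is.null(seqlens))
        seqlens <- stats::setNames(rep(5e6, 22), paste0("chr", 1:22))
    if (identical(seqlens, "grch37"))
        seqlens <- grch37Seqlens()
    stopifnot(gcMean > 0, gcMean < 1, gcSd > 0,
              all(fetalRange >= 0), all(fetalRange <= 1), phi >= 0)
    structure(list(seed = seed, seqlens = seqlens, binWidth = binWidth,
                   gcMean = gcMean, gcSd = gcSd,
                   maskFraction = maskFraction, binWeightSd = binWeightSd,
                   binJitterSd = binJitterSd,
                   nReference = nReference, nTestNormal = nTestNormal,
                   nTestTrisomy = nTestTrisomy, targetChrom = targetChrom,
                   fetalRange = fetalRange, libSizeRange = libSizeRange,
                   refSizeRange = refSizeRange,
                   testSizeRange = testSizeRange,
                   biasSlopeSd = biasSlopeSd,
                   biasCurvRange = biasCurvRange,
                   biasPeakRange = biasPeakRange, phi = phi),
              class = "simConfig")
}

#' Autosome lengths of the GRCh37 human reference
#' @return Named numeric vector of the 22 autosome lengths in bp.
#' @export
grch37Seqlens <- function() {
    stats::setNames(c(
        249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
        159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
        115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
        59128983, 63025520, 48129895, 51304566), paste0("chr", 1:22))
}

#' Simulate the binned genome
#'
#' Builds the bin grid with \code{\link{makeBins}}, draws per-bin GC i.i.d.
#' from the configured beta distribution, masks a random bin fraction, and
#' draws the shared log-normal per-bin propensity (stored in the
#' \code{weight} metadata column and consumed by
#' \code{\link{simulateLibrary}}).
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed seed (default \code{config$seed}).
#' @return A \linkS4class{BinSet} with \code{gc}, \code{masked} and
#'   \code{weight} columns.
#' @export
simulateGenome <- function(config = simConfig(), seed = config$seed) {
    set.seed(seed)
    bins <- makeBins(config$seqlens, width = config$binWidth)
    n <- length(bins)
    v <- config$gcSd^2
    m <- config$gcMean
    nu <- m * (1 - m) / v - 1
    if (nu <= 0) stop("gcSd too large for gcMean (beta parameters <= 0)")
    mcols(bins)$gc <- stats::rbeta(n, m * nu, (1 - m) * nu)
    mcols(bins)$masked <- stats::runif(n) < config$maskFraction
    mcols(bins)$weight <- exp(stats::rnorm(n, 0, config$binWeightSd))
    bins
}

.drawTheta <- function(config) {
    list(slope = stats::rnorm(1, 0, config$biasSlopeSd),
         curv = stats::runif(1, config$biasCurvRange[1], config$biasCurvRange[2]),
         peak = stats::runif(1, config$biasPeakRange[1], config$biasPeakRange[2]))
}

.logBias <- function(gc, theta, center) {
    theta$slope * (gc - center) + theta$curv * (gc - theta$peak)^2
}

#' Simulate one sequencing library
#'
#' Per-bin rates are \code{lambda_i = w_i * j_i * exp(b(gc_i; theta)) * d_i},
#' where \code{w_i} is the shared bin propensity, \code{j_i} a log-normal
#' per-library bin jitter (sd \code{jitterSd}), \code{b} the
#' library-specific quadratic log-scale GC bias and \code{d_i} the fetal
#' dosage factor: \code{1 + f/2} on bins of a trisomic chromosome,
#' \code{1 - f/2} on a monosomic one (karyotype tokens \code{"+21"} /
#' \code{"-21"}), and 1 elsewhere. Rates are normalised to the library size
#' and counts drawn negative-binomially (\code{var = mu + phi * mu^2};
#' Poisson at \code{phi = 0}). Uses the current RNG state; seed upstream.
#'
#' @param bins a \linkS4class{BinSet} from \code{\link{simulateGenome}}
#'   (must carry the \code{weight} column).
#' @param N total expected aligned reads.
#' @param theta list with \code{slope}, \code{curv}, \code{peak} (GC-bias
#'   coefficients); \code{NULL} for no bias.
#' @param karyotype cytogenetic label, e.g. \code{"47,XX,+21"}.
#' @param f fetal fraction in [0, 1].
#' @param phi negative-binomial dispersion.
#' @param jitterSd sd of the per-library log-normal bin jitter (default 0).
#' @param gcCenter centre of the linear bias term (default 0.41).
#' @return Integer vector of counts, one per bin.
#' @export
simulateLibrary <- function(bins, N, theta = NULL, karyotype = "46,XY",
                            f = 0, phi = 5e-4, jitterSd = 0,
                            gcCenter = 0.41) {
    stopifnot(N >= 1, f >= 0, f <= 1)
    gc <- binGC(bins)
    w <- mcols(bins)$weight
    if (is.null(w)) w <- rep(1, length(bins))
    gcEff <- ifelse(is.na(gc), gcCenter, gc)
    lb <- if (is.null(theta)) 0 else .logBias(gcEff, theta, gcCenter)
    chrom <- as.character(seqnames(bins))
    d <- rep(1, length(bins))
    tri <- regmatches(karyotype, gregexpr("\\+[0-9XY]+", karyotype))[[1]]
    mono <- regmatches(karyotype, gregexpr("-[0-9XY]+", karyotype))[[1]]
    if (length(tri))
        d[chrom %in% paste0("chr", sub("^\\+", "", tri))] <- 1 + f / 2
    if (length(mono))
        d[chrom %in% paste0("chr", sub("^-", "", mono))] <- 1 - f / 2
    if (jitterSd > 0)
        w <- w * exp(stats::rnorm(length(bins), 0, jitterSd))
    lambda <- w * exp(lb) * d
    mu <- N * lambda / sum(lambda)
    if (phi > 0) stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
    else stats::rpois(length(mu), mu)
}

#' Simulate a full cohort with known truth
#'
#' Generates the genome, then one library per cohort member: references are
#' karyotypically normal; test libraries are normal or trisomic for the
#' target chromosome per the configured split. Each library gets its own
#' size (log-uniform within its role's range), GC-bias coefficients and --
#' per sample -- fetal fraction; the truth (karyotype, fetal fraction, role)
#' is recorded in the column data. Fully reproducible from the seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed seed (default \code{config$seed}).
#' @return A \linkS4class{MinkCountSet}; \code{libraryMeta(x)} is the truth
#'   table.
#' @examples
#' cfg <- simConfig(nReference = 4, nTestNormal = 2, nTestTrisomy = 2,
#'                  seqlens = setNames(rep(1e6, 4), paste0("chr", c(1, 2, 3, 21))))
#' simulateCohort(cfg, seed = 11)
#' @export
simulateCohort <- function(config = simConfig(), seed = config$seed) {
    bins <- simulateGenome(config, seed = seed)
    # genome generation consumed part of the stream; continue deterministically
    roles <- c(rep("reference", config$nReference),
               rep("test", config$nTestNormal + config$nTestTrisomy))
    kary <- c(rep("46,XY", config$nReference + config$nTestNormal),
              rep(sprintf("47,XX,+%s", sub("^chr", "", config$targetChrom)),
                  config$nTestTrisomy))
    ids <- c(sprintf("REF%02d", seq_len(config$nReference)),
             sprintf("TESTN%02d", seq_len(config$nTestNormal)),
             sprintf("TESTT%02d", seq_len(config$nTestTrisomy)))
    nlib <- length(ids)
    loguni <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
    counts <- matrix(0L, nrow = length(bins), ncol = nlib,
                     dimnames = list(NULL, ids))
    meta <- data.frame(row.names = ids,
                       sample_id = paste0("S_", ids),
                       karyotype = kary, role = roles,
                       fetal_fraction = NA_real_,
                       lib_size = NA_real_)
    for (j in seq_len(nlib)) {
        sizeRange <- if (roles[j] == "reference") {
            if (is.null(config$refSizeRange)) config$libSizeRange
            else config$refSizeRange
        } else {
            if (is.null(config$testSizeRange)) config$libSizeRange
            else config$testSizeRange
        }
        N <- loguni(sizeRange)
        f <- stats::runif(1, config$fetalRange[1], config$fetalRange[2])
        theta <- .drawTheta(config)
        counts[, j] <- simulateLibrary(bins, N, theta, kary[j], f,
                                       phi = config$phi,
                                       jitterSd = config$binJitterSd,
                                       gcCenter = config$gcMean)
        meta$fetal_fraction[j] <- f
        meta$lib_size[j] <- N
    }
    MinkCountSet(counts, bins, meta)
}
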