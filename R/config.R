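#' Flat run configuration for the command-line workflow
#'
#' Every tunable of the pipeline in one flat key=value structure that
#' round-trips bit-exactly through its file format and is echoed into the
#' header of every CLI output, so any result file records the configuration
#' that produced it.
#'
#' @param ... named overrides of the defaults.
#' @return Named list of class \code{"runConfig"} with fields
#'   \code{bin_width}, \code{eps}, \code{min_count}, \code{t_lo},
#'   \code{t_hi}, \code{span}, \code{degree}, \code{robust_iters},
#'   \code{form}, \code{direction}, \code{target_chroms}, \code{ci_method},
#'   \code{ci_level}, \code{depths}, \code{seed}.
#' @export
runConfig <- function(...) {
    def <- list(
        bin_width = 50000,
        eps = 0.5,
        min_count = 1,
        t_lo = 0.05,
        t_hi = 0.1,
        span = 0.3,
        degree = 2,
        robust_iters = 2,
        form = "linear",
        direction = "gain",
        target_chroms = c("chr13", "chr14", "chr18", "chr21"),
        ci_method = "clopper-pearson",
        ci_level = 0.95,
        depths = c(20, 15, 10, 8, 6, 4, 2, 1) * 1e6,
        seed = 1)
    ov <- list(...)
    bad <- setdiff(names(ov), names(def))
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    def[names(ov)] <- ov
    structure(def, class = "runConfig")
}

#' @rdname runConfig
#' @param config a \code{"runConfig"}.
#' @param path file path.
#' @export
writeRunConfig <- function(config, path) {
    lines <- vapply(names(config), function(k) {
        v <- config[[k]]
        sprintf("%s=%s", k,
                paste(format(v, scientific = FALSE, trim = TRUE),
                      collapse = ","))
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
    def <- runConfig()
    bad <- setdiff(keys, names(def))
    if (length(bad))
        stop("unknown config key(s) in ", path, ": ",
             paste(bad, collapse = ", "))
    out <- def
    for (i in seq_along(keys)) {
        parts <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
        out[[keys[i]]] <- if (is.numeric(def[[keys[i]]]))
            as.numeric(parts) else parts
    }
    structure(out, class = "runConfig")
}

#' @rdname runConfig
#' @export
configEcho <- function(config) {
    vapply(names(config), function(k)
        sprintf("%s=%s", k,
                paste(format(config[[k]], scientific = FALSE, trim = TRUE),
                      collapse = ",")), character(1))
}

#' Translate a runConfig into a caller configuration
#' @param config a \code{"runConfig"}.
#' @return A \code{\link{minkConfig}}.
#' @export
asMinkConfig <- function(config) {
    minkConfig(eps = config$eps, minCount = config$min_count,
               tLo = config$t_lo, tHi = config$t_hi,
               form = config$form, direction = config$direction,
               targetChroms = config$target_chroms,
               span = config$span, degreeLoess = config$degree,
               robustIters = config$robust_iters)
}
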