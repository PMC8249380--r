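#' Fit a power law to the reverse-cumulative CTSS count distribution
#'
#' Many CAGE datasets follow a power law: the number of CTSSs supported by
#' at least `x` tags falls off as `x^-alpha`.  The fit is ordinary least
#' squares of `log10(#CTSS with value >= x)` on `log10(x)` over the distinct
#' values inside `fitRange`; `alpha` is minus the slope.
#'
#' The fitting range is configurable because the extremes of the
#' distribution are unreliable: the default `c(5, 1000)` excludes the noisy
#' singleton tail and the sparse high-count head.
#'
#' @param x a [CTSSSample-class] (raw counts are fitted) or a numeric vector
#'   of values (e.g. normalized signal, for re-fitting).
#' @param fitRange length-2 numeric, inclusive value range used in the fit.
#'
#' @return an object of class `powerLawFit`: list with `alpha`, `intercept`,
#'   `rSquared`, `fitRange`, `nPoints`.
#' @examples
#' vals <- (seq_len(1000) / 2)^(-1 / 1.25) * 1000
#' fitPowerLaw(vals, fitRange = range(vals))$alpha
#' @export
fitPowerLaw <- function(x, fitRange = c(5, 1000)) {
    vals <- if (methods::is(x, "CTSSSample")) ctss(x)$count else as.numeric(x)
    stopifnot(length(fitRange) == 2L, fitRange[1L] < fitRange[2L],
              fitRange[1L] >= 1e-12)
    vals <- sort(vals)
    xs <- unique(vals[vals >= fitRange[1L] & vals <= fitRange[2L]])
    if (length(xs) < 2L)
        stop("fewer than 2 distinct values inside the fitting range; ",
             "widen fitRange")
    # reverse cumulative: number of values >= each threshold
    n <- length(vals)
    revCum <- n - findInterval(xs, vals, left.open = TRUE)
    fit <- stats::lm(log10(revCum) ~ log10(xs))
    structure(list(alpha = -unname(stats::coef(fit)[2L]),
                   intercept = unname(stats::coef(fit)[1L]),
                   rSquared = suppressWarnings(summary(fit))$r.squared,
                   fitRange = fitRange,
                   nPoints = length(xs)),
              class = "powerLawFit")
}

#' @export
print.powerLawFit <- function(x, ...) {
    cat(sprintf("power-law fit: alpha = %.4f (R^2 = %.3f, %d points in [%g, %g])\n",
                x$alpha, x$rSquared, x$nPoints, x$fitRange[1], x$fitRange[2]))
    invisible(x)
}

#' Build a common power-law normalization reference
#'
#' The reference slope is the median of the per-sample fitted slopes, and
#' all samples are normalized to a common total of `T` tags (default 10^6,
#' so normalized values are tags per million).
#'
#' @param fits list of `powerLawFit` objects (at least one).
#' @param T total tag target of the reference distribution.
#'
#' @return an object of class `normalizationSpec`: list with `alphaRef`,
#'   `T`, `alphas` (per-sample slopes).
#' @export
makeReference <- function(fits, T = 1e6) {
    if (!length(fits)) stop("need at least one power-law fit")
    stopifnot(T > 0)
    alphas <- vapply(fits, function(f) f$alpha, 0)
    structure(list(alphaRef = stats::median(alphas), T = T, alphas = alphas),
              class = "normalizationSpec")
}

#' @export
print.normalizationSpec <- function(x, ...) {
    cat(sprintf("normalization reference: alpha = %.4f, T = %g (%d samples)\n",
                x$alphaRef, x$T, length(x$alphas)))
    invisible(x)
}

#' Normalize a CTSS sample to tags per million
#'
#' Two methods are available.  `"powerLaw"` maps raw counts onto a
#' reference power law with slope `alphaRef` through the sample's own
#' fitted power law: a count `x` is sent to the value whose position on
#' the reference reverse-cumulative line equals `x`'s position on the
#' sample's fitted line, giving `tpm(x)` proportional to
#' `x^(alphaSample/alphaRef)`, scaled so the total normalized signal
#' equals `T` exactly.  Using the fitted line rather than the empirical
#' reverse-cumulative staircase keeps the map smooth at the low-count end
#' (where the staircase is dominated by discreteness), so within-cluster
#' signal shapes are preserved; when the sample already follows the
#' reference law the map is linear.  Tied counts share one value and the
#' map is strictly increasing in the count.  `"simpleTpm"` is plain
#' scaling, `count / librarySize * 1e6`.  Raw counts are never modified.
#'
#' @param sample a non-empty [CTSSSample-class].
#' @param spec a `normalizationSpec` from [makeReference()] (required for
#'   `method = "powerLaw"`).
#' @param method `"powerLaw"` or `"simpleTpm"`.
#' @param fit an optional pre-computed `powerLawFit` for this sample;
#'   fitted on the fly (over `fitRange`) when absent.
#' @param fitRange passed to [fitPowerLaw()] when `fit` is missing.
#'
#' @return the sample with the `tpm` metadata column populated.  Rank order
#'   of counts is preserved by both methods.
#' @export
normalizeSample <- function(sample, spec = NULL,
                            method = c("powerLaw", "simpleTpm"),
                            fit = NULL, fitRange = c(5, 1000)) {
    method <- match.arg(method)
    stopifnot(methods::is(sample, "CTSSSample"))
    gr <- ctss(sample)
    if (!length(gr)) stop("cannot normalize an empty sample")
    if (librarySize(sample) <= 0) stop("zero library size")
    cnt <- gr$count
    if (method == "simpleTpm") {
        tpm <- cnt / librarySize(sample) * 1e6
    } else {
        if (is.null(spec) || !inherits(spec, "normalizationSpec"))
            stop("powerLaw normalization needs a normalizationSpec ",
                 "(see makeReference)")
        if (is.null(fit)) fit <- fitPowerLaw(sample, fitRange)
        tpm <- cnt^(fit$alpha / spec$alphaRef)
        tpm <- tpm * (spec$T / sum(tpm))     # total == T exactly
    }
    gr$tpm <- tpm
    methods::new("CTSSSample", sampleID = sampleID(sample), ctss = gr,
                 librarySize = librarySize(sample))
}
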