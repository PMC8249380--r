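#' Bootstrap comparison of two observed proportions
#'
#' Resamples the reference observation's proportion: `nReps` binomial draws
#' of size `nB` at rate `kA / nA` give the null distribution of the second
#' proportion under "no difference".  The observed `kB / nB` is declared
#' significant when it falls outside the central 95% interval of that
#' distribution (two-sided by default; `sided = "one"` uses the 95th
#' percentile of the appropriate tail).
#'
#' @param kA,nA events and trials of the reference observation.
#' @param kB,nB events and trials of the compared observation (`nB > 0`).
#' @param nReps bootstrap replicates (default 10000).
#' @param seed integer seed (required; the test is deterministic per seed).
#' @param level central interval mass (default 0.95).
#' @param sided `"two"` (default) or `"one"`.
#'
#' @return list with `percentile` (percentile of `kB/nB` in the resampled
#'   distribution), `significant`, `interval` (the null interval used).
#' @export
bootstrapProportionTest <- function(kA, nA, kB, nB, nReps = 10000L, seed,
                                    level = 0.95, sided = c("two", "one")) {
    sided <- match.arg(sided)
    stopifnot(kA >= 0, kA <= nA, kB >= 0, nA > 0)
    if (nB <= 0) stop("nB must be positive")
    pA <- kA / nA
    pB <- kB / nB
    draws <- withSeed(seed, stats::rbinom(nReps, size = nB, prob = pA) / nB)
    if (sided == "two") {
        alpha <- (1 - level) / 2
        int <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE)
        sig <- pB < int[1L] | pB > int[2L]
    } else {
        if (pB >= pA) {
            int <- c(-Inf, stats::quantile(draws, level, names = FALSE))
            sig <- pB > int[2L]
        } else {
            int <- c(stats::quantile(draws, 1 - level, names = FALSE), Inf)
            sig <- pB < int[1L]
        }
    }
    list(percentile = 100 * mean(draws <= pB), significant = sig,
         interval = int)
}

#' Half-coverage technical reproducibility
#'
#' Splits a raw sample in half in silico, runs the
#' normalization -> clustering -> consensus pipeline on the total sample
#' and on one half, aggregates both into a joint consensus set, and
#' reports the fraction of consensus clusters observed (nonzero signal) in
#' both among those observed in the total sample, along with the Pearson
#' correlation of per-cluster Shannon diversity between half and total.
#'
#' @param sample a raw [CTSSSample-class].
#' @param seed integer seed for the split.
#' @param minSupport minimum tag support per CTSS, applied to the total
#'   sample and to the half after splitting (the same quality filter the
#'   extraction step applies; without it every position with a single
#'   surviving tag would count as observed and reproducibility would be
#'   saturated at any depth).
#' @param fitRange,maxDist,minTpm,maxGap pipeline parameters (see
#'   [fitPowerLaw()], [clusterCTSS()], [aggregateConsensus()]).
#'
#' @return list with `depth` (CTSSs passing `minSupport` in the total
#'   sample),
#'   `fractionCommon`, `shannonCorrelation`, `nTotalClusters`,
#'   `nCommonClusters`.  A sample too shallow to form any cluster returns
#'   `fractionCommon = 0` with a warning.
#' @export
halfCoverageReproducibility <- function(sample, seed, minSupport = 3L,
                                        fitRange = c(5, 1000),
                                        maxDist = 20L, minTpm = 1,
                                        maxGap = 100L) {
    halves <- splitHalf(sample, seed)
    support <- function(s) s[ctss(s)$count >= minSupport]
    norm1 <- function(s) {
        fit <- fitPowerLaw(s, fitRange)
        normalizeSample(s, makeReference(list(fit)), method = "powerLaw",
                        fit = fit)
    }
    res <- tryCatch({
        total <- norm1(support(sample))
        half <- norm1(support(halves$half1))
        list(total = total, half = half,
             tcT = clusterCTSS(total, maxDist = maxDist, minTpm = minTpm),
             tcH = clusterCTSS(half, maxDist = maxDist, minTpm = minTpm))
    }, error = function(e) NULL)
    depth <- sum(ctss(sample)$count >= minSupport)
    if (is.null(res) || !length(res$tcT)) {
        warning("sample too shallow to form any tag cluster")
        return(list(depth = depth, fractionCommon = 0,
                    shannonCorrelation = NA_real_, nTotalClusters = 0L,
                    nCommonClusters = 0L))
    }
    total <- res$total; half <- res$half
    cons <- aggregateConsensus(
        list(total = res$tcT, half = res$tcH),
        list(total = total, half = half), maxGap = maxGap)
    tot <- sampleTotals(cons)
    inTotal <- tot[, "total"] > 0
    inBoth <- inTotal & tot[, "half"] > 0
    div <- diversityTable(cons)
    dT <- stats::setNames(div$shannon[div$sample == "total"],
                          div$id[div$sample == "total"])
    dH <- stats::setNames(div$shannon[div$sample == "half"],
                          div$id[div$sample == "half"])
    common <- clusters(cons)$id[inBoth]
    r <- if (length(common) >= 3L &&
             stats::sd(dT[common]) > 0 && stats::sd(dH[common]) > 0)
        stats::cor(dT[common], dH[common]) else NA_real_
    list(depth = depth,
         fractionCommon = sum(inBoth) / sum(inTotal),
         shannonCorrelation = r,
         nTotalClusters = sum(inTotal),
         nCommonClusters = sum(inBoth))
}
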