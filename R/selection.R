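#' Weir-Cockerham FST for two populations
#'
#' The Weir & Cockerham (1984) variance-components estimator theta for a
#' biallelic locus in two populations, computed from allele frequencies
#' and gamete counts (the haploid-equivalent analysis-of-variance form,
#' appropriate when per-genotype heterozygosity is not available):
#' `theta = (MSP - MSG) / (MSP + (nc - 1) * MSG)` with the among- and
#' within-population mean squares over allele indicators.  The estimator's
#' bias correction makes it negative on average under panmixia; a fixed
#' difference gives exactly 1.  Use [wcFstGenotypic()] when individual
#' genotypes (heterozygote counts) are available.
#'
#' @param p1,p2 alternate-allele frequencies in the two populations.
#' @param n1,n2 genotyped gamete counts (>= 2 each).
#'
#' @return theta (may be negative; `NaN` for a monomorphic pooled locus).
#' @examples
#' wcFst(0, 100, 1, 100)   # fixed difference -> 1
#' @export
wcFst <- function(p1, n1, p2, n2) {
    stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
    if (any(n1 < 2) || any(n2 < 2)) stop("need >= 2 gametes per population")
    n <- n1 + n2
    pbar <- (n1 * p1 + n2 * p2) / n
    nc <- n - (n1^2 + n2^2) / n
    msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
    msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n - 2)
    (msp - msg) / (msp + (nc - 1) * msg)
}

#' Multi-locus Weir-Cockerham FST
#'
#' The standard multi-locus combination: variance components are summed
#' over loci before taking the ratio (`sum(a) / sum(a + b)` in the
#' haploid-equivalent two-population form).  Unlike the mean of per-locus
#' ratio estimates, which is biased upward at moderate sample sizes, the
#' ratio of sums is consistent for the parametric FST.
#'
#' @inheritParams wcFst
#' @return a single theta estimate over all loci.
#' @export
wcFstGlobal <- function(p1, n1, p2, n2) {
    comp <- wcFstComponents(p1, n1, p2, n2)
    sum(comp$a) / sum(comp$d)
}

# haploid-equivalent variance components per locus: numerator a (among)
# and denominator d = a + within
wcFstComponents <- function(p1, n1, p2, n2) {
    n <- n1 + n2
    pbar <- (n1 * p1 + n2 * p2) / n
    nc <- n - (n1^2 + n2^2) / n
    msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
    msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n - 2)
    a <- (msp - msg) / nc
    list(a = a, d = a + msg)
}

#' Contingency-table FST and its chi-square identity
#'
#' The variance-standardized allele-frequency differentiation for which
#' `X2 = 2N * FST` is exactly the Pearson chi-square of the 2 x 2
#' (allele x population) table of gamete counts.  This is the estimator
#' under which the chi-square selection test is calibrated; plugging the
#' bias-corrected Weir-Cockerham theta into the same identity gives a
#' statistic roughly twice as large under panmixia (see the package
#' vignette).
#'
#' @inheritParams wcFst
#' @return FST in `[0, 1]` (`NaN` for a monomorphic pooled locus).
#' @export
contingencyFst <- function(p1, n1, p2, n2) {
    n <- n1 + n2
    pbar <- (n1 * p1 + n2 * p2) / n
    (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (n * pbar * (1 - pbar))
}

#' Weir-Cockerham FST from diploid genotype counts
#'
#' The full Weir & Cockerham (1984) theta for two populations using
#' observed heterozygosity: `a / (a + b + c)` with the standard variance
#' components.  Differs from [wcFst()] (haploid-equivalent reduction) when
#' genotype frequencies deviate from Hardy-Weinberg proportions.
#'
#' @param p1,p2 alternate-allele frequencies.
#' @param nInd1,nInd2 genotyped individuals per population.
#' @param h1,h2 observed heterozygote *frequencies* per population.
#' @return theta.
#' @export
wcFstGenotypic <- function(p1, nInd1, h1, p2, nInd2, h2) {
    r <- 2
    nbar <- (nInd1 + nInd2) / r
    nc <- (r * nbar - (nInd1^2 + nInd2^2) / (r * nbar)) / (r - 1)
    pbar <- (nInd1 * p1 + nInd2 * p2) / (r * nbar)
    s2 <- (nInd1 * (p1 - pbar)^2 + nInd2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (nInd1 * h1 + nInd2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
        (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a / (a + b + cc)
}

#' Chi-square selection test from FST
#'
#' `X2 = 2N * FST` with `2N` the sum of genotyped gametes in the two
#' populations, referred to a 1-df chi-square upper tail.  Negative FST
#' estimates are clamped to 0 first (the statistic must be non-negative).
#'
#' @param fst Weir-Cockerham estimate(s).
#' @param nGametesTotal sum of genotyped gametes across both populations.
#' @return data.frame with `chi2` and `p`.
#' @export
fstChi2Test <- function(fst, nGametesTotal) {
    stopifnot(all(nGametesTotal >= 2))
    chi2 <- nGametesTotal * pmax(fst, 0)
    data.frame(chi2 = chi2, p = stats::pchisq(chi2, df = 1,
                                              lower.tail = FALSE))
}

#' l*P/d false discovery rate
#'
#' Overall FDR for a set of per-locus tests: number of loci tested times
#' the individual significance level, divided by the number of significant
#' loci.
#'
#' @param l number of loci tested.
#' @param P significance level of the individual tests (0 < P < 1).
#' @param d number of significant loci.
#' @return the FDR estimate; `NA` with a warning when `d` is 0.
#' @export
fdrLpd <- function(l, P, d) {
    stopifnot(l >= d, P > 0, P < 1, d >= 0)
    if (d == 0) {
        warning("no significant loci; FDR undefined")
        return(NA_real_)
    }
    l * P / d
}

#' Hypergeometric probability mass
#'
#' `p(x; N, n, m) = C(m, x) C(N - m, n - x) / C(N, n)`: the probability of
#' observing `x` marked items in a draw of `n` from a population of `N`
#' containing `m` marked items.  Computed in log space so genome-scale `N`
#' is exact.  Out-of-support arguments return 0.
#'
#' @param x,N,n,m integers (vectorized over `x`).
#' @return probability in `[0, 1]`.
#' @export
hypergeometricPmf <- function(x, N, n, m) {
    stopifnot(N >= 0, n >= 0, n <= N, m >= 0, m <= N)
    out <- numeric(length(x))
    ok <- x >= max(0, n + m - N) & x <= min(n, m) & x == round(x)
    out[ok] <- exp(lchoose(m, x[ok]) + lchoose(N - m, n - x[ok]) -
                   lchoose(N, n))
    out
}

# upper-tail P(X >= x) by summing the pmf over the support
hypergeometricUpper <- function(x, N, n, m) {
    hi <- min(n, m)
    if (x > hi) return(0)
    min(1, sum(hypergeometricPmf(seq(x, hi), N, n, m)))
}

# lower-tail P(X <= x)
hypergeometricLower <- function(x, N, n, m) {
    lo <- max(0, n + m - N)
    if (x < lo) return(0)
    min(1, sum(hypergeometricPmf(seq(lo, x), N, n, m)))
}

#' MAF-bin enrichment of significant SNPs
#'
#' Minor allele frequencies are split into `nBins` half-open bins
#' `(lo, hi]` each spanning `0.5 / nBins` (default 50 bins of 1% of the
#' MAF range over `(0, 0.5]`; a MAF of 0.005 falls in bin 1, a MAF of 0.5
#' in bin 50).  Per bin, the number `x` of significant SNPs is compared to
#' the genome-wide composition by a hypergeometric test: a draw of `n`
#' (total significant SNPs) from `N` genome-wide SNPs of which `m` lie in
#' the bin.  Enrichment uses the upper-tail sum of the pmf, depletion the
#' lower tail; p-values are BH-adjusted across bins and flagged at
#' `fdr < fdrThreshold` (default 0.001).
#'
#' @param significantMaf MAFs of the significant SNPs (in `(0, 0.5]`).
#' @param genomeBinCounts integer vector of length `nBins`: genome-wide
#'   SNP counts per MAF bin (`m`); their sum is `N`.
#' @param nBins number of MAF bins.
#' @param tail `"upper"` (enrichment, default) or `"lower"` (depletion).
#' @param fdrThreshold flagging threshold on the adjusted p-value.
#'
#' @return data.frame with one row per bin: `bin`, `mafLow`, `mafHigh`,
#'   `x`, `m`, `p`, `fdr`, `flagged`.
#' @export
mafBinEnrichment <- function(significantMaf, genomeBinCounts, nBins = 50L,
                             tail = c("upper", "lower"),
                             fdrThreshold = 0.001) {
    tail <- match.arg(tail)
    stopifnot(length(genomeBinCounts) == nBins)
    if (any(significantMaf <= 0 | significantMaf > 0.5))
        stop("MAF values must lie in (0, 0.5]")
    width <- 0.5 / nBins
    binOf <- pmin(nBins, ceiling(significantMaf / width - 1e-12))
    x <- tabulate(binOf, nbins = nBins)
    n <- length(significantMaf)
    N <- sum(genomeBinCounts)
    p <- vapply(seq_len(nBins), function(b) {
        if (tail == "upper") hypergeometricUpper(x[b], N, n,
                                                 genomeBinCounts[b])
        else hypergeometricLower(x[b], N, n, genomeBinCounts[b])
    }, 0)
    fdr <- bhFdr(p)
    data.frame(bin = seq_len(nBins),
               mafLow = (seq_len(nBins) - 1L) * width,
               mafHigh = seq_len(nBins) * width,
               x = x, m = genomeBinCounts, p = p, fdr = fdr,
               flagged = fdr < fdrThreshold)
}

#' Load biallelic SNPs within regions from a VCF
#'
#' Reads a VCF, restricts to SNPs inside the supplied regions, computes
#' per-population allele frequencies from called genotypes only (missing
#' genotypes are excluded from the gamete counts), and removes SNPs whose
#' pooled minor allele frequency is not strictly greater than `minMaf`.
#' Multiallelic sites are skipped with a warning.
#'
#' @param vcf path to a VCF file.
#' @param regions path to a BED file (or a `GRanges`) of regions to keep.
#' @param popAssignments data.frame with columns `sample`, `population`
#'   (exactly two populations); every listed sample must be in the VCF.
#' @param minMaf pooled MAF cutoff (strict; default 0.005).
#'
#' @return data.frame with one row per retained SNP: `chrom`, `pos`,
#'   `ref`, `alt`, and per population `p1`, `n1`, `maf1`, `p2`, `n2`,
#'   `maf2`, plus `nGametesTotal` and the pooled `maf`.
#' @export
loadSnpsInRegions <- function(vcf, regions, popAssignments, minMaf = 0.005) {
    stopifnot(all(c("sample", "population") %in% names(popAssignments)))
    pops <- sort(unique(popAssignments$population))
    if (length(pops) != 2L) stop("exactly two populations are required")
    v <- VariantAnnotation::readVcf(vcf, genome = "synthetic")
    missing <- setdiff(popAssignments$sample,
                       colnames(VariantAnnotation::geno(v)$GT))
    if (length(missing))
        stop("samples absent from the VCF: ", paste(missing, collapse = ", "))
    rr <- SummarizedExperiment::rowRanges(v)
    nAlt <- lengths(VariantAnnotation::alt(v))
    refLen <- nchar(as.character(VariantAnnotation::ref(v)))
    multi <- nAlt != 1L
    if (any(multi))
        warning(sum(multi), " multiallelic site(s) skipped")
    altChar <- rep(NA_character_, length(v))
    altChar[!multi] <- as.character(unlist(VariantAnnotation::alt(v)[!multi]))
    snp <- !multi & refLen == 1L & !is.na(altChar) & nchar(altChar) == 1L
    regGR <- if (methods::is(regions, "GRanges")) regions
             else rtracklayer::import(regions)
    GenomicRanges::strand(regGR) <- "*"
    inReg <- IRanges::overlapsAny(rr, regGR, ignore.strand = TRUE)
    keep <- which(snp & inReg)
    if (!length(keep))
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          p1 = numeric(), n1 = numeric(), maf1 = numeric(),
                          p2 = numeric(), n2 = numeric(), maf2 = numeric(),
                          nGametesTotal = numeric(), maf = numeric()))
    gt <- VariantAnnotation::geno(v)$GT[keep, , drop = FALSE]
    tally <- function(g) {
        # count alt alleles and called gametes from GT strings
        g[g %in% c(".", "./.", ".|.")] <- NA
        alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
        altc <- vapply(alleles, function(a)
            sum(a == "1", na.rm = TRUE), 0)
        called <- vapply(alleles, function(a)
            sum(a %in% c("0", "1")), 0)
        c(alt = sum(altc), called = sum(called))
    }
    res <- lapply(pops, function(pp) {
        cols <- popAssignments$sample[popAssignments$population == pp]
        t(apply(gt[, cols, drop = FALSE], 1L, tally))
    })
    n1 <- res[[1L]][, "called"]; n2 <- res[[2L]][, "called"]
    p1 <- ifelse(n1 > 0, res[[1L]][, "alt"] / n1, NA_real_)
    p2 <- ifelse(n2 > 0, res[[2L]][, "alt"] / n2, NA_real_)
    pooled <- (res[[1L]][, "alt"] + res[[2L]][, "alt"]) / (n1 + n2)
    maf <- pmin(pooled, 1 - pooled)
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr))[keep],
                      pos = GenomicRanges::start(rr)[keep],
                      ref = as.character(VariantAnnotation::ref(v))[keep],
                      alt = altChar[keep],
                      p1 = p1, n1 = n1, maf1 = pmin(p1, 1 - p1),
                      p2 = p2, n2 = n2, maf2 = pmin(p2, 1 - p2),
                      nGametesTotal = n1 + n2, maf = maf)
    rownames(out) <- NULL
    out[out$maf > minMaf & out$n1 >= 2 & out$n2 >= 2, , drop = FALSE]
}

#' Per-SNP selection scan
#'
#' Adds Weir-Cockerham FST, the `X2 = 2N * FST` chi-square test and the
#' l*P/d FDR to a SNP table from [loadSnpsInRegions()].
#'
#' @param snps data.frame with columns `p1`, `n1`, `p2`, `n2`,
#'   `nGametesTotal`.
#' @param pThreshold per-SNP significance level (default 0.05).
#' @return the input with `fst`, `chi2`, `p`, `significant` columns plus
#'   attributes `nTested`, `nSignificant`, `fdr` (l*P/d).
#' @export
selectionScan <- function(snps, pThreshold = 0.05) {
    fst <- wcFst(snps$p1, snps$n1, snps$p2, snps$n2)
    ct <- fstChi2Test(fst, snps$nGametesTotal)
    snps$fst <- fst
    snps$chi2 <- ct$chi2
    snps$p <- ct$p
    snps$significant <- ct$p < pThreshold
    d <- sum(snps$significant)
    attr(snps, "nTested") <- nrow(snps)
    attr(snps, "nSignificant") <- d
    attr(snps, "fdr") <- if (d > 0) fdrLpd(nrow(snps), pThreshold, d)
                         else NA_real_
    snps
}
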