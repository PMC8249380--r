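test_that("Weir-Cockerham theta matches the ANOVA oracle and edge cases", {
    expect_equal(wcFst(0, 100, 1, 100), 1)
    expect_lte(wcFst(0.4, 100, 0.4, 100), 0)  # negative bias correction
    expect_equal(wcFst(0.2, 100, 0.8, 100), wcFst(0.8, 100, 0.2, 100))
    expect_error(wcFst(0.5, 1, 0.5, 100), "gametes")
    set.seed(9)
    for (i in 1:100) {
        n1 <- sample(4:300, 1); n2 <- sample(4:300, 1)
        x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
        if (x1 + x2 == 0 || x1 + x2 == n1 + n2) next
        expect_equal(wcFst(x1 / n1, n1, x2 / n2, n2),
                     bruteWcFst(x1, n1, x2, n2), tolerance = 1e-10)
    }
})

test_that("the genotypic estimator uses observed heterozygosity", {
    # under exact Hardy-Weinberg heterozygosity the two forms nearly agree
    p1 <- 0.2; p2 <- 0.7; nI <- 500
    gt <- wcFstGenotypic(p1, nI, 2 * p1 * (1 - p1), p2, nI,
                         2 * p2 * (1 - p2))
    hap <- wcFst(p1, 2 * nI, p2, 2 * nI)
    expect_equal(gt, hap, tolerance = 0.01)
    # observed heterozygosity enters the estimate: departing from HWE
    # proportions changes theta
    gtInbred <- wcFstGenotypic(p1, nI, 0.5 * 2 * p1 * (1 - p1), p2, nI,
                               0.5 * 2 * p2 * (1 - p2))
    expect_false(isTRUE(all.equal(gtInbred, gt, tolerance = 1e-6)))
})

test_that("the chi-square selection test is 2N * FST with clamping", {
    r0 <- fstChi2Test(0, 100)
    expect_equal(r0$chi2, 0)
    expect_equal(r0$p, 1)
    r <- fstChi2Test(0.01, 2506)
    expect_equal(r$chi2, 25.06)
    # independent 1-df identity: p = 2 * pnorm(-sqrt(chi2))
    expect_equal(r$p, 2 * pnorm(-sqrt(25.06)), tolerance = 1e-12)
    expect_equal(fstChi2Test(-0.2, 500)$chi2, 0)
})

test_that("l*P/d reproduces the printed selection FDR", {
    expect_equal(round(fdrLpd(667, 0.05, 475), 4), 0.0702)
    expect_equal(fdrLpd(300, 0.05, 300), 0.05)
    # monotone: more detections, lower FDR
    expect_true(all(diff(vapply(1:20, function(d) fdrLpd(50, 0.01, d),
                                0)) < 0))
    expect_warning(expect_true(is.na(fdrLpd(10, 0.05, 0))), "undefined")
})

test_that("the hypergeometric pmf equals enumeration and dhyper", {
    # (x=1, N=5, n=2, m=2): 6 of the C(5,2)=10 draws hit exactly one
    expect_equal(hypergeometricPmf(1, 5, 2, 2), 0.6)
    expect_equal(hypergeometricPmf(3, 7, 3, 7), 1)   # all draws must hit
    expect_equal(sum(hypergeometricPmf(0:10, 50, 10, 20)), 1,
                 tolerance = 1e-12)
    expect_equal(hypergeometricPmf(5, 10, 2, 2), 0)  # out of support
    # exhaustive check against dhyper over a grid (full N <= 12 sweep in
    # the acceptance suite)
    for (N in c(6, 9, 12)) for (m in 0:N) for (n in 0:N)
        expect_equal(hypergeometricPmf(0:n, N, n, m),
                     dhyper(0:n, m, N - m, n), tolerance = 1e-13)
    # log-space evaluation stays finite at genome scale
    expect_gt(hypergeometricPmf(10, 34645762, 472, 700000), 0)
})

test_that("MAF bins are half-open 1% intervals with tail tests", {
    # bin boundary convention
    tab <- mafBinEnrichment(c(0.005, 0.01, 0.0100001, 0.5),
                            genomeBinCounts = rep(100, 50))
    expect_equal(tab$x[1], 2L)   # 0.005 and 0.01 in bin 1 (0, 0.01]
    expect_equal(tab$x[2], 1L)
    expect_equal(tab$x[50], 1L)  # 0.5 in bin 50
    expect_error(mafBinEnrichment(0.6, rep(100, 50)), "\\(0, 0.5\\]")

    # x at its expectation in every bin: nothing flagged
    m <- rep(200, 50)
    sig <- rep((1:50) / 100 - 0.005, each = 4)  # 4 per bin = n*m/N
    tabNull <- mafBinEnrichment(sig, m)
    expect_false(any(tabNull$flagged))

    # all significant SNPs in one 2% bin: astronomically enriched
    m2 <- c(2000, rep(96000 / 49, 49))
    tabHot <- mafBinEnrichment(rep(0.004, 400), round(m2))
    expect_lt(tabHot$p[1], 1e-10)
    expect_true(tabHot$flagged[1])
    expect_false(any(tabHot$flagged[-1]))
    # upper tail equals phyper
    expect_equal(tabHot$p[1],
                 phyper(399, round(m2)[1], sum(round(m2)[-1]), 400,
                        lower.tail = FALSE),
                 tolerance = 1e-10)
})

test_that("SNPs load from VCF with hand-counted gamete frequencies", {
    dir <- tempfile(); dir.create(dir)
    vcf <- file.path(dir, "toy.vcf")
    ids <- c(paste0("A", 1:5), paste0("B", 1:5))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=chr1>",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", ids), collapse = "\t"),
        # inside region; pop1 alt gametes: 0/1,1/1,0/0,0/1,./. -> 4 of 8
        #                pop2 alt gametes: 0/0,0/0,0/1,1/1,0/1 -> 4 of 10
        paste(c("chr1", "150", "s1", "A", "G", ".", "PASS", ".", "GT",
                "0/1", "1/1", "0/0", "0/1", "./.",
                "0/0", "0/0", "0/1", "1/1", "0/1"), collapse = "\t"),
        # outside all regions
        paste(c("chr1", "5000", "s2", "C", "T", ".", "PASS", ".", "GT",
                rep("0/1", 10)), collapse = "\t"),
        # pooled MAF exactly 1/20 = 0.05 > 0.005 kept; this one is
        # pooled 0/20 after filtering? no: singleton kept, MAF 0.05
        paste(c("chr1", "160", "s3", "G", "C", ".", "PASS", ".", "GT",
                "0/1", rep("0/0", 9)), collapse = "\t"),
        # monomorphic: pooled MAF 0 -> removed (not > 0.005)
        paste(c("chr1", "170", "s4", "T", "A", ".", "PASS", ".", "GT",
                rep("0/0", 10)), collapse = "\t"),
        # multiallelic -> skipped with warning
        paste(c("chr1", "180", "s5", "A", "G,T", ".", "PASS", ".", "GT",
                rep("0/1", 10)), collapse = "\t")), vcf)
    bed <- file.path(dir, "regions.bed")
    writeLines("chr1\t100\t1000\tr1", bed)
    pops <- data.frame(sample = ids,
                       population = rep(c("pop1", "pop2"), each = 5))
    expect_warning(snps <- loadSnpsInRegions(vcf, bed, pops),
                   "multiallelic")
    expect_equal(snps$pos, c(150, 160))
    s1 <- snps[snps$pos == 150, ]
    expect_equal(s1$p1, 4 / 8)     # missing genotype excluded
    expect_equal(s1$n1, 8)
    expect_equal(s1$p2, 4 / 10)
    expect_equal(s1$nGametesTotal, 18)
    badPops <- rbind(pops, data.frame(sample = "ghost",
                                      population = "pop1"))
    expect_error(suppressWarnings(loadSnpsInRegions(vcf, bed, badPops)),
                 "ghost")

    scan <- selectionScan(snps)
    expect_equal(scan$fst[1], wcFst(4 / 8, 8, 4 / 10, 10))
    expect_equal(scan$chi2, scan$nGametesTotal * pmax(scan$fst, 0))
})
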