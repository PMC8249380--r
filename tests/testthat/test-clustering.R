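normed <- function(pos, tpm, strand = "+", chrom = "chr1", id = "n") {
    makeSample(id, chrom = chrom, pos = pos, strand = strand,
               count = rep(1, length(pos)), tpm = tpm)
}

test_that("distance-based chaining follows the 20 bp rule", {
    s <- normed(c(100, 115, 140), c(2, 3, 4))
    tc <- clusterCTSS(s, maxDist = 20)
    cl <- clusters(tc)
    expect_equal(length(cl), 2L)
    expect_equal(GenomicRanges::start(cl), c(100, 140))
    expect_equal(GenomicRanges::end(cl), c(115, 140))

    one <- clusterCTSS(normed(500, 5))
    expect_equal(length(one), 1L)
    expect_equal(clusters(one)$iqWidth, 0)

    # sub-threshold CTSSs are removed before chaining
    s2 <- normed(c(100, 110, 120), c(5, 0.5, 5))
    expect_equal(length(clusterCTSS(s2, maxDist = 5, minTpm = 1)), 2L)

    raw <- makeSample("raw", pos = 1:3, count = 1:3)
    expect_error(clusterCTSS(raw), "normalize")
})

test_that("clustering equals a transitive-closure oracle and is stable", {
    set.seed(21)
    for (i in 1:40) {
        pos <- sort(sample.int(2000, 150))
        tpm <- runif(150, 1, 50)
        s <- normed(pos, tpm)
        tc <- clusterCTSS(s, maxDist = 20)
        oracle <- bruteCluster(pos, 20)
        got <- ctss(tc)$clusterID[match(pos, GenomicRanges::start(ctss(tc)))]
        expect_equal(got, oracle)
        # input order invariance
        perm <- sample(length(pos))
        tc2 <- clusterCTSS(normed(pos[perm], tpm[perm]), maxDist = 20)
        expect_equal(as.data.frame(clusters(tc2)),
                     as.data.frame(clusters(tc)))
        # partition: every retained CTSS in exactly one cluster
        expect_equal(sum(clusters(tc)$nCTSS), length(pos))
    }
})

test_that("quantile positions follow the cumulative >= rule per strand", {
    expect_equal(quantilePosition(c(10, 20, 30, 40), rep(1, 4), 0.25, "+"),
                 10)
    expect_equal(quantilePosition(c(10, 20, 30, 40), rep(1, 4), 0.5, "+"),
                 20)
    expect_equal(quantilePosition(55, 3, 0.9, "+"), 55)
    expect_equal(quantilePosition(55, 3, 0.1, "-"), 55)
    # on the minus strand 5'->3' runs high to low
    expect_equal(quantilePosition(c(10, 20, 30, 40), rep(1, 4), 0.25, "-"),
                 40)
    expect_error(quantilePosition(integer(), numeric(), 0.5), "empty")
    # brute-force cumulative scan oracle
    set.seed(4)
    for (i in 1:50) {
        n <- sample(2:30, 1)
        pos <- sort(sample.int(500, n))
        tpm <- runif(n, 0.1, 10)
        q <- runif(1, 0.05, 0.95)
        cum <- cumsum(tpm) / sum(tpm)
        expect_equal(quantilePosition(pos, tpm, q, "+"),
                     pos[which(cum >= q - 1e-12)[1]])
    }
})

test_that("dominant TSS ties break toward the 5' end of the strand", {
    expect_equal(dominantTSS(c(100, 110), c(5, 9), "+")$pos, 110)
    expect_equal(dominantTSS(c(100, 110), c(5, 5), "+")$pos, 100)
    expect_equal(dominantTSS(c(100, 110), c(5, 5), "-")$pos, 110)
    set.seed(5)
    for (i in 1:30) {
        n <- sample(2:20, 1)
        pos <- sample.int(1000, n)
        tpm <- runif(n)
        expect_equal(dominantTSS(pos, tpm, "+")$tpm, max(tpm))
    }
})

test_that("shape classification uses a strict 4 bp bound", {
    expect_equal(classifyShape(0), "sharp")
    expect_equal(classifyShape(4), "broad")    # boundary is strict <
    expect_equal(classifyShape(3.9), "sharp")
    # uniform 20-position cluster spanning ~100 bp is broad
    pos <- seq(1, 100, length.out = 20)
    iq <- abs(quantilePosition(pos, rep(1, 20), 0.75, "+") -
              quantilePosition(pos, rep(1, 20), 0.25, "+"))
    expect_equal(classifyShape(iq), "broad")
})

test_that("consensus aggregation merges boundary intervals under 100 bp", {
    mk <- function(id, pos, tpm, strand = "+") {
        s <- normed(pos, tpm, strand, id = id)
        clusterCTSS(s, maxDist = 20)
    }
    # boundary intervals [100,120] and [180,200]: gap 60 < 100 -> one
    a <- mk("a", c(100, 120), c(5, 5))
    b <- mk("b", c(180, 200), c(5, 5))
    cons <- aggregateConsensus(
        list(a = a, b = b),
        list(a = normed(c(100, 120), c(5, 5), id = "a"),
             b = normed(c(180, 200), c(5, 5), id = "b")))
    expect_equal(length(cons), 1L)
    expect_equal(GenomicRanges::start(clusters(cons)), 100)
    expect_equal(GenomicRanges::end(clusters(cons)), 200)
    # per-sample totals equal the profile sums
    expect_equal(unname(sampleTotals(cons)[1, ]), c(10, 10))

    # gap 150 stays apart
    b2 <- mk("b", c(270, 290), c(5, 5))
    cons2 <- aggregateConsensus(
        list(a = a, b = b2),
        list(a = normed(c(100, 120), c(5, 5), id = "a"),
             b = normed(c(270, 290), c(5, 5), id = "b")))
    expect_equal(length(cons2), 2L)

    expect_equal(length(aggregateConsensus(list(), list())), 0L)
})

test_that("aggregation equals the brute-force closure and never overlaps", {
    set.seed(31)
    for (i in 1:30) {
        nA <- sample(3:8, 1); nB <- sample(3:8, 1)
        posA <- sort(sample.int(5000, nA * 3))
        posB <- sort(sample.int(5000, nB * 3))
        sa <- normed(posA, runif(length(posA), 1, 20), id = "a")
        sb <- normed(posB, runif(length(posB), 1, 20), id = "b")
        ta <- clusterCTSS(sa, maxDist = 20)
        tb <- clusterCTSS(sb, maxDist = 20)
        cons <- aggregateConsensus(list(a = ta, b = tb),
                                   list(a = sa, b = sb))
        expect_true(validObject(cons))   # validity asserts non-overlap
        # every tag cluster maps into exactly one consensus cluster
        allCl <- c(clusters(ta), clusters(tb))
        hits <- GenomicRanges::findOverlaps(allCl, clusters(cons))
        expect_equal(S4Vectors::queryHits(hits), seq_along(allCl))
        # partition matches the O(n^2) transitive-closure oracle exactly
        oracle <- bruteConsensusPartition(
            as.character(GenomicRanges::seqnames(allCl)),
            as.character(GenomicRanges::strand(allCl)),
            GenomicRanges::start(allCl), GenomicRanges::end(allCl),
            allCl$qLow, allCl$qHigh, 100)
        got <- S4Vectors::subjectHits(hits)
        expect_true(samePartition(got, oracle))
    }
})

test_that("aggregation is mirror-symmetric under strand flipping", {
    set.seed(8)
    pos <- sort(sample.int(3000, 40))
    tpm <- runif(40, 1, 30)
    M <- 10000L
    sa <- normed(pos, tpm, "+", id = "a")
    saM <- normed(M - pos, tpm, "-", id = "a")
    ta <- clusterCTSS(sa); taM <- clusterCTSS(saM)
    expect_equal(length(ta), length(taM))
    clF <- clusters(ta); clM <- clusters(taM)
    o <- order(-GenomicRanges::end(clM))
    expect_equal(GenomicRanges::width(clM)[o], GenomicRanges::width(clF))
    expect_equal(clM$totalTpm[o], clF$totalTpm)
    expect_equal(clM$iqWidth[o], clF$iqWidth)
    expect_equal(M - clM$dominantPos[o], clF$dominantPos)
})

test_that("annotation precedence and distances match the gene model", {
    gm <- GenomicRanges::GRanges(
        rep("chr1", 4),
        IRanges::IRanges(start = c(1000, 1000, 1000, 8000),
                         end = c(3000, 1200, 2800, 9000)),
        strand = c("+", "+", "+", "-"),
        type = c("transcript", "exon", "exon", "transcript"),
        gene_id = c("g1", "g1", "g1", "g2"),
        transcript_id = c("t1", "t1", "t1", "t2"))
    mkCons <- function(pos, strand = "+") {
        s <- normed(pos, rep(5, length(pos)), strand, id = "s")
        tc <- clusterCTSS(s)
        aggregateConsensus(list(s = tc), list(s = s))
    }
    # 30 bp downstream of the start, window 500 -> promoter
    cons <- annotateClusters(mkCons(1030), gm)
    expect_equal(clusters(cons)$annotation, "promoter")
    expect_equal(clusters(cons)$geneID, "g1")
    expect_equal(distanceToAnnotatedStart(cons, gm, clusters(cons)$id), 30)
    # inside an exon beyond the promoter window
    expect_equal(clusters(annotateClusters(mkCons(2700), gm))$annotation,
                 "exon")
    # inside the transcript but not an exon
    expect_equal(clusters(annotateClusters(mkCons(2900), gm))$annotation,
                 "intron")
    # annotation-free region
    cons4 <- annotateClusters(mkCons(5000), gm)
    expect_equal(clusters(cons4)$annotation, "intergenic")
    expect_error(distanceToAnnotatedStart(cons4, gm, clusters(cons4)$id),
                 "not promoter")
    # minus-strand gene: start is the transcript end; downstream is 5'->3'
    cons5 <- annotateClusters(mkCons(8965, "-"), gm)
    expect_equal(clusters(cons5)$annotation, "promoter")
    expect_equal(distanceToAnnotatedStart(cons5, gm, clusters(cons5)$id), 35)
    # wrong strand is not a promoter hit
    cons6 <- annotateClusters(mkCons(1030, "-"), gm)
    expect_equal(clusters(cons6)$annotation, "intergenic")
})

test_that("annotation categories match an interval-membership oracle", {
    set.seed(13)
    nGenes <- 15
    starts <- sort(sample(seq(1000, 90000, by = 3000), nGenes))
    gm <- do.call(c, lapply(seq_len(nGenes), function(i) {
        GenomicRanges::GRanges("chr1",
            IRanges::IRanges(start = c(starts[i], starts[i],
                                       starts[i] + 900),
                             end = c(starts[i] + 2000, starts[i] + 300,
                                     starts[i] + 1400)),
            strand = "+",
            type = c("transcript", "exon", "exon"),
            gene_id = paste0("g", i), transcript_id = paste0("t", i))
    }))
    pos <- sample.int(95000, 60)
    s <- normed(sort(pos), rep(5, 60), id = "s")
    tc <- clusterCTSS(s)
    cons <- annotateClusters(aggregateConsensus(list(s = tc),
                                                list(s = s)), gm,
                             promoterWindow = 500)
    cl <- clusters(cons)
    for (k in seq_along(cl)) {
        lo <- GenomicRanges::start(cl)[k]; hi <- GenomicRanges::end(cl)[k]
        overlaps <- function(a, b) lo <= b & hi >= a
        isProm <- any(overlaps(starts - 500, starts + 500))
        exA <- overlaps(starts, starts + 300)
        exB <- overlaps(starts + 900, starts + 1400)
        isExon <- any(exA | exB)
        isTx <- any(overlaps(starts, starts + 2000))
        want <- if (isProm) "promoter" else if (isExon) "exon"
                else if (isTx) "intron" else "intergenic"
        expect_equal(cl$annotation[k], want)
    }
})
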