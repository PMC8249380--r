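prof <- function(pos, tpm) data.frame(pos = pos, tpm = tpm)

test_that("Shannon index has its closed-form values", {
    expect_equal(shannonIndex(c(7, 0, 0)), 0)
    expect_equal(shannonIndex(rep(3, 4)), log(4))
    expect_equal(shannonIndex(rep(1, 4)), 1.3863, tolerance = 1e-4)
    expect_error(shannonIndex(c(0, 0)), "zero total")
    expect_error(shannonIndex(c(-1, 2)), "non-negative")
    set.seed(2)
    for (i in 1:25) {
        v <- runif(sample(2:40, 1))
        p <- v / sum(v)
        expect_equal(shannonIndex(v), -sum(p * log(p)), tolerance = 1e-12)
    }
})

test_that("shifting score follows max(F1-F2)/max(F1) in both directions", {
    # identical profiles -> 0
    expect_equal(shiftingScore(prof(1:3, c(1, 2, 3)),
                               prof(1:3, c(1, 2, 3)))$score, 0)
    # equal-total disjoint profiles, a entirely 5' of b -> 1
    s <- shiftingScore(prof(1:2, c(5, 5)), prof(11:12, c(5, 5)))
    expect_equal(s$score, 1)
    # the hand cumulative-sum example: 0.4 in the reverse direction
    s2 <- shiftingScore(prof(c(1, 2), c(30, 70)), prof(c(1, 2), c(70, 30)))
    expect_equal(s2$score, 0.4)
    expect_equal(s2$direction, "reverse")
    expect_error(shiftingScore(prof(1, 0), prof(1, 0)), "zero total")
    # one-sided signal is divergence, not shifting
    expect_true(is.na(shiftingScore(prof(1, 5), prof(1, 0))$score))
})

test_that("shifting score matches the brute cumulative oracle and mirrors", {
    set.seed(6)
    for (i in 1:200) {
        k <- sample(2:25, 1)
        pos <- sort(sample.int(200, k))
        va <- round(runif(k, 0, 20), 2)
        vb <- round(runif(k, 0, 20), 2)
        if (sum(va) == 0 || sum(vb) == 0) next
        got <- shiftingScore(prof(pos, va), prof(pos, vb), "+")
        expect_equal(got$score, bruteShiftScore(va, vb), tolerance = 1e-12)
        # mirroring coordinates and flipping strand preserves the score
        mir <- shiftingScore(prof(1000 - pos, va), prof(1000 - pos, vb),
                             "-")
        expect_equal(mir$score, got$score, tolerance = 1e-12)
    }
})

test_that("the profile KS test matches ks.test on expanded tag data", {
    # identical normalized shapes -> D = 0, p = 1
    r <- ksProfileTest(prof(1:3, c(10, 20, 10)), prof(1:3, c(5, 10, 5)))
    expect_equal(r$D, 0)
    expect_equal(r$p, 1)
    # fully disjoint supports -> D = 1
    expect_equal(ksProfileTest(prof(1:2, c(3, 3)),
                               prof(5:6, c(4, 4)))$D, 1)
    expect_error(ksProfileTest(prof(1, 0), prof(1, 1)), "positive total")
    # integer-count profiles: expanding to per-tag observations reproduces
    # the classical asymptotic two-sample KS test
    set.seed(12)
    for (i in 1:20) {
        k <- sample(5:30, 1)
        pos <- sort(sample.int(100, k))
        ca <- rpois(k, 4); cb <- rpois(k, 4)
        if (sum(ca) < 2 || sum(cb) < 2) next
        got <- ksProfileTest(prof(pos, ca), prof(pos, cb))
        ref <- suppressWarnings(stats::ks.test(rep(pos, ca), rep(pos, cb),
                                               exact = FALSE))
        expect_equal(got$D, unname(ref$statistic), tolerance = 1e-12)
        expect_equal(got$p, ref$p.value, tolerance = 1e-3)
    }
})

test_that("BH adjustment is the standard step-up procedure", {
    expect_equal(bhFdr(0.03), 0.03)
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
    expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

twoSampleCons <- function(posA, tpmA, posB, tpmB, strand = "+",
                          countA = NULL, countB = NULL) {
    a <- makeSample("A", pos = posA, strand = strand,
                    count = if (is.null(countA)) round(tpmA) else countA,
                    tpm = tpmA)
    b <- makeSample("B", pos = posB, strand = strand,
                    count = if (is.null(countB)) round(tpmB) else countB,
                    tpm = tpmB)
    aggregateConsensus(list(A = clusterCTSS(a), B = clusterCTSS(b)),
                       list(A = a, B = b))
}

test_that("divergence calls need zero raw signal in the other group", {
    # cluster expressed in A at 50 TPM, zero raw tags in B
    consDiv <- twoSampleCons(c(100, 110), c(30, 20), 5000, 15)
    dv <- divergenceProfile(consDiv, "A", "B", thresholds = 10)
    expect_equal(dv$nExpressed, 2L)
    expect_equal(dv$nDivergent, 2L)   # both one-sided here
    # B has raw signal (2 TPM) in the span -> not divergent
    cons2 <- twoSampleCons(c(100, 110), c(30, 20), 100, 2)
    dv2 <- divergenceProfile(cons2, "A", "B", thresholds = 10)
    expect_equal(dv2$nDivergent, 0L)
    expect_equal(dv2$proportion, 0)
    expect_error(divergenceProfile(cons2, "A", "nope"), "unknown")
})

test_that("dominant distances are strand-oriented and filtered", {
    # same dominant position -> 0
    cons <- twoSampleCons(c(100, 110), c(30, 20), c(100, 110), c(40, 10))
    dd <- dominantDistance(cons, "A", "B", minTpm = 10)
    expect_equal(dd$distance, 0)
    # b dominant 12 bp 3' of a on the minus strand -> +12
    consM <- twoSampleCons(c(100, 112), c(10, 30), c(100, 112), c(30, 10),
                           strand = "-")
    ddM <- dominantDistance(consM, "A", "B", minTpm = 10)
    expect_equal(ddM$distance, 12)
    # clusters failing the 10 TPM (both groups) filter are skipped
    consLow <- twoSampleCons(c(100, 110), c(30, 20), c(100, 110), c(3, 2))
    expect_equal(nrow(dominantDistance(consLow, "A", "B", minTpm = 10)), 0L)
    expect_equal(nrow(dominantDistance(consLow, "A", "B", minTpm = 10,
                                       require = "either")), 1L)
})

test_that("shift tables combine score, KS and BH across clusters", {
    a <- makeSample("A", pos = c(100, 101, 500, 501), count = c(50, 50, 40, 60),
                    tpm = c(50, 50, 40, 60))
    b <- makeSample("B", pos = c(100, 161, 500, 501), count = c(50, 50, 60, 40),
                    tpm = c(50, 50, 60, 40))
    cons <- aggregateConsensus(list(A = clusterCTSS(a), B = clusterCTSS(b)),
                               list(A = a, B = b))
    tab <- shiftTable(cons, "A", "B")
    expect_equal(nrow(tab), 2L)
    expect_true(all(c("score", "direction", "ksD", "p", "fdr") %in%
                    names(tab)))
    expect_true(all(tab$fdr >= 0 & tab$fdr <= 1))
    expect_equal(tab$fdr, bhFdr(tab$p))
    # the planted half-shift cluster scores higher than the subtle one
    expect_gt(max(tab$score), 0.4)
})

test_that("diversity tables and correlations behave", {
    cons <- twoSampleCons(c(100, 110, 120), c(10, 10, 10),
                          c(100, 110, 120), c(30, 0, 0))
    dt <- diversityTable(cons)
    expect_equal(dt$shannon[dt$sample == "A"], log(3))
    expect_equal(dt$shannon[dt$sample == "B"], 0)
    expect_equal(dt$S[dt$sample == "B"], 1L)

    v <- c(a = 1, b = 2, c = 3, d = 2.5)
    expect_equal(diversityCorrelation(v, v), 1)
    expect_equal(diversityCorrelation(v, -v), -1)
    expect_error(diversityCorrelation(v[1:2], v[1:2]), "at least 3")
    set.seed(14)
    x <- setNames(runif(20), paste0("c", 1:20))
    y <- setNames(runif(20), paste0("c", 1:20))
    expect_equal(diversityCorrelation(x, y),
                 sum((x - mean(x)) * (y - mean(y))) /
                     sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
})
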