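# shared fixtures and independent oracles, built in code at test time

makeSample <- function(id = "s", chrom = "chr1", pos, strand = "+",
                       count = NULL, tpm = NULL) {
    n <- length(pos)
    if (is.null(count)) count <- rep(1, n)
    CTSSSample(id, chrom = rep(chrom, length.out = n), pos = pos,
               strand = rep(strand, length.out = n),
               count = count, tpm = tpm)
}

randomSample <- function(n, id = "r", chroms = c("chr1", "chr2"),
                         maxPos = 1e5, maxCount = 50) {
    pos <- sample.int(maxPos, n)
    chrom <- sample(chroms, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    d <- data.frame(chrom, pos, strand)
    d <- d[!duplicated(d), , drop = FALSE]
    makeSample(id, chrom = d$chrom, pos = d$pos, strand = d$strand,
               count = sample.int(maxCount, nrow(d), replace = TRUE))
}

# O(n^2) transitive-closure clustering oracle: positions in the same cluster
# iff connected through gaps <= maxDist (single chrom/strand)
bruteCluster <- function(pos, maxDist) {
    n <- length(pos)
    grp <- seq_len(n)
    repeat {
        changed <- FALSE
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (abs(pos[i] - pos[j]) <= maxDist && grp[i] != grp[j]) {
                grp[grp == grp[j]] <- grp[i]
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    match(grp, unique(grp[order(pos)]))
}

# full consensus-grouping oracle: transitive closure on the "boundary
# intervals < maxGap apart" relation (same chrom/strand), then iterative
# merging of groups whose full-span unions overlap
bruteConsensusPartition <- function(chrom, strand, spanLo, spanHi,
                                    qLo, qHi, maxGap) {
    n <- length(qLo)
    key <- paste(chrom, strand)
    gap <- function(a1, a2, b1, b2) {
        if (a2 < b1) b1 - a2 else if (b2 < a1) a1 - b2 else 0L
    }
    grp <- seq_len(n)
    repeat {
        changed <- FALSE
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (key[i] == key[j] && grp[i] != grp[j] &&
                gap(qLo[i], qHi[i], qLo[j], qHi[j]) < maxGap) {
                grp[grp == grp[j]] <- grp[i]
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    repeat {
        changed <- FALSE
        gl <- tapply(spanLo, grp, min)[as.character(grp)]
        gh <- tapply(spanHi, grp, max)[as.character(grp)]
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (key[i] == key[j] && grp[i] != grp[j] &&
                gl[i] <= gh[j] && gh[i] >= gl[j]) {
                grp[grp == grp[j]] <- grp[i]
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    as.integer(factor(grp, levels = unique(grp)))
}

samePartition <- function(a, b) {
    identical(as.integer(factor(a, levels = unique(a))),
              as.integer(factor(b, levels = unique(b))))
}

# hand cumulative-sum shifting score oracle over aligned vectors (5'->3')
bruteShiftScore <- function(va, vb) {
    if (sum(va) <= sum(vb)) { f1 <- va; f2 <- vb } else { f1 <- vb; f2 <- va }
    fwd <- max(cumsum(f1) - cumsum(f2)) / sum(f1)
    bwd <- max(cumsum(rev(f1)) - cumsum(rev(f2))) / sum(f1)
    max(fwd, bwd)
}

# Weir-Cockerham theta by literal ANOVA on 0/1 allele indicators
# (independent of the closed-form frequency implementation)
bruteWcFst <- function(x1, n1, x2, n2) {
    y <- c(rep(1, x1), rep(0, n1 - x1), rep(1, x2), rep(0, n2 - x2))
    g <- c(rep(1, n1), rep(2, n2))
    n <- n1 + n2
    ybar <- mean(y)
    m1 <- mean(y[g == 1]); m2 <- mean(y[g == 2])
    ssb <- n1 * (m1 - ybar)^2 + n2 * (m2 - ybar)^2
    ssw <- sum((y[g == 1] - m1)^2) + sum((y[g == 2] - m2)^2)
    msb <- ssb / 1
    msw <- ssw / (n - 2)
    nc <- (n - (n1^2 + n2^2) / n) / 1
    s2A <- (msb - msw) / nc
    s2A / (s2A + msw)
}

# write a small SAM file; reads defined by (chrom, pos, strand, mapq, cigar)
writeSamFixture <- function(path, reads,
                            contigs = c(chr1 = 100000L, chr2 = 100000L)) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
    body <- vapply(seq_len(nrow(reads)), function(i) {
        r <- reads[i, ]
        flag <- if (r$strand == "-") 16L else 0L
        if (isTRUE(r$secondary)) flag <- flag + 256L
        if (isTRUE(r$duplicate)) flag <- flag + 1024L
        if (isTRUE(r$unmapped)) flag <- 4L
        seqlen <- GenomicAlignments::cigarWidthAlongQuerySpace(r$cigar)
        paste(sprintf("read%03d", i), flag,
              if (isTRUE(r$unmapped)) "*" else r$chrom,
              if (isTRUE(r$unmapped)) 0L else r$pos,
              r$mapq, if (isTRUE(r$unmapped)) "*" else r$cigar, "*", 0L, 0L,
              strrep("A", seqlen), strrep("F", seqlen), sep = "\t")
    }, "")
    writeLines(c(hdr, body), path)
    path
}

samRead <- function(chrom = "chr1", pos, strand = "+", mapq = 30L,
                    cigar = "27M", secondary = FALSE, duplicate = FALSE,
                    unmapped = FALSE) {
    data.frame(chrom = chrom, pos = pos, strand = strand, mapq = mapq,
               cigar = cigar, secondary = secondary, duplicate = duplicate,
               unmapped = unmapped)
}
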