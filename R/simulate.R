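#' Simulate a pair of CTSS samples with planted evolutionary events
#'
#' Generates two CAGE samples, A and B, sharing a common promoter
#' architecture with known ground truth.  Per-promoter expression follows
#' a power law with exponent `alphaSim`; within-promoter signal is either
#' sharp (a dominant peak with 1 bp jitter, interquartile width 0) or
#' broad (a smooth unimodal spread of 20-80 bp).  Sample B is derived from
#' A's architecture with planted events:
#'
#' * `divergent` - B's signal in the promoter is removed entirely;
#' * `shifted(f, offset)` - a fraction `f` of B's promoter signal moves to
#'   a narrow peak `offset` bp downstream of the promoter's 3' end,
#'   outside A's support but close enough (< 100 bp) to stay inside one
#'   consensus cluster;
#' * `translocated(offset)` - B's dominant CTSS moves `offset` bp along
#'   the strand (|offset| < 20 bp, so the tag cluster stays intact).
#'
#' Tags are then multinomially sampled to `depth` per sample, so the two
#' samples differ by sampling noise plus the planted events only.
#'
#' @param nPromoters number of promoters.
#' @param chromLengths named vector of chromosome lengths.
#' @param fracSharp fraction of sharp promoters.
#' @param alphaSim power-law exponent of per-promoter expression.
#' @param depth total tags per sample.
#' @param fracDivergent fraction of promoters planted as divergent.
#' @param shiftFractions planted usage-shift fractions `f` (one event per
#'   entry).
#' @param shiftOffset distance (bp, along the strand) of the shifted block
#'   beyond the promoter's 3' end.
#' @param translocationOffsets strand-oriented dominant-TSS offsets (bp),
#'   one event per entry.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#'
#' @return list with `sampleA`, `sampleB` ([CTSSSample-class]), `truth`
#'   (data.frame: promoter, chrom, strand, start, end, category, param),
#'   and `geneModel` (a `GRanges` of one transcript per promoter, usable
#'   with [annotateClusters()]).
#' @export
simulateCtssPair <- function(nPromoters = 500L,
                             chromLengths = c(chr1 = 5e6, chr2 = 5e6),
                             fracSharp = 0.4, alphaSim = 1.25,
                             depth = 5e5,
                             fracDivergent = 0.1,
                             shiftFractions = rep(c(0.2, 0.3, 0.4, 0.5), 5L),
                             shiftOffset = 60L,
                             translocationOffsets = c(2L, 3L, 5L, 8L, 12L,
                                                      -2L, -4L, -6L, -9L,
                                                      -11L),
                             seed = 1L) {
    nDiv <- round(fracDivergent * nPromoters)
    nShift <- length(shiftFractions)
    nTrans <- length(translocationOffsets)
    if (nDiv + nShift + nTrans > nPromoters)
        stop("more planted events than promoters")
    withSeed(seed, {
        # promoter anchors on a 2 kb grid (>= 1 kb spacing by construction)
        chroms <- rep(names(chromLengths), length.out = nPromoters)
        slot <- stats::ave(seq_len(nPromoters), chroms, FUN = seq_along)
        anchor <- 5000L + (slot - 1L) * 2000L + sample(0:500, nPromoters,
                                                       replace = TRUE)
        strand <- sample(c("+", "-"), nPromoters, replace = TRUE)
        weight <- stats::runif(nPromoters)^(-1 / alphaSim)
        sharp <- stats::runif(nPromoters) < fracSharp

        shapes <- vector("list", nPromoters)
        for (i in seq_len(nPromoters)) {
            if (sharp[i]) {
                off <- c(-1L, 0L, 1L)
                w <- c(0.1, 0.8, 0.1)
            } else {
                W <- sample(20:80, 1L)
                off <- 0:(W - 1L)
                mode <- W * stats::runif(1L, 0.3, 0.7)
                w <- stats::dnorm(off, mean = mode, sd = W / 4) + 0.02 / W
                # a clear dominant CTSS spike on top of the broad base, as
                # in real broad promoters; keeps the dominant unambiguous
                w[which.max(w)] <- w[which.max(w)] * 3
                w <- w / sum(w)
            }
            shapes[[i]] <- list(pos = anchor[i] + off, w = w)
        }

        idx <- sample(nPromoters)  # random assignment of event categories
        divIdx <- idx[seq_len(nDiv)]
        shiftIdx <- idx[nDiv + seq_len(nShift)]
        transIdx <- idx[nDiv + nShift + seq_len(nTrans)]
        category <- rep("null", nPromoters)
        param <- rep(NA_real_, nPromoters)
        category[divIdx] <- "divergent"
        category[shiftIdx] <- "shifted"
        param[shiftIdx] <- shiftFractions
        category[transIdx] <- "translocated"
        param[transIdx] <- translocationOffsets

        shapesB <- shapes
        for (k in seq_along(shiftIdx)) {
            i <- shiftIdx[k]
            f <- shiftFractions[k]
            sgn <- if (strand[i] == "+") 1L else -1L
            endPos <- if (strand[i] == "+") max(shapes[[i]]$pos)
                      else min(shapes[[i]]$pos)
            newPos <- endPos + sgn * (shiftOffset + c(0L, 1L, 2L))
            shapesB[[i]] <- list(
                pos = c(shapes[[i]]$pos, newPos),
                w = c(shapes[[i]]$w * (1 - f), f * c(0.6, 0.3, 0.1)))
        }
        for (k in seq_along(transIdx)) {
            i <- transIdx[k]
            sgn <- if (strand[i] == "+") 1L else -1L
            dom <- shapes[[i]]$pos[which.max(shapes[[i]]$w)]
            newDom <- dom + sgn * translocationOffsets[k]
            w <- shapes[[i]]$w
            j <- which.max(w)
            pos <- shapes[[i]]$pos
            hit <- match(newDom, pos)
            if (is.na(hit)) {
                pos <- c(pos, newDom)
                w <- c(w, w[j] * 1.5)
            } else {
                w[hit] <- w[hit] + w[j] * 1.5
            }
            w[j] <- w[j] * 0.3   # old dominant demoted, new clearly dominant
            shapesB[[i]] <- list(pos = pos, w = w / sum(w))
        }

        buildProb <- function(shp, wts, drop) {
            wts[drop] <- 0
            pos <- unlist(lapply(seq_along(shp), function(i)
                shp[[i]]$pos))
            chr <- rep(chroms, vapply(shp, function(s) length(s$pos), 0L))
            str <- rep(strand, vapply(shp, function(s) length(s$pos), 0L))
            prom <- rep(seq_along(shp), vapply(shp, function(s)
                length(s$pos), 0L))
            pw <- unlist(lapply(seq_along(shp), function(i)
                shp[[i]]$w * wts[i]))
            list(chrom = chr, pos = pos, strand = str, prom = prom,
                 p = pw / sum(pw))
        }
        probA <- buildProb(shapes, weight, drop = integer())
        probB <- buildProb(shapesB, weight, drop = divIdx)

        drawSample <- function(pr, id) {
            cnt <- as.integer(stats::rmultinom(1L, size = depth, prob = pr$p))
            keep <- cnt > 0L
            CTSSSample(id, chrom = pr$chrom[keep], pos = pr$pos[keep],
                       strand = pr$strand[keep], count = cnt[keep])
        }
        sampleA <- drawSample(probA, "simA")
        sampleB <- drawSample(probB, "simB")
    })
    spanStart <- vapply(shapes, function(s) min(s$pos), 0)
    spanEnd <- vapply(shapes, function(s) max(s$pos), 0)
    truth <- data.frame(promoter = seq_len(nPromoters), chrom = chroms,
                        strand = strand, start = spanStart, end = spanEnd,
                        weight = weight, sharp = sharp,
                        category = category, param = param)
    txStart <- ifelse(strand == "+", anchor, anchor)
    gene <- GenomicRanges::GRanges(chroms,
        IRanges::IRanges(start = ifelse(strand == "+", txStart,
                                        txStart - 1000L),
                         end = ifelse(strand == "+", txStart + 1000L,
                                      txStart)),
        strand = strand, type = "transcript",
        gene_id = paste0("gene", seq_len(nPromoters)),
        transcript_id = paste0("tx", seq_len(nPromoters)))
    list(sampleA = sampleA, sampleB = sampleB, truth = truth,
         geneModel = gene)
}

#' Simulate a per-replicate switch-design expression table
#'
#' Null genes carry additive cluster and stage effects (no interaction);
#' switch genes reverse cluster dominance between the two stages by the
#' stated fold.  Observations get multiplicative lognormal noise of the
#' stated coefficient of variation.
#'
#' @param nGenes number of genes.
#' @param nSwitch number of planted crossover switch genes.
#' @param fold dominance reversal fold of switch genes (> 1).
#' @param cv coefficient of variation of the lognormal noise.
#' @param reps replicates per stage (>= 2).
#' @param baseTpm baseline expression level (TPM).
#' @param seed integer seed.
#'
#' @return list with `expr` (data.frame: gene, cluster, stage, replicate,
#'   tpm) and `truth` (data.frame: gene, switch).
#' @export
simulateSwitchTable <- function(nGenes = 388L, nSwitch = 13L, fold = 4,
                                cv = 0.1, reps = 2L, baseTpm = 10,
                                seed = 1L) {
    stopifnot(nSwitch <= nGenes, fold >= 1, reps >= 2L)
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- -sdlog^2 / 2            # noise has mean exactly 1
    withSeed(seed, {
        switch <- c(rep(TRUE, nSwitch), rep(FALSE, nGenes - nSwitch))
        switch <- sample(switch)
        rows <- vector("list", nGenes)
        for (g in seq_len(nGenes)) {
            if (switch[g]) {
                mu <- rbind(TSS1 = c(fetal = baseTpm * fold,
                                     adult = baseTpm),
                            TSS2 = c(fetal = baseTpm,
                                     adult = baseTpm * fold))
            } else {
                clusterEff <- stats::runif(1L, 0, baseTpm / 2)
                stageEff <- stats::runif(1L, -baseTpm / 5, baseTpm / 5)
                mu <- rbind(TSS1 = c(fetal = baseTpm,
                                     adult = baseTpm + stageEff),
                            TSS2 = c(fetal = baseTpm + clusterEff,
                                     adult = baseTpm + clusterEff +
                                             stageEff))
            }
            grid <- expand.grid(cluster = rownames(mu),
                                stage = colnames(mu),
                                replicate = seq_len(reps),
                                stringsAsFactors = FALSE)
            eps <- exp(stats::rnorm(nrow(grid), meanlog, sdlog))
            grid$tpm <- mu[cbind(grid$cluster, grid$stage)] * eps
            grid$gene <- paste0("gene", g)
            rows[[g]] <- grid[c("gene", "cluster", "stage", "replicate",
                                "tpm")]
        }
    })
    list(expr = do.call(rbind, rows),
         truth = data.frame(gene = paste0("gene", seq_len(nGenes)),
                            switch = switch))
}

#' Simulate two-population biallelic SNPs with known divergence
#'
#' Balding-Nichols model: ancestral frequencies are uniform on
#' `(0.05, 0.95)` and each population's frequency is drawn from
#' `Beta(p(1-c)/c, (1-p)(1-c)/c)`, so the expected FST between the two
#' populations is `c`.  Allele counts per population are binomial in the
#' gamete count.  Optionally writes a VCF (diploid genotypes assembled by
#' random pairing of gametes), a BED of the containing regions and a truth
#' table to `dir`.
#'
#' @param nSnps number of SNPs.
#' @param nGametes gametes per population (even; individuals =
#'   `nGametes / 2`).
#' @param c divergence parameter (expected FST), in (0, 1); `c` near 0
#'   approaches panmixia.
#' @param seed integer seed.
#' @param dir optional output directory for `snps.vcf`, `regions.bed`,
#'   `truth.tsv`.
#' @param snpsPerRegion SNPs per BED region (regions are 10 kb blocks).
#'
#' @return list with `snps` (data.frame: chrom, pos, ref, alt, p1, n1,
#'   maf1, p2, n2, maf2, nGametesTotal, maf, pAncestral, pTrue1, pTrue2)
#'   and, when `dir` is given, `vcf`, `bed`, `truth` file paths.
#' @export
simulateTwoPopSnps <- function(nSnps = 10000L, nGametes = 200L, c = 0.1,
                               seed = 1L, dir = NULL,
                               snpsPerRegion = 50L) {
    stopifnot(nGametes %% 2L == 0L, c > 0, c < 1)
    withSeed(seed, {
        pAnc <- stats::runif(nSnps, 0.05, 0.95)
        pTrue1 <- stats::rbeta(nSnps, pAnc * (1 - c) / c,
                               (1 - pAnc) * (1 - c) / c)
        pTrue2 <- stats::rbeta(nSnps, pAnc * (1 - c) / c,
                               (1 - pAnc) * (1 - c) / c)
        x1 <- stats::rbinom(nSnps, nGametes, pTrue1)
        x2 <- stats::rbinom(nSnps, nGametes, pTrue2)
        refAlt <- t(vapply(seq_len(nSnps), function(i)
            sample(c("A", "C", "G", "T"), 2L), c("", "")))
        gametes1 <- lapply(seq_len(nSnps), function(i)
            sample(c(rep(1L, x1[i]), rep(0L, nGametes - x1[i]))))
        gametes2 <- lapply(seq_len(nSnps), function(i)
            sample(c(rep(1L, x2[i]), rep(0L, nGametes - x2[i]))))
    })
    region <- (seq_len(nSnps) - 1L) %/% snpsPerRegion
    posInRegion <- ((seq_len(nSnps) - 1L) %% snpsPerRegion + 1L) *
        (10000L %/% (snpsPerRegion + 1L))
    pos <- region * 20000L + posInRegion + 1L
    p1 <- x1 / nGametes
    p2 <- x2 / nGametes
    pooled <- (x1 + x2) / (2 * nGametes)
    snps <- data.frame(chrom = "chr1", pos = pos,
                       ref = refAlt[, 1L], alt = refAlt[, 2L],
                       p1 = p1, n1 = nGametes, maf1 = pmin(p1, 1 - p1),
                       p2 = p2, n2 = nGametes, maf2 = pmin(p2, 1 - p2),
                       nGametesTotal = 2L * nGametes,
                       maf = pmin(pooled, 1 - pooled),
                       pAncestral = pAnc, pTrue1 = pTrue1, pTrue2 = pTrue2)
    out <- list(snps = snps)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        nInd <- nGametes / 2L
        ids <- c(paste0("pop1_", seq_len(nInd)),
                 paste0("pop2_", seq_len(nInd)))
        gtRow <- function(g1, g2) {
            gam <- c(g1, g2)
            paste0(gam[c(TRUE, FALSE)], "/", gam[c(FALSE, TRUE)])
        }
        gts <- t(vapply(seq_len(nSnps), function(i)
            gtRow(gametes1[[i]], gametes2[[i]]), character(2L * nInd)))
        vcfPath <- file.path(dir, "snps.vcf")
        con <- file(vcfPath, "w")
        writeLines(c("##fileformat=VCFv4.2",
                     "##contig=<ID=chr1>",
                     paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                            "Description=\"Genotype\">"),
                     paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                             "FILTER", "INFO", "FORMAT", ids),
                           collapse = "\t")), con)
        body <- paste(snps$chrom, snps$pos,
                      paste0("snp", seq_len(nSnps)), snps$ref, snps$alt,
                      ".", "PASS", ".", "GT",
                      apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
        writeLines(body, con)
        close(con)
        bedPath <- file.path(dir, "regions.bed")
        regs <- unique(region)
        utils::write.table(data.frame("chr1", regs * 20000L,
                               regs * 20000L + 10000L,
                               paste0("region", regs + 1L)),
                    bedPath, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        truthPath <- file.path(dir, "truth.tsv")
        utils::write.table(snps[c("chrom", "pos", "pAncestral", "pTrue1",
                           "pTrue2")],
                    truthPath, sep = "\t", quote = FALSE, row.names = FALSE)
        out$vcf <- vcfPath
        out$bed <- bedPath
        out$truth <- truthPath
        out$popAssignments <- data.frame(
            sample = ids,
            population = rep(c("pop1", "pop2"), each = nInd))
    }
    out
}
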