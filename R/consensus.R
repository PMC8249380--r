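#' Aggregate per-sample tag clusters into consensus clusters
#'
#' Tag clusters from all samples are merged by single linkage on their
#' quantile-boundary intervals `[qLow, qHigh]`: two clusters on the same
#' chromosome and strand join the same consensus cluster whenever the gap
#' between their boundary intervals is strictly less than `maxGap` bp
#' (default 100).  The consensus span is the union of the member clusters'
#' full spans, so per-sample profiles lose no signal; groups whose full
#' spans still overlap are merged further until consensus clusters are
#' non-overlapping per chromosome and strand.
#'
#' @param clusterSets named list of [TagClusterSet-class], one per sample.
#' @param samples named list of normalized [CTSSSample-class] objects (same
#'   names) used to fill per-sample signal profiles across each consensus
#'   span.
#' @param maxGap aggregation distance (strict upper bound on the boundary
#'   gap).
#'
#' @return a [ConsensusClusterSet-class] with per-sample TPM and raw-count
#'   totals and full per-position profiles.
#' @export
aggregateConsensus <- function(clusterSets, samples, maxGap = 100L) {
    stopifnot(is.list(clusterSets), is.list(samples))
    if (length(clusterSets))
        stopifnot(!is.null(names(clusterSets)), !is.null(names(samples)),
                  all(names(clusterSets) %in% names(samples)))
    sampleNames <- names(clusterSets)
    cl <- lapply(clusterSets, clusters)
    all <- suppressWarnings(do.call(c, unname(cl)))
    if (!length(all)) {
        return(methods::new("ConsensusClusterSet",
            clusters = GenomicRanges::GRanges(
                id = character(), annotation = character(),
                geneID = character()),
            sampleTotals = matrix(0, 0, length(sampleNames),
                                  dimnames = list(NULL, sampleNames)),
            sampleCounts = matrix(0, 0, length(sampleNames),
                                  dimnames = list(NULL, sampleNames)),
            profiles = data.frame(id = character(), sample = character(),
                                  pos = integer(), count = numeric(),
                                  tpm = numeric())))
    }
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(all)),
                     strand = as.character(GenomicRanges::strand(all)),
                     spanStart = GenomicRanges::start(all),
                     spanEnd = GenomicRanges::end(all),
                     qLow = all$qLow, qHigh = all$qHigh)
    # single-linkage on boundary intervals within each chrom/strand
    df$group <- NA_integer_
    nextGroup <- 0L
    for (key in unique(paste(df$chrom, df$strand))) {
        i <- which(paste(df$chrom, df$strand) == key)
        o <- i[order(df$qLow[i], df$qHigh[i])]
        qh <- cummax(df$qHigh[o])
        gap <- df$qLow[o][-1L] - qh[-length(o)]
        g <- cumsum(c(TRUE, gap >= maxGap)) + nextGroup
        df$group[o] <- g
        nextGroup <- max(g)
    }
    # merge further while union-of-span groups overlap on a chrom/strand
    repeat {
        spans <- do.call(rbind, lapply(split(df, df$group), function(d)
            data.frame(chrom = d$chrom[1L], strand = d$strand[1L],
                       start = min(d$spanStart), end = max(d$spanEnd),
                       group = d$group[1L])))
        remap <- stats::setNames(spans$group, spans$group)
        merged <- FALSE
        for (key in unique(paste(spans$chrom, spans$strand))) {
            i <- which(paste(spans$chrom, spans$strand) == key)
            o <- i[order(spans$start[i])]
            if (length(o) < 2L) next
            overl <- spans$start[o][-1L] <= cummax(spans$end[o])[-length(o)]
            if (any(overl)) {
                merged <- TRUE
                comp <- cumsum(c(TRUE, !overl))
                for (cc in split(o, comp))
                    remap[as.character(spans$group[cc])] <-
                        spans$group[cc[1L]]
            }
        }
        if (!merged) break
        df$group <- unname(remap[as.character(df$group)])
    }
    spans <- do.call(rbind, lapply(split(df, df$group), function(d)
        data.frame(chrom = d$chrom[1L], strand = d$strand[1L],
                   start = min(d$spanStart), end = max(d$spanEnd))))
    o <- order(spans$chrom, spans$strand, spans$start)
    spans <- spans[o, , drop = FALSE]
    consGR <- GenomicRanges::GRanges(spans$chrom,
        IRanges::IRanges(spans$start, spans$end), strand = spans$strand)
    consGR$id <- sprintf("CC%05d", seq_along(consGR))
    consGR$annotation <- NA_character_
    consGR$geneID <- NA_character_

    totals <- matrix(0, length(consGR), length(sampleNames),
                     dimnames = list(consGR$id, sampleNames))
    counts <- totals
    profs <- vector("list", length(sampleNames))
    for (s in sampleNames) {
        gr <- ctss(samples[[s]])
        hits <- GenomicRanges::findOverlaps(gr, consGR, ignore.strand = FALSE)
        if (!length(hits)) next
        qi <- S4Vectors::queryHits(hits)
        ci <- S4Vectors::subjectHits(hits)
        tpmv <- gr$tpm[qi]
        tpmv[is.na(tpmv)] <- 0
        profs[[s]] <- data.frame(id = consGR$id[ci], sample = s,
                                 pos = GenomicRanges::start(gr)[qi],
                                 count = gr$count[qi], tpm = tpmv)
        totals[, s] <- totals[, s] +
            as.numeric(tapply(tpmv, factor(ci, seq_along(consGR)), sum,
                              default = 0))
        counts[, s] <- counts[, s] +
            as.numeric(tapply(gr$count[qi], factor(ci, seq_along(consGR)),
                              sum, default = 0))
    }
    profs <- do.call(rbind, profs[!vapply(profs, is.null, TRUE)])
    if (is.null(profs))
        profs <- data.frame(id = character(), sample = character(),
                            pos = integer(), count = numeric(),
                            tpm = numeric())
    rownames(profs) <- NULL
    methods::new("ConsensusClusterSet", clusters = consGR,
                 sampleTotals = totals, sampleCounts = counts,
                 profiles = profs)
}

# 5'->3' signal profile of one consensus cluster for a set of samples
# (tpm and raw counts summed over the samples at each position)
groupProfile <- function(cons, id, samples) {
    pr <- cons@profiles
    pr <- pr[pr$id == id & pr$sample %in% samples, , drop = FALSE]
    cl <- clusters(cons)
    strand <- as.character(GenomicRanges::strand(cl[cl$id == id]))
    if (!nrow(pr))
        return(list(pos = integer(), tpm = numeric(), count = numeric(),
                    strand = strand, total = 0))
    tpm <- tapply(pr$tpm, pr$pos, sum)
    count <- tapply(pr$count, pr$pos, sum)
    pos <- as.integer(names(tpm))
    o <- fivePrimeOrder(pos, strand)
    list(pos = pos[o], tpm = as.numeric(tpm)[o],
         count = as.numeric(count)[o], strand = strand,
         total = sum(pr$tpm))
}
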