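#' Position of a signal quantile within a cluster
#'
#' The quantile position is the smallest position, in 5'->3' order along
#' the strand, at which the cumulative signal reaches `q` times the total.
#' The 0.1/0.9 quantile positions define cluster boundaries for consensus
#' aggregation, and the 0.25/0.75 positions define the interquartile width
#' used to classify promoter shape.
#'
#' @param pos integer positions of the cluster members.
#' @param tpm signal at each position (same length as `pos`).
#' @param q quantile fraction in (0, 1).
#' @param strand "+" or "-"; on "-" the 5'->3' order runs from high to low
#'   coordinates.
#'
#' @return a single genomic position.
#' @examples
#' quantilePosition(c(10, 20, 30, 40), c(1, 1, 1, 1), 0.5, "+")  # 20
#' @export
quantilePosition <- function(pos, tpm, q, strand = "+") {
    stopifnot(length(pos) == length(tpm), q > 0, q < 1)
    stopifnotStrand(strand)
    if (!length(pos)) stop("empty cluster")
    o <- fivePrimeOrder(pos, strand)
    cum <- cumsum(tpm[o])
    pos[o][which(cum >= q * cum[length(cum)] - 1e-12)[1L]]
}

#' Dominant TSS of a cluster
#'
#' The member position carrying the highest signal; ties are broken toward
#' the most 5' position on the cluster's strand, which keeps the rule
#' deterministic and strand-symmetric.
#'
#' @inheritParams quantilePosition
#' @return list with `pos` and `tpm` of the dominant CTSS.
#' @export
dominantTSS <- function(pos, tpm, strand = "+") {
    stopifnot(length(pos) == length(tpm), length(pos) >= 1L)
    stopifnotStrand(strand)
    o <- fivePrimeOrder(pos, strand)
    i <- o[which.max(tpm[o])]   # which.max takes the first (= most 5') tie
    list(pos = pos[i], tpm = tpm[i])
}

#' Classify promoter shape from interquartile width
#'
#' A cluster is "sharp" when the distance between its 0.25 and 0.75 signal
#' quantile positions is strictly less than `sharpThreshold` base pairs
#' (default 4), else "broad".
#'
#' @param iqWidth interquartile width(s) in bp.
#' @param sharpThreshold strict upper bound for "sharp".
#' @return character vector of "sharp"/"broad".
#' @export
classifyShape <- function(iqWidth, sharpThreshold = 4) {
    ifelse(iqWidth < sharpThreshold, "sharp", "broad")
}

# summary statistics for one run of member CTSSs
clusterStats <- function(pos, tpm, strand, sharpThreshold = 4) {
    dom <- dominantTSS(pos, tpm, strand)
    qb <- c(quantilePosition(pos, tpm, 0.1, strand),
            quantilePosition(pos, tpm, 0.9, strand))
    iq <- abs(quantilePosition(pos, tpm, 0.75, strand) -
              quantilePosition(pos, tpm, 0.25, strand))
    list(start = min(pos), end = max(pos), nCTSS = length(pos),
         totalTpm = sum(tpm), dominantPos = dom$pos, dominantTpm = dom$tpm,
         qLow = min(qb), qHigh = max(qb), iqWidth = iq,
         shape = classifyShape(iq, sharpThreshold))
}

#' Call tag clusters by distance-based chaining
#'
#' CTSSs below `minTpm` normalized tags are discarded, then CTSSs on the
#' same chromosome and strand are chained into one tag cluster while the
#' gap to the next CTSS is at most `maxDist` bp (default 20); adjacent
#' clusters are separated by gaps greater than `maxDist`.
#'
#' @param sample a normalized [CTSSSample-class] (tpm present).
#' @param maxDist maximal allowed distance between neighbouring CTSSs.
#' @param minTpm minimum normalized signal per CTSS (strictly below is
#'   filtered out).
#' @param sharpThreshold interquartile width bound for the "sharp" label.
#'
#' @return a [TagClusterSet-class].
#' @export
clusterCTSS <- function(sample, maxDist = 20L, minTpm = 1,
                        sharpThreshold = 4) {
    stopifnot(methods::is(sample, "CTSSSample"))
    gr <- ctss(sample)
    if (length(gr) && all(is.na(gr$tpm)))
        stop("sample is not normalized; run normalizeSample() first")
    gr <- gr[!is.na(gr$tpm) & gr$tpm >= minTpm]
    if (!length(gr)) {
        empty <- GenomicRanges::GRanges()
        S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
            nCTSS = integer(), totalTpm = numeric(), dominantPos = integer(),
            dominantTpm = numeric(), qLow = integer(), qHigh = integer(),
            iqWidth = numeric(), shape = character())
        gr2 <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr2) <- S4Vectors::DataFrame(
            count = numeric(), tpm = numeric(), clusterID = integer())
        return(methods::new("TagClusterSet", sampleID = sampleID(sample),
                            clusters = empty, ctss = gr2))
    }
    # canonical sort groups chrom/strand into contiguous blocks
    gr <- sortCtssRanges(gr)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    strand <- as.character(GenomicRanges::strand(gr))
    pos <- GenomicRanges::start(gr)
    newBlock <- c(TRUE, chrom[-1L] != chrom[-length(chrom)] |
                        strand[-1L] != strand[-length(strand)] |
                        diff(pos) > maxDist)
    cid <- cumsum(newBlock)
    gr$clusterID <- cid
    stats <- lapply(split(seq_along(gr), cid), function(i)
        c(list(chrom = chrom[i[1L]], strand = strand[i[1L]]),
          clusterStats(pos[i], gr$tpm[i], strand[i[1L]], sharpThreshold)))
    pull <- function(what, proto) unname(vapply(stats, `[[`, proto, what))
    cl <- GenomicRanges::GRanges(
        pull("chrom", ""),
        IRanges::IRanges(start = pull("start", 0), end = pull("end", 0)),
        strand = pull("strand", ""),
        nCTSS = pull("nCTSS", 0L),
        totalTpm = pull("totalTpm", 0),
        dominantPos = pull("dominantPos", 0),
        dominantTpm = pull("dominantTpm", 0),
        qLow = pull("qLow", 0),
        qHigh = pull("qHigh", 0),
        iqWidth = pull("iqWidth", 0),
        shape = pull("shape", ""))
    methods::new("TagClusterSet", sampleID = sampleID(sample),
                 clusters = cl, ctss = gr)
}

#' Export cluster spans as BED
#'
#' Writes tag-cluster or consensus-cluster spans in BED format (0-based
#' half-open, handled by rtracklayer); the thick region marks the
#' interquantile span for tag clusters, and the score column carries total
#' TPM capped at 1000.
#'
#' @param x a [TagClusterSet-class] or [ConsensusClusterSet-class].
#' @param path output file path.
#' @export
exportClustersBED <- function(x, path) {
    cl <- clusters(x)
    if (methods::is(x, "TagClusterSet")) {
        cl$name <- paste0(sampleID(x), "_TC", seq_along(cl))
        cl$thick <- IRanges::IRanges(cl$qLow, cl$qHigh)
        cl$score <- pmin(cl$totalTpm, 1000)
    } else {
        cl$name <- cl$id
        cl$score <- pmin(rowSums(sampleTotals(x)), 1000)
    }
    rtracklayer::export.bed(cl, path)
    invisible(path)
}
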