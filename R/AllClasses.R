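#' CTSSSample: per-nucleotide CAGE tag start-site counts for one sample
#'
#' Holds strand-specific CAGE tag 5'-end counts at single-nucleotide
#' resolution for one sample (or one merged group of replicates).  Positions
#' are 1-based.  Raw tag counts are kept unmodified; the `tpm` metadata
#' column carries normalized signal once a sample has been normalized (NA
#' before that).
#'
#' @slot sampleID single character identifier.
#' @slot ctss [GenomicRanges::GRanges] of width-1 positions with metadata
#'   columns `count` (non-negative raw tag count) and `tpm` (normalized
#'   signal, `NA_real_` before normalization).  Sorted by (chrom, strand,
#'   pos) with unique positions per strand.
#' @slot librarySize total raw tag count (sum of `count`).
#'
#' @seealso [CTSSSample()], [readCTSS()], [extractCTSS()]
#' @export
setClass("CTSSSample",
    representation(sampleID = "character",
                   ctss = "GRanges",
                   librarySize = "numeric"))

setValidity("CTSSSample", function(object) {
    msg <- NULL
    gr <- object@ctss
    if (length(object@sampleID) != 1L || is.na(object@sampleID))
        msg <- c(msg, "sampleID must be a single non-NA string")
    if (!all(c("count", "tpm") %in% colnames(S4Vectors::mcols(gr))))
        msg <- c(msg, "ctss must carry 'count' and 'tpm' metadata columns")
    else {
        cnt <- gr$count
        if (any(is.na(cnt)) || any(cnt < 0))
            msg <- c(msg, "counts must be non-negative and non-NA")
        if (length(gr)) {
            if (!all(as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
                msg <- c(msg, "strand must be '+' or '-' for every CTSS")
            if (any(GenomicRanges::width(gr) != 1L))
                msg <- c(msg, "all CTSS ranges must have width 1")
            if (any(GenomicRanges::start(gr) < 1L))
                msg <- c(msg, "positions must be >= 1")
            key <- paste(GenomicRanges::seqnames(gr),
                         GenomicRanges::strand(gr),
                         GenomicRanges::start(gr))
            if (anyDuplicated(key))
                msg <- c(msg, "(chrom, pos, strand) must be unique")
            o <- order(as.factor(GenomicRanges::seqnames(gr)),
                       as.factor(GenomicRanges::strand(gr)),
                       GenomicRanges::start(gr))
            if (!identical(o, seq_along(gr)))
                msg <- c(msg, "ctss must be sorted by (chrom, strand, pos)")
        }
        if (!isTRUE(all.equal(object@librarySize, sum(as.numeric(cnt)))))
            msg <- c(msg, "librarySize must equal the sum of counts")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a CTSSSample
#'
#' @param sampleID sample identifier.
#' @param chrom,pos,strand,count parallel vectors describing CTSS records;
#'   alternatively pass a `GRanges` as `chrom` (with `count`, optionally
#'   `tpm`, metadata columns) and leave the rest missing.
#' @param tpm optional normalized signal (defaults to `NA`).
#'
#' @return a [CTSSSample-class] object, records sorted by (chrom, strand, pos).
#' @examples
#' s <- CTSSSample("ex", chrom = "chr1", pos = c(100, 120),
#'                 strand = "+", count = c(5, 3))
#' librarySize(s)
#' @export
CTSSSample <- function(sampleID, chrom = character(), pos = integer(),
                       strand = character(), count = numeric(), tpm = NULL) {
    if (methods::is(chrom, "GRanges")) {
        gr <- chrom
        if (is.null(gr$count)) stop("GRanges input must carry a 'count' column")
        if (is.null(gr$tpm)) gr$tpm <- NA_real_
        gr <- gr[, c("count", "tpm")]
    } else {
        if (is.null(tpm)) tpm <- rep(NA_real_, length(pos))
        gr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = as.integer(pos), width = 1L),
            strand = strand, count = as.numeric(count), tpm = as.numeric(tpm))
    }
    gr <- sortCtssRanges(gr)
    methods::new("CTSSSample", sampleID = as.character(sampleID), ctss = gr,
                 librarySize = sum(as.numeric(gr$count)))
}

# canonical (chrom, strand, pos) total order used throughout
sortCtssRanges <- function(gr) {
    gr[order(as.factor(GenomicRanges::seqnames(gr)),
             as.factor(GenomicRanges::strand(gr)),
             GenomicRanges::start(gr))]
}

#' @rdname promdiv-generics
#' @export
setMethod("sampleID", "CTSSSample", function(object) object@sampleID)

#' @rdname promdiv-generics
#' @export
setMethod("librarySize", "CTSSSample", function(object) object@librarySize)

#' @rdname promdiv-generics
#' @export
setMethod("ctss", "CTSSSample", function(object) object@ctss)

setMethod("show", "CTSSSample", function(object) {
    norm <- if (length(object@ctss) && !all(is.na(object@ctss$tpm)))
        "normalized" else "raw"
    cat("CTSSSample '", object@sampleID, "': ", length(object@ctss),
        " CTSSs, library size ", format(object@librarySize, big.mark = ","),
        " (", norm, ")\n", sep = "")
})

#' @param x,i,j,drop subsetting arguments.
#' @describeIn CTSSSample-class subset records, keeping library size in sync
#'   with the retained counts.
#' @export
setMethod("[", "CTSSSample", function(x, i, j, ..., drop = TRUE) {
    gr <- x@ctss[i]
    methods::new("CTSSSample", sampleID = x@sampleID, ctss = gr,
                 librarySize = sum(as.numeric(gr$count)))
})

#' @describeIn CTSSSample-class number of CTSS records.
#' @export
setMethod("length", "CTSSSample", function(x) length(x@ctss))


#' TagClusterSet: per-sample distance-based TSS clusters
#'
#' Result of [clusterCTSS()]: contiguous strand-specific runs of CTSSs,
#' summarized by total signal, dominant position, 0.1/0.9 signal-quantile
#' boundaries and interquartile width.
#'
#' @slot sampleID the sample the clusters were called in.
#' @slot clusters `GRanges` of cluster spans with metadata columns `nCTSS`,
#'   `totalTpm`, `dominantPos`, `dominantTpm`, `qLow`, `qHigh` (genomic
#'   coordinates of the 0.1/0.9 signal quantile positions, qLow <= qHigh),
#'   `iqWidth` (bp between the 0.25 and 0.75 quantile positions) and `shape`
#'   ("sharp"/"broad").
#' @slot ctss the retained (>= min TPM) member CTSSs with a `clusterID`
#'   metadata column indexing into `clusters`.
#' @export
setClass("TagClusterSet",
    representation(sampleID = "character",
                   clusters = "GRanges",
                   ctss = "GRanges"))

setValidity("TagClusterSet", function(object) {
    msg <- NULL
    cl <- object@clusters
    need <- c("nCTSS", "totalTpm", "dominantPos", "dominantTpm",
              "qLow", "qHigh", "iqWidth", "shape")
    if (!all(need %in% colnames(S4Vectors::mcols(cl))))
        msg <- c(msg, "missing cluster summary columns")
    else if (length(cl)) {
        if (any(cl$totalTpm <= 0)) msg <- c(msg, "totalTpm must be > 0")
        if (any(cl$qLow > cl$qHigh)) msg <- c(msg, "qLow must be <= qHigh")
        if (any(cl$dominantPos < GenomicRanges::start(cl) |
                cl$dominantPos > GenomicRanges::end(cl)))
            msg <- c(msg, "dominant position must lie within the cluster span")
    }
    if (!is.null(object@ctss$clusterID) && length(object@ctss)) {
        if (any(object@ctss$clusterID < 1L |
                object@ctss$clusterID > length(cl)))
            msg <- c(msg, "clusterID out of range")
    }
    if (is.null(msg)) TRUE else msg
})

#' @rdname promdiv-generics
#' @export
setMethod("sampleID", "TagClusterSet", function(object) object@sampleID)

#' @rdname promdiv-generics
#' @export
setMethod("clusters", "TagClusterSet", function(object, ...) object@clusters)

#' @rdname promdiv-generics
#' @export
setMethod("ctss", "TagClusterSet", function(object) object@ctss)

#' @describeIn TagClusterSet-class number of tag clusters.
#' @export
setMethod("length", "TagClusterSet", function(x) length(x@clusters))

setMethod("show", "TagClusterSet", function(object) {
    cl <- object@clusters
    cat("TagClusterSet '", object@sampleID, "': ", length(cl),
        " tag clusters (", sum(cl$shape == "sharp"), " sharp / ",
        sum(cl$shape == "broad"), " broad), ",
        length(object@ctss), " member CTSSs\n", sep = "")
})


#' ConsensusClusterSet: cross-sample consensus TSS clusters
#'
#' Result of [aggregateConsensus()]: non-overlapping (per chrom/strand)
#' aggregations of per-sample tag clusters, carrying per-sample signal
#' profiles so that all between-sample statistics can be computed from one
#' object.
#'
#' @slot clusters `GRanges` of consensus spans with metadata columns `id`,
#'   `annotation` ("promoter"/"exon"/"intron"/"intergenic" or NA before
#'   annotation) and `geneID`.
#' @slot sampleTotals numeric matrix (clusters x samples) of total TPM per
#'   sample within each consensus span.
#' @slot sampleCounts numeric matrix of total raw tag counts per sample.
#' @slot profiles data.frame of the per-sample CTSS signal inside each span:
#'   columns `id`, `sample`, `pos`, `count`, `tpm`.
#' @export
setClass("ConsensusClusterSet",
    representation(clusters = "GRanges",
                   sampleTotals = "matrix",
                   sampleCounts = "matrix",
                   profiles = "data.frame"))

setValidity("ConsensusClusterSet", function(object) {
    msg <- NULL
    cl <- object@clusters
    if (length(cl)) {
        if (is.null(cl$id) || anyDuplicated(cl$id))
            msg <- c(msg, "clusters must carry unique ids")
        hits <- GenomicRanges::findOverlaps(cl, cl, ignore.strand = FALSE)
        if (length(hits) > length(cl))
            msg <- c(msg, "consensus clusters overlap on the same chrom/strand")
        if (nrow(object@sampleTotals) != length(cl) ||
            nrow(object@sampleCounts) != length(cl))
            msg <- c(msg, "total matrices must have one row per cluster")
    }
    if (is.null(msg)) TRUE else msg
})

#' @rdname promdiv-generics
#' @export
setMethod("clusters", "ConsensusClusterSet", function(object, ...)
    object@clusters)

#' @rdname promdiv-generics
#' @export
setMethod("profiles", "ConsensusClusterSet", function(object) object@profiles)

#' @rdname promdiv-generics
#' @export
setMethod("sampleTotals", "ConsensusClusterSet", function(object)
    object@sampleTotals)

#' @rdname promdiv-generics
#' @export
setMethod("sampleCounts", "ConsensusClusterSet", function(object)
    object@sampleCounts)

#' @describeIn ConsensusClusterSet-class number of consensus clusters.
#' @export
setMethod("length", "ConsensusClusterSet", function(x) length(x@clusters))

setMethod("show", "ConsensusClusterSet", function(object) {
    cl <- object@clusters
    ann <- if (length(cl) && !all(is.na(cl$annotation)))
        paste0("; ", sum(cl$annotation == "promoter", na.rm = TRUE),
               " promoter") else ""
    cat("ConsensusClusterSet: ", length(cl), " consensus clusters over ",
        ncol(object@sampleTotals), " samples", ann, "\n", sep = "")
})
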