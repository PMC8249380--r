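#' Extract CTSSs from a BAM/SAM file
#'
#' Tallies CAGE tag 5' ends per genomic position and strand.  Only mapped,
#' primary, non-duplicate alignments with mapping quality strictly greater
#' than `minMapq` contribute.  The 5' end is the leftmost aligned reference
#' base for plus-strand alignments and the rightmost for minus-strand
#' alignments.  Positions supported by fewer than `minSupport` tag 5' ends
#' are discarded.
#'
#' @param file path to a BAM file (or a SAM text file, which is converted
#'   on the fly).
#' @param minMapq keep alignments with MAPQ > `minMapq` (default 20).
#' @param minSupport minimum number of supporting tag 5' ends per CTSS
#'   (default 3).
#' @param sampleID sample identifier; defaults to the file base name.
#'
#' @return a [CTSSSample-class].  An input with no usable alignments yields
#'   an empty sample, not an error.  Alignments with MAPQ recorded as
#'   unavailable (255) are treated as MAPQ 0 with a warning.
#' @export
extractCTSS <- function(file, minMapq = 20L, minSupport = 3L,
                        sampleID = sub("\\.(bam|sam)$", "", basename(file))) {
    if (grepl("\\.sam$", file, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        file <- Rsamtools::asBam(file, destination = dest,
                                 overwrite = TRUE, indexDestination = FALSE)
    }
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE,
                                   isDuplicate = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, what = "mapq")
    aln <- GenomicAlignments::readGAlignments(file, param = param)
    mapq <- S4Vectors::mcols(aln)$mapq
    if (length(mapq) && any(is.na(mapq) | mapq == 255L)) {
        warning("alignments without a recorded MAPQ treated as MAPQ 0")
        mapq[is.na(mapq) | mapq == 255L] <- 0L
    }
    aln <- aln[mapq > minMapq]
    if (!length(aln))
        return(CTSSSample(sampleID))
    str <- as.character(GenomicRanges::strand(aln))
    pos <- ifelse(str == "+", GenomicRanges::start(aln),
                  GenomicRanges::end(aln))
    tab <- stats::aggregate(
        list(count = rep(1L, length(aln))),
        by = list(chrom = as.character(GenomicRanges::seqnames(aln)),
                  pos = pos, strand = str),
        FUN = sum)
    tab <- tab[tab$count >= minSupport, , drop = FALSE]
    CTSSSample(sampleID, chrom = tab$chrom, pos = tab$pos,
               strand = tab$strand, count = tab$count)
}

#' Read / write CTSS tables
#'
#' The CTSS interchange format is tab-delimited with columns
#' `chrom`, `pos` (1-based), `strand` (+/-), `count` and an optional fifth
#' `tpm` column.  Lines starting with `#` are comments.  Records are
#' re-sorted by (chrom, strand, pos) on read, so `writeCTSS()` followed by
#' `readCTSS()` is an identity on the record set.
#'
#' @param path file path.
#' @param sampleID sample identifier; defaults to the file base name.
#'
#' @return `readCTSS()` returns a [CTSSSample-class]; malformed lines raise
#'   an error naming the offending line number.
#' @export
readCTSS <- function(path, sampleID = sub("\\.[^.]*$", "", basename(path))) {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines))
        return(CTSSSample(sampleID))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(nf < 4L | nf > 5L)
    if (length(bad))
        stop("malformed CTSS line ", lineno[bad[1L]], " in '", path,
             "': expected 4 or 5 tab-delimited fields")
    chrom <- vapply(parts, `[`, "", 1L)
    pos <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    strand <- vapply(parts, `[`, "", 3L)
    count <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 4L)))
    tpm <- suppressWarnings(as.numeric(vapply(parts, function(p)
        if (length(p) >= 5L) p[5L] else NA_character_, "")))
    bad <- which(is.na(pos) | pos < 1L | is.na(count) |
                 !(strand %in% c("+", "-")))
    if (length(bad))
        stop("malformed CTSS line ", lineno[bad[1L]], " in '", path,
             "': need pos >= 1, strand in {+,-} and a numeric count")
    if (any(count < 0))
        stop("malformed CTSS line ", lineno[which(count < 0)[1L]], " in '",
             path, "': negative count")
    CTSSSample(sampleID, chrom = chrom, pos = pos, strand = strand,
               count = count, tpm = tpm)
}

#' @param sample a [CTSSSample-class] to write.
#' @rdname readCTSS
#' @export
writeCTSS <- function(sample, path) {
    gr <- ctss(sample)
    hasTpm <- length(gr) && !all(is.na(gr$tpm))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# CTSS table for sample ", sampleID(sample)), con)
    if (length(gr)) {
        fields <- list(as.character(GenomicRanges::seqnames(gr)),
                       GenomicRanges::start(gr),
                       as.character(GenomicRanges::strand(gr)),
                       format(gr$count, trim = TRUE, scientific = FALSE))
        if (hasTpm)
            fields <- c(fields, list(format(gr$tpm, trim = TRUE,
                                            digits = 15)))
        writeLines(do.call(paste, c(fields, sep = "\t")), con)
    }
    invisible(path)
}

#' Merge replicate CTSS samples
#'
#' Produces the union of CTSS positions across replicates with raw tag
#' counts summed per position, so that total library depth is conserved.
#' Any normalized values are dropped (the merged sample is raw).
#'
#' @param samples a list of [CTSSSample-class] objects (at least one).
#' @param sampleID identifier of the merged sample.
#'
#' @return a [CTSSSample-class] whose library size is the sum of the inputs'.
#' @export
mergeReplicates <- function(samples,
                            sampleID = paste(vapply(samples, promdiv::sampleID,
                                                    ""), collapse = "+")) {
    if (!length(samples)) stop("need at least one sample to merge")
    stopifnot(all(vapply(samples, methods::is, TRUE, "CTSSSample")))
    if (length(samples) == 1L) {
        s <- samples[[1L]]
        return(CTSSSample(sampleID, ctss(s)))
    }
    grs <- lapply(samples, ctss)
    all <- suppressWarnings(do.call(c, unname(grs)))
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(all)),
                     pos = GenomicRanges::start(all),
                     strand = as.character(GenomicRanges::strand(all)),
                     count = all$count)
    agg <- stats::aggregate(count ~ chrom + pos + strand, data = df, FUN = sum)
    CTSSSample(sampleID, chrom = agg$chrom, pos = agg$pos,
               strand = agg$strand, count = agg$count)
}

#' Split a sample into two random halves
#'
#' Partitions the tag count at every CTSS by a fair binomial draw, emulating
#' an in-silico half-coverage split.  Counts are conserved exactly:
#' `half1 + half2 == total` at every position.
#'
#' @param sample a raw [CTSSSample-class].
#' @param seed integer seed; the split is reproducible for a fixed seed.
#'
#' @return a list of two [CTSSSample-class] objects named `half1`, `half2`
#'   (zero-count positions are dropped from each half).
#' @export
splitHalf <- function(sample, seed) {
    stopifnot(methods::is(sample, "CTSSSample"))
    gr <- ctss(sample)
    withSeed(seed, {
        k <- stats::rbinom(length(gr), size = as.integer(gr$count), prob = 0.5)
    })
    mk <- function(cnt, suffix) {
        keep <- cnt > 0
        g <- gr[keep]
        CTSSSample(paste0(sampleID(sample), suffix),
                   chrom = as.character(GenomicRanges::seqnames(g)),
                   pos = GenomicRanges::start(g),
                   strand = as.character(GenomicRanges::strand(g)),
                   count = cnt[keep])
    }
    list(half1 = mk(k, ".half1"), half2 = mk(gr$count - k, ".half2"))
}
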