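# parse a gene model (GTF/GFF3 path or GRanges) into transcript starts,
# transcript spans and exons, each carrying a gene_id
parseGeneModel <- function(geneModel) {
    gm <- if (methods::is(geneModel, "GRanges")) geneModel
          else tryCatch(rtracklayer::import(geneModel),
                        error = function(e)
                            stop("unparseable gene annotation '", geneModel,
                                 "': ", conditionMessage(e)))
    type <- as.character(gm$type)
    geneID <- if (!is.null(gm$gene_id)) as.character(gm$gene_id)
              else rep(NA_character_, length(gm))
    tx <- gm[type %in% c("transcript", "mRNA")]
    exons <- gm[type == "exon"]
    if (!length(tx) && length(exons)) {
        # derive transcript spans from exons grouped by transcript_id
        key <- if (!is.null(exons$transcript_id)) exons$transcript_id
               else exons$gene_id
        spl <- split(seq_along(exons), key)
        tx <- unlist(GenomicRanges::GRangesList(lapply(spl, function(i)
            GenomicRanges::reduce(GenomicRanges::granges(exons[i]),
                                  min.gapwidth = 1e9))))
        tx$gene_id <- vapply(spl, function(i)
            as.character(exons$gene_id[i[1L]]), "")
    }
    if (!length(tx))
        stop("gene model contains no transcript or exon features")
    txStart <- ifelse(as.character(GenomicRanges::strand(tx)) == "+",
                      GenomicRanges::start(tx), GenomicRanges::end(tx))
    list(tx = tx, exons = exons, txStart = txStart,
         txGene = if (!is.null(tx$gene_id)) as.character(tx$gene_id)
                  else rep(NA_character_, length(tx)))
}

#' Annotate consensus clusters against a gene model
#'
#' Each consensus cluster receives a single category with precedence
#' promoter > exon > intron > intergenic.  "Promoter" means the cluster
#' overlaps a window of +/- `promoterWindow` bp around any annotated
#' transcript start on the same strand; "exon"/"intron" require same-strand
#' overlap with an exon / a transcript body.  `geneID` is filled for
#' non-intergenic clusters from the first overlapping feature.
#'
#' @param cons a [ConsensusClusterSet-class].
#' @param geneModel GTF/GFF3 file path or an imported `GRanges` with `type`,
#'   `gene_id` (and ideally `transcript_id`) metadata.
#' @param promoterWindow promoter half-width in bp around annotated starts
#'   (default 500).
#'
#' @return the input with `annotation` and `geneID` metadata filled.
#' @export
annotateClusters <- function(cons, geneModel, promoterWindow = 500L) {
    stopifnot(methods::is(cons, "ConsensusClusterSet"))
    gm <- parseGeneModel(geneModel)
    cl <- clusters(cons)
    ann <- rep("intergenic", length(cl))
    gene <- rep(NA_character_, length(cl))

    promGR <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(gm$tx),
        IRanges::IRanges(pmax(1L, gm$txStart - promoterWindow),
                         gm$txStart + promoterWindow),
        strand = GenomicRanges::strand(gm$tx))
    assign1 <- function(featGR, featGene, label, current) {
        hits <- GenomicRanges::findOverlaps(cl, featGR, ignore.strand = FALSE)
        qi <- S4Vectors::queryHits(hits)
        new <- setdiff(unique(qi), which(current != "intergenic"))
        ann[new] <<- label
        first <- hits[!duplicated(qi)]
        gi <- S4Vectors::queryHits(first)
        keep <- gi %in% new
        gene[gi[keep]] <<- featGene[S4Vectors::subjectHits(first)[keep]]
        ann
    }
    ann <- assign1(promGR, gm$txGene, "promoter", ann)
    if (length(gm$exons)) {
        exonGene <- if (!is.null(gm$exons$gene_id))
            as.character(gm$exons$gene_id) else rep(NA_character_,
                                                    length(gm$exons))
        ann <- assign1(gm$exons, exonGene, "exon", ann)
    }
    ann <- assign1(gm$tx, gm$txGene, "intron", ann)

    cl$annotation <- ann
    cl$geneID <- gene
    methods::new("ConsensusClusterSet", clusters = cl,
                 sampleTotals = cons@sampleTotals,
                 sampleCounts = cons@sampleCounts,
                 profiles = cons@profiles)
}

#' Signed distance from a consensus cluster to the nearest annotated start
#'
#' For a promoter-annotated consensus cluster, the distance from its pooled
#' dominant position (signal summed over all samples) to the nearest
#' annotated transcript start on the same strand, oriented along the
#' strand: positive means the dominant TSS lies downstream (3') of the
#' annotated start, negative upstream.
#'
#' @param cons an annotated [ConsensusClusterSet-class].
#' @param geneModel as in [annotateClusters()].
#' @param id consensus cluster id.
#'
#' @return signed distance in bp.
#' @export
distanceToAnnotatedStart <- function(cons, geneModel, id) {
    cl <- clusters(cons)
    i <- match(id, cl$id)
    if (is.na(i)) stop("unknown consensus id '", id, "'")
    if (!identical(cl$annotation[i], "promoter"))
        stop("consensus cluster '", id, "' is not promoter-annotated")
    gm <- parseGeneModel(geneModel)
    prof <- groupProfile(cons, id, unique(cons@profiles$sample))
    dom <- dominantTSS(prof$pos, prof$tpm, prof$strand)
    same <- as.character(GenomicRanges::strand(gm$tx)) ==
        as.character(GenomicRanges::strand(cl[i])) &
        as.character(GenomicRanges::seqnames(gm$tx)) ==
        as.character(GenomicRanges::seqnames(cl[i]))
    if (!any(same)) stop("no same-strand annotated start on this chromosome")
    starts <- gm$txStart[same]
    nearest <- starts[which.min(abs(starts - dom$pos))]
    d <- dom$pos - nearest
    if (as.character(GenomicRanges::strand(cl[i])) == "-") d <- -d
    d
}
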