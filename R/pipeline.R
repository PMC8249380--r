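#' Full two-group comparison pipeline
#'
#' Runs the complete between-group workflow on raw CTSS samples:
#' replicate merging per group, power-law normalization to a common
#' reference, tag-cluster calling, consensus aggregation, optional
#' annotation (with optional restriction to promoter-annotated clusters),
#' and the comparative statistics battery (divergence profile, shifting
#' scores with the TPM-weighted KS test, dominant-TSS translocation
#' distances, Shannon diversity correlation).
#'
#' @param samplesA,samplesB lists of raw [CTSSSample-class] objects
#'   (replicates of each group; merged before TSS calling).
#' @param groupA,groupB group labels.
#' @param fitRange power-law fitting range (see [fitPowerLaw()]).
#' @param T normalization total (default 1e6 -> TPM).
#' @param maxDist,minTpm tag clustering parameters (see [clusterCTSS()]).
#' @param maxGap consensus aggregation distance (see
#'   [aggregateConsensus()]).
#' @param minTpmExpression expression filter for the comparative
#'   statistics (default 10 TPM).
#' @param scoreMin,fdr conventional detection filter on the shift table.
#' @param thresholds TPM levels of the divergence profile.
#' @param geneModel optional gene model for annotation (path or GRanges).
#' @param promoterOnly restrict comparative statistics to
#'   promoter-annotated consensus clusters (requires `geneModel`).
#'
#' @return a report list: `consensus` ([ConsensusClusterSet-class]),
#'   `normalization` (the reference), `divergence`, `shifts`,
#'   `shiftsDetected`, `dominantDistances`, `diversity`,
#'   `diversityCorrelation`, `funnel` (per-stage record counts) and
#'   `params`.
#' @export
compareGroups <- function(samplesA, samplesB,
                          groupA = "groupA", groupB = "groupB",
                          fitRange = c(5, 1000), T = 1e6,
                          maxDist = 20L, minTpm = 1, maxGap = 100L,
                          minTpmExpression = 10, scoreMin = 0.1,
                          fdr = 0.05,
                          thresholds = c(1, 2, 5, 10, 20, 50, 100),
                          geneModel = NULL, promoterOnly = FALSE) {
    if (methods::is(samplesA, "CTSSSample")) samplesA <- list(samplesA)
    if (methods::is(samplesB, "CTSSSample")) samplesB <- list(samplesB)
    mA <- mergeReplicates(samplesA, sampleID = groupA)
    mB <- mergeReplicates(samplesB, sampleID = groupB)
    fits <- list(fitPowerLaw(mA, fitRange), fitPowerLaw(mB, fitRange))
    ref <- makeReference(fits, T = T)
    nA <- normalizeSample(mA, ref, fit = fits[[1L]])
    nB <- normalizeSample(mB, ref, fit = fits[[2L]])
    tcA <- clusterCTSS(nA, maxDist = maxDist, minTpm = minTpm)
    tcB <- clusterCTSS(nB, maxDist = maxDist, minTpm = minTpm)
    sets <- stats::setNames(list(tcA, tcB), c(groupA, groupB))
    samp <- stats::setNames(list(nA, nB), c(groupA, groupB))
    cons <- aggregateConsensus(sets, samp, maxGap = maxGap)
    if (!is.null(geneModel))
        cons <- annotateClusters(cons, geneModel)
    consStats <- cons
    if (promoterOnly) {
        if (is.null(geneModel))
            stop("promoterOnly requires a geneModel")
        keep <- clusters(cons)$annotation == "promoter"
        consStats <- methods::new("ConsensusClusterSet",
            clusters = clusters(cons)[keep],
            sampleTotals = cons@sampleTotals[keep, , drop = FALSE],
            sampleCounts = cons@sampleCounts[keep, , drop = FALSE],
            profiles = cons@profiles[cons@profiles$id %in%
                                     clusters(cons)$id[keep], ,
                                     drop = FALSE])
    }
    div <- divergenceProfile(consStats, groupA, groupB,
                             thresholds = thresholds)
    shifts <- shiftTable(consStats, groupA, groupB,
                         minTpm = minTpmExpression)
    detected <- shifts[!is.na(shifts$score) & shifts$score > scoreMin &
                       shifts$fdr < fdr, , drop = FALSE]
    dd <- dominantDistance(consStats, groupA, groupB,
                           minTpm = minTpmExpression)
    dt <- diversityTable(consStats)
    dA <- stats::setNames(dt$shannon[dt$sample == groupA],
                          dt$id[dt$sample == groupA])
    dB <- stats::setNames(dt$shannon[dt$sample == groupB],
                          dt$id[dt$sample == groupB])
    dcor <- tryCatch(diversityCorrelation(dA, dB),
                     error = function(e) NA_real_)
    list(consensus = cons,
         normalization = ref,
         divergence = div,
         shifts = shifts,
         shiftsDetected = detected,
         dominantDistances = dd,
         diversity = dt,
         diversityCorrelation = dcor,
         funnel = c(rawA = librarySize(mA), rawB = librarySize(mB),
                    ctssA = length(mA), ctssB = length(mB),
                    tagClustersA = length(tcA), tagClustersB = length(tcB),
                    consensus = length(cons),
                    tested = nrow(shifts), detected = nrow(detected)),
         params = list(fitRange = fitRange, T = T, maxDist = maxDist,
                       minTpm = minTpm, maxGap = maxGap,
                       minTpmExpression = minTpmExpression,
                       scoreMin = scoreMin, fdr = fdr,
                       promoterOnly = promoterOnly))
}

#' Run a scenario-style analysis from a configuration list
#'
#' Dispatches the scenario comparisons on a single configuration object:
#'
#' * `between_groups`, `within_replicates`, `developmental` - two-group
#'   comparison via [compareGroups()]; the three scenarios share machinery
#'   and differ in what the groups mean (subspecies, biological
#'   replicates, developmental stages);
#' * `switching` - crossover TSS switching via [runSwitchAnalysis()] on
#'   `config$expr`;
#' * `multi_tissue` - all pairwise two-group comparisons across
#'   `config$tissues` (a named list of sample lists).
#'
#' All pipeline stages are deterministic, so rerunning a configuration
#' reproduces the report exactly.
#'
#' @param config a list with `scenario` plus the fields the scenario
#'   needs: `samplesA`/`samplesB` (+ optional `groupA`, `groupB`,
#'   `geneModel`, `promoterOnly`, thresholds) for the comparison
#'   scenarios; `expr` (+ optional `minTpm`, `pThreshold`) for
#'   `switching`; `tissues` for `multi_tissue`.
#'
#' @return the scenario report (see [compareGroups()] /
#'   [runSwitchAnalysis()]); `multi_tissue` returns a named list of
#'   pairwise reports.
#' @export
runScenario <- function(config) {
    scenario <- match.arg(config$scenario,
                          c("between_groups", "within_replicates",
                            "developmental", "switching", "multi_tissue"))
    arg <- function(name, default) {
        if (!is.null(config[[name]])) config[[name]] else default
    }
    if (scenario %in% c("between_groups", "within_replicates",
                        "developmental")) {
        if (is.null(config$samplesA) || is.null(config$samplesB))
            stop("scenario '", scenario,
                 "' needs samplesA and samplesB")
        return(compareGroups(
            config$samplesA, config$samplesB,
            groupA = arg("groupA", "groupA"),
            groupB = arg("groupB", "groupB"),
            fitRange = arg("fitRange", c(5, 1000)),
            T = arg("T", 1e6),
            maxDist = arg("maxDist", 20L),
            minTpm = arg("minTpm", 1),
            maxGap = arg("maxGap", 100L),
            minTpmExpression = arg("minTpmExpression", 10),
            scoreMin = arg("scoreMin", 0.1),
            fdr = arg("fdr", 0.05),
            thresholds = arg("thresholds", c(1, 2, 5, 10, 20, 50, 100)),
            geneModel = config$geneModel,
            promoterOnly = arg("promoterOnly", FALSE)))
    }
    if (scenario == "switching") {
        if (is.null(config$expr)) stop("scenario 'switching' needs expr")
        return(runSwitchAnalysis(config$expr,
                                 minTpm = arg("minTpm", 1),
                                 pThreshold = arg("pThreshold", 0.01)))
    }
    # multi_tissue: pairwise comparisons
    tissues <- config$tissues
    if (is.null(tissues) || is.null(names(tissues)) || length(tissues) < 2L)
        stop("scenario 'multi_tissue' needs a named list of >= 2 tissues")
    out <- list()
    nm <- names(tissues)
    for (i in seq_len(length(nm) - 1L)) {
        for (j in seq(i + 1L, length(nm))) {
            key <- paste(nm[i], nm[j], sep = "_vs_")
            out[[key]] <- compareGroups(tissues[[i]], tissues[[j]],
                                        groupA = nm[i], groupB = nm[j],
                                        geneModel = config$geneModel,
                                        promoterOnly = arg("promoterOnly",
                                                           FALSE))
        }
    }
    out
}
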