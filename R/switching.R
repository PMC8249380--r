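#' Select candidate genes for TSS switching analysis
#'
#' Candidates are genes with at least `minClusters` consensus TSS clusters
#' each expressed at `minTpm` or more in every individual replicate (both
#' stages).  When more than `minClusters` clusters qualify, the two with
#' the highest mean expression form the design (`allPairs = TRUE` instead
#' returns every qualifying pair).
#'
#' @param expr data.frame with columns `gene`, `cluster`, `stage`,
#'   `replicate`, `tpm` (one row per cluster x stage x replicate).
#' @param minTpm per-replicate expression floor (default 1 TPM).
#' @param minClusters minimum qualifying clusters per gene (default 2).
#' @param allPairs test all pairs of qualifying clusters instead of the
#'   top 2 by mean expression.
#'
#' @return named list of design data.frames (columns as `expr`, two
#'   clusters each); empty list when nothing qualifies.
#' @export
selectCandidates <- function(expr, minTpm = 1, minClusters = 2L,
                             allPairs = FALSE) {
    stopifnot(all(c("gene", "cluster", "stage", "replicate", "tpm") %in%
                  names(expr)))
    out <- list()
    byGene <- split(expr, expr$gene)
    for (g in unique(expr$gene)) {
        d <- byGene[[as.character(g)]]
        minByCluster <- tapply(d$tpm, d$cluster, min)
        ok <- names(minByCluster)[minByCluster >= minTpm]
        if (length(ok) < minClusters) next
        if (allPairs) {
            pairs <- utils::combn(ok, 2L, simplify = FALSE)
        } else {
            means <- tapply(d$tpm[d$cluster %in% ok],
                            d$cluster[d$cluster %in% ok], mean)
            pairs <- list(names(sort(means, decreasing = TRUE))[1:2])
        }
        for (p in pairs) {
            key <- if (length(pairs) > 1L) paste0(g, ":", paste(p, collapse = "|"))
                   else as.character(g)
            out[[key]] <- d[d$cluster %in% p, , drop = FALSE]
        }
    }
    out
}

#' Fit the TSS-by-stage interaction model for one gene
#'
#' Ordinary least squares of per-replicate expression on two 0/1-coded
#' factors and their interaction:
#' `Y = alpha + beta1*TSS + beta2*stage + beta3*TSS*stage`.
#' The interaction p-value is the two-sided t-test on `beta3`; a gene is a
#' switching candidate when it falls below `pThreshold` (default 0.01).
#' Expression is modeled on the TPM scale by default; `log2p1 = TRUE`
#' applies `log2(Y + 1)` for variance stabilization.
#'
#' @param design a design data.frame from [selectCandidates()] (exactly two
#'   clusters, two stages, replicated observations).
#' @param pThreshold candidate threshold on the interaction p-value.
#' @param log2p1 model `log2(tpm + 1)` instead of raw TPM.
#'
#' @return list with `alpha`, `beta1`, `beta2`, `beta3`, `pInteraction`,
#'   `candidate`, plus the per-(cluster, stage) mean expression matrix
#'   `cellMeans` (clusters x stages).
#' @export
fitSwitchModel <- function(design, pThreshold = 0.01, log2p1 = FALSE) {
    cl <- sort(unique(design$cluster))
    st <- sort(unique(design$stage))
    if (length(cl) != 2L || length(st) != 2L)
        stop("design must contain exactly two clusters and two stages")
    y <- if (log2p1) log2(design$tpm + 1) else design$tpm
    tssF <- as.numeric(design$cluster == cl[2L])
    stageF <- as.numeric(design$stage == st[2L])
    if (nrow(design) < 5L)
        stop("singular design: need replication (>= 5 observations ",
             "for a 1-df error term)")
    fit <- stats::lm(y ~ tssF * stageF)
    sm <- suppressWarnings(summary(fit))
    cf <- sm$coefficients
    if (nrow(cf) < 4L || stats::df.residual(fit) < 1L)
        stop("singular design: interaction not estimable")
    cellMeans <- tapply(y, list(design$cluster, design$stage), mean)
    pInt <- cf["tssF:stageF", "Pr(>|t|)"]
    # an (essentially) perfect fit has no residual evidence to test against
    if (is.nan(pInt) ||
        sm$sigma < 1e-10 * (mean(abs(y)) + 1)) pInt <- 1
    list(alpha = unname(cf["(Intercept)", "Estimate"]),
         beta1 = unname(cf["tssF", "Estimate"]),
         beta2 = unname(cf["stageF", "Estimate"]),
         beta3 = unname(cf["tssF:stageF", "Estimate"]),
         pInteraction = pInt,
         candidate = pInt < pThreshold,
         cellMeans = cellMeans)
}

#' Classify a crossover switching event
#'
#' A crossover event requires the dominant cluster (by mean expression) to
#' differ between the two stages *and* a significant interaction
#' (candidate flag from [fitSwitchModel()]).  Parallel profiles are never
#' crossover, however significant the interaction.
#'
#' @param fit result of [fitSwitchModel()].
#' @return logical.
#' @export
classifyCrossover <- function(fit) {
    cm <- fit$cellMeans
    reversal <- (cm[1L, 1L] > cm[2L, 1L]) != (cm[1L, 2L] > cm[2L, 2L])
    isTRUE(reversal && fit$candidate)
}

#' Overall FDR for switching (or any per-locus) detections
#'
#' The l*P/d estimate: `nTested * pThreshold / nDetected`.
#'
#' @param nTested number of genes (loci) tested.
#' @param pThreshold significance level of the individual tests.
#' @param nDetected number of detections.
#' @return the FDR estimate; `NA` with a warning when `nDetected` is 0.
#' @export
switchFdr <- function(nTested, pThreshold, nDetected) {
    stopifnot(nTested > 0, pThreshold > 0, pThreshold < 1, nDetected >= 0)
    if (nDetected == 0) {
        warning("no detections; FDR undefined")
        return(NA_real_)
    }
    nTested * pThreshold / nDetected
}

#' Run the full crossover switching analysis
#'
#' Candidate selection, per-gene interaction fits, crossover
#' classification and the overall l*P/d FDR.
#'
#' @inheritParams selectCandidates
#' @inheritParams fitSwitchModel
#'
#' @return list with `table` (per-gene data.frame: gene, clusters, betas,
#'   pInteraction, crossover), `nTested`, `nCrossover`, `fdr`.
#' @export
runSwitchAnalysis <- function(expr, minTpm = 1, pThreshold = 0.01,
                              log2p1 = FALSE) {
    designs <- selectCandidates(expr, minTpm = minTpm)
    rows <- lapply(names(designs), function(g) {
        fit <- fitSwitchModel(designs[[g]], pThreshold = pThreshold,
                              log2p1 = log2p1)
        data.frame(gene = g,
                   clusters = paste(sort(unique(designs[[g]]$cluster)),
                                    collapse = "|"),
                   beta1 = fit$beta1, beta2 = fit$beta2, beta3 = fit$beta3,
                   pInteraction = fit$pInteraction,
                   crossover = classifyCrossover(fit))
    })
    tab <- if (length(rows)) do.call(rbind, rows)
           else data.frame(gene = character(), clusters = character(),
                           beta1 = numeric(), beta2 = numeric(),
                           beta3 = numeric(), pInteraction = numeric(),
                           crossover = logical())
    nCross <- sum(tab$crossover)
    fdr <- if (nrow(tab) && nCross > 0)
        switchFdr(nrow(tab), pThreshold, nCross) else NA_real_
    list(table = tab, nTested = nrow(tab), nCrossover = nCross, fdr = fdr)
}
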