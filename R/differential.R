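#' Shannon index of TSS diversity
#'
#' `-sum(Pi * ln(Pi))` over positions with positive signal, where `Pi` is
#' the proportion of the cluster's CAGE signal at the i-th TSS (natural
#' log).  Zero when a single dominant TSS carries all signal; `ln(S)` for
#' signal spread evenly over `S` TSSs.
#'
#' @param tpm signal per position (non-negative, positive total).
#' @return non-negative real.
#' @examples
#' shannonIndex(c(10, 0, 0))        # 0
#' shannonIndex(rep(2, 4))          # log(4)
#' @export
shannonIndex <- function(tpm) {
    if (any(tpm < 0)) stop("signal must be non-negative")
    total <- sum(tpm)
    if (total <= 0) stop("zero total signal")
    p <- tpm[tpm > 0] / total
    -sum(p * log(p))
}

#' Promoter shifting score between two signal profiles
#'
#' `score = max(F1 - F2) / max(F1)`, where `F1` is the cumulative CAGE
#' signal along the consensus cluster in the profile with the lower total
#' signal and `F2` in the other.  The score is computed in both the forward
#' (5'->3') and the reverse (3'->5') direction and the larger value is
#' returned with its direction.  It measures the fraction of the
#' lower-signal profile's transcription initiated outside the region used
#' by the other profile: identical profiles score 0, disjoint equal-total
#' profiles score 1; the score may be negative and is reported unclamped.
#'
#' @param a,b data.frames with columns `pos`, `tpm` describing the two
#'   profiles over the same consensus span.
#' @param strand "+" or "-" (defines the 5'->3' direction).
#'
#' @return list with `score`, `direction` ("forward"/"reverse"), `totalA`,
#'   `totalB`.  If the lower-total profile has no signal at all the score
#'   is `NA` (such clusters are divergent, not shifted).
#' @export
shiftingScore <- function(a, b, strand = "+") {
    stopifnotStrand(strand)
    al <- alignProfiles(a, b, strand)
    Ta <- sum(al$a); Tb <- sum(al$b)
    if (Ta <= 0 && Tb <= 0) stop("both profiles have zero total signal")
    if (min(Ta, Tb) <= 0)
        return(list(score = NA_real_, direction = NA_character_,
                    totalA = Ta, totalB = Tb))
    if (Ta <= Tb) { f1 <- al$a; f2 <- al$b; T1 <- Ta }
    else          { f1 <- al$b; f2 <- al$a; T1 <- Tb }
    fwd <- max(cumsum(f1) - cumsum(f2)) / T1
    rev <- max(cumsum(base::rev(f1)) - cumsum(base::rev(f2))) / T1
    if (fwd >= rev) list(score = fwd, direction = "forward",
                         totalA = Ta, totalB = Tb)
    else list(score = rev, direction = "reverse", totalA = Ta, totalB = Tb)
}

# align two (pos, tpm) profiles on the union of positions, 5'->3'
alignProfiles <- function(a, b, strand) {
    pos <- sort(unique(c(a$pos, b$pos)), decreasing = identical(strand, "-"))
    va <- numeric(length(pos)); vb <- numeric(length(pos))
    va[match(a$pos, pos)] <- a$tpm
    vb[match(b$pos, pos)] <- b$tpm
    list(pos = pos, a = va, b = vb)
}

#' TPM-weighted two-sample Kolmogorov-Smirnov test on signal profiles
#'
#' `D` is the maximal absolute difference between the two normalized
#' cumulative signal curves over the shared positions.  The p-value comes
#' from the asymptotic two-sample Kolmogorov distribution with effective
#' sample sizes equal to the rounded TPM totals of the two profiles,
#' `nEff = nA * nB / (nA + nB)`, so deeper-supported clusters are weighted
#' more.
#'
#' @inheritParams shiftingScore
#' @return list with `D` and `p`.
#' @export
ksProfileTest <- function(a, b, strand = "+") {
    al <- alignProfiles(a, b, strand)
    Ta <- sum(al$a); Tb <- sum(al$b)
    if (Ta <= 0 || Tb <= 0) stop("both profiles need positive total signal")
    D <- max(abs(cumsum(al$a) / Ta - cumsum(al$b) / Tb))
    nA <- max(1, round(Ta)); nB <- max(1, round(Tb))
    nEff <- nA * nB / (nA + nB)
    list(D = D, p = kolmogorovQ(sqrt(nEff) * D))
}

# upper tail of the Kolmogorov distribution, Q(z) = P(sup|B(t)| > z)
kolmogorovQ <- function(z) {
    if (z < 1e-8) return(1)
    if (z < 1) {
        # theta-function form, accurate for small z
        k <- seq_len(20L)
        p <- 1 - sqrt(2 * pi) / z * sum(exp(-(2 * k - 1)^2 * pi^2 /
                                            (8 * z^2)))
    } else {
        k <- seq_len(100L)
        p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * z^2))
    }
    min(max(p, 0), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate adjustment (wraps
#' [stats::p.adjust()] after validating the input range).
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values in `[0, 1]`.
#' @export
bhFdr <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Differential TSS usage between two sample groups
#'
#' Computes, for every consensus cluster with signal in both groups, the
#' shifting score (forward/reverse) and the TPM-weighted KS test, with BH
#' adjustment across all tested clusters.  The conventional detection filter
#' is `fdr < 0.05 & score > scoreMin`.
#'
#' @param cons a [ConsensusClusterSet-class].
#' @param groupA,groupB character vectors of sample names defining the two
#'   groups (profiles are summed within each group).
#' @param minTpm optional minimum group-total TPM (in the higher group) for
#'   a cluster to be tested; default 0 tests every cluster with signal in
#'   both groups.
#'
#' @return data.frame with columns `id`, `totalA`, `totalB`, `score`,
#'   `direction`, `ksD`, `p`, `fdr`.
#' @export
shiftTable <- function(cons, groupA, groupB, minTpm = 0) {
    checkGroups(cons, groupA, groupB)
    tot <- sampleTotals(cons)
    tA <- rowSums(tot[, groupA, drop = FALSE])
    tB <- rowSums(tot[, groupB, drop = FALSE])
    test <- tA > 0 & tB > 0 & pmax(tA, tB) >= minTpm
    ids <- clusters(cons)$id[test]
    strands <- as.character(GenomicRanges::strand(clusters(cons)))[test]
    pr <- cons@profiles
    prA <- pr[pr$sample %in% groupA, , drop = FALSE]
    prB <- pr[pr$sample %in% groupB, , drop = FALSE]
    spA <- split(prA[c("pos", "tpm")], prA$id)
    spB <- split(prB[c("pos", "tpm")], prB$id)
    res <- lapply(seq_along(ids), function(k) {
        a <- poolProfile(spA[[ids[k]]])
        b <- poolProfile(spB[[ids[k]]])
        sh <- shiftingScore(a, b, strands[k])
        ks <- ksProfileTest(a, b, strands[k])
        data.frame(id = ids[k], totalA = sh$totalA, totalB = sh$totalB,
                   score = sh$score, direction = sh$direction,
                   ksD = ks$D, p = ks$p)
    })
    out <- if (length(res)) do.call(rbind, res)
           else data.frame(id = character(), totalA = numeric(),
                           totalB = numeric(), score = numeric(),
                           direction = character(), ksD = numeric(),
                           p = numeric())
    out$fdr <- if (nrow(out)) bhFdr(out$p) else numeric()
    out
}

# sum tpm of a per-sample profile chunk over positions
poolProfile <- function(d) {
    if (is.null(d) || !nrow(d))
        return(data.frame(pos = integer(), tpm = numeric()))
    v <- tapply(d$tpm, d$pos, sum)
    data.frame(pos = as.integer(names(v)), tpm = as.numeric(v))
}

checkGroups <- function(cons, groupA, groupB) {
    known <- colnames(sampleTotals(cons))
    bad <- setdiff(c(groupA, groupB), known)
    if (length(bad))
        stop("unknown sample group members: ", paste(bad, collapse = ", "))
    invisible(TRUE)
}

#' Divergent-cluster profile across expression thresholds
#'
#' A consensus cluster is "expressed" at threshold `t` when the larger of
#' the two group TPM totals reaches `t`, and "divergent" when additionally
#' the other group shows no signal at all in the span (zero raw tags by
#' default; set `mode = "belowTpm"` with `detectTpm` to use a detection
#' threshold on normalized signal instead).
#'
#' @inheritParams shiftTable
#' @param thresholds ascending positive TPM levels.
#' @param mode divergence definition, `"zeroRaw"` (default) or
#'   `"belowTpm"`.
#' @param detectTpm detection bound used by `mode = "belowTpm"`.
#'
#' @return data.frame with one row per threshold: `threshold`,
#'   `nExpressed`, `nOnlyA`, `nOnlyB`, `nDivergent`, `proportion`.
#' @export
divergenceProfile <- function(cons, groupA, groupB,
                              thresholds = c(1, 2, 5, 10, 20, 50, 100),
                              mode = c("zeroRaw", "belowTpm"),
                              detectTpm = 1) {
    mode <- match.arg(mode)
    checkGroups(cons, groupA, groupB)
    stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
    tot <- sampleTotals(cons)
    cnt <- sampleCounts(cons)
    tA <- rowSums(tot[, groupA, drop = FALSE])
    tB <- rowSums(tot[, groupB, drop = FALSE])
    if (mode == "zeroRaw") {
        absentA <- rowSums(cnt[, groupA, drop = FALSE]) == 0
        absentB <- rowSums(cnt[, groupB, drop = FALSE]) == 0
    } else {
        absentA <- tA < detectTpm
        absentB <- tB < detectTpm
    }
    do.call(rbind, lapply(thresholds, function(t) {
        expressed <- pmax(tA, tB) >= t
        onlyA <- expressed & absentB & !absentA
        onlyB <- expressed & absentA & !absentB
        data.frame(threshold = t, nExpressed = sum(expressed),
                   nOnlyA = sum(onlyA), nOnlyB = sum(onlyB),
                   nDivergent = sum(onlyA | onlyB),
                   proportion = if (sum(expressed))
                       sum(onlyA | onlyB) / sum(expressed) else NA_real_)
    }))
}

#' Dominant-TSS translocation distances between two groups
#'
#' For every consensus cluster passing the expression filter (default: at
#' least 10 TPM in both groups; `require = "either"` relaxes this), the
#' strand-oriented distance between the two groups' dominant positions:
#' positive means group B's dominant TSS lies 3' of group A's.
#'
#' @inheritParams shiftTable
#' @param minTpm expression filter on group totals (default 10).
#' @param require `"both"` (default) or `"either"` group must pass
#'   `minTpm`.
#'
#' @return data.frame with `id`, `domA`, `domB`, `distance`.
#' @export
dominantDistance <- function(cons, groupA, groupB, minTpm = 10,
                             require = c("both", "either")) {
    require <- match.arg(require)
    checkGroups(cons, groupA, groupB)
    tot <- sampleTotals(cons)
    tA <- rowSums(tot[, groupA, drop = FALSE])
    tB <- rowSums(tot[, groupB, drop = FALSE])
    keep <- if (require == "both") tA >= minTpm & tB >= minTpm
            else (tA >= minTpm | tB >= minTpm) & tA > 0 & tB > 0
    cl <- clusters(cons)
    ids <- cl$id[keep]
    strands <- as.character(GenomicRanges::strand(cl))[keep]
    pr <- cons@profiles
    prA <- pr[pr$sample %in% groupA, , drop = FALSE]
    prB <- pr[pr$sample %in% groupB, , drop = FALSE]
    spA <- split(prA[c("pos", "tpm")], prA$id)
    spB <- split(prB[c("pos", "tpm")], prB$id)
    res <- lapply(seq_along(ids), function(k) {
        a <- poolProfile(spA[[ids[k]]])
        b <- poolProfile(spB[[ids[k]]])
        dA <- dominantTSS(a$pos, a$tpm, strands[k])$pos
        dB <- dominantTSS(b$pos, b$tpm, strands[k])$pos
        d <- if (strands[k] == "-") dA - dB else dB - dA
        data.frame(id = ids[k], domA = dA, domB = dB, distance = d)
    })
    if (length(res)) do.call(rbind, res)
    else data.frame(id = character(), domA = integer(), domB = integer(),
                    distance = integer())
}

#' Per-cluster, per-sample Shannon diversity
#'
#' @param cons a [ConsensusClusterSet-class].
#' @return data.frame with `id`, `sample`, `S` (number of contributing
#'   CTSSs) and `shannon` (NA where a sample has no signal in the span).
#' @export
diversityTable <- function(cons) {
    pr <- cons@profiles
    samples <- colnames(sampleTotals(cons))
    ids <- clusters(cons)$id
    grid <- expand.grid(id = ids, sample = samples,
                        stringsAsFactors = FALSE)
    key <- paste(pr$id, pr$sample)
    spl <- split(pr$tpm, key)
    grid$S <- NA_integer_
    grid$shannon <- NA_real_
    gkey <- paste(grid$id, grid$sample)
    hit <- match(gkey, names(spl))
    for (i in which(!is.na(hit))) {
        v <- spl[[hit[i]]]
        v <- v[v > 0]
        if (length(v)) {
            grid$S[i] <- length(v)
            grid$shannon[i] <- shannonIndex(v)
        }
    }
    grid
}

#' Pearson correlation of TSS diversity between two samples or groups
#'
#' @param divA,divB named numeric vectors of per-cluster Shannon indices
#'   (names = consensus ids); only clusters with a defined index in both
#'   are used (at least 3 required).
#' @return Pearson correlation coefficient.
#' @export
diversityCorrelation <- function(divA, divB) {
    shared <- intersect(names(divA)[is.finite(divA)],
                        names(divB)[is.finite(divB)])
    if (length(shared) < 3L)
        stop("need at least 3 shared clusters with defined diversity")
    a <- divA[shared]; b <- divB[shared]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("zero variance in a diversity vector; correlation undefined")
        return(NA_real_)
    }
    stats::cor(a, b)
}
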