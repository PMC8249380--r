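# internal helpers

# evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never perturb user code
withSeed <- function(seed, expr) {
    if (is.null(seed)) stop("a seed is required for reproducibility")
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
    eval.parent(substitute(expr))
}

# order positions 5'->3' along the strand
fivePrimeOrder <- function(pos, strand) {
    if (identical(strand, "-")) order(pos, decreasing = TRUE) else order(pos)
}

stopifnotStrand <- function(strand) {
    if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
}
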