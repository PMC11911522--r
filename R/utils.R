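# Internal helpers shared across the package.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never disturb the
# session RNG.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# n Dirichlet(alpha) draws as a length(alpha) x n matrix (columns sum to 1).
rdirichlet <- function(n, alpha) {
    K <- length(alpha)
    g <- matrix(stats::rgamma(n * K, shape = alpha), nrow = K)
    sweep(g, 2L, colSums(g), "/")
}

# Derive a bounded child seed from a master seed and a stream label, so one
# top-level seed drives every stage RNG independently.
childSeed <- function(seed, stream) {
    (as.integer(seed) * 1103L + as.integer(stream) * 12289L) %% 2147483647L
}

# log(sum(exp(x))) without overflow.
logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}
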