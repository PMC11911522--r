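# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# Small SpatialExpression with the given matrix.
seFrom <- function(values, ...) {
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
    SpatialExpression(values, ...)
}

# Exact noiseless factorization Y = M0 H0 with column-stochastic H0.
noiselessFactorization <- function(L = 60, S = 30, K = 3, seed = 42) {
    set.seed(seed)
    M0 <- matrix(stats::rexp(L * K, rate = 1 / 5), L, K)
    H0 <- prop.table(matrix(stats::rexp(K * S), K, S), 2)
    dimnames(M0) <- list(sprintf("g%03d", seq_len(L)), paste0("t", seq_len(K)))
    dimnames(H0) <- list(paste0("t", seq_len(K)), sprintf("s%03d", seq_len(S)))
    list(M = M0, H = H0, Y = M0 %*% H0)
}

# Noiseless point cloud in an ambient space: N points that are convex
# combinations of K vertices, with the vertices themselves among the
# points (rows 1..K).
simplexCloud <- function(K = 3, N = 200, ambient = 8, seed = 3) {
    set.seed(seed)
    V <- matrix(stats::runif(K * ambient), K, ambient)
    Wint <- prop.table(matrix(stats::rexp(K * (N - K)), K, N - K), 2)
    W <- cbind(diag(K), Wint)
    pts <- t(W) %*% V
    rownames(pts) <- sprintf("p%03d", seq_len(N))
    list(vertices = V, weights = W, points = pts)
}

# Max vertex coordinate error after brute-force permutation alignment.
alignedVertexError <- function(est, truth) {
    K <- nrow(truth)
    perms <- simplexDeconv:::permutationsOf(K)
    min(vapply(perms, function(p)
        max(abs(est[p, , drop = FALSE] - truth)), numeric(1)))
}

# Default simulated dataset used by several integration tests.
simFixture <- function(seed, K = 4, L = 1000, spotsPerRegion = 80,
                       hetRate = 0.3) {
    ref <- makeReference(K = K, L = L, seed = seed)
    sim <- simulateSpots(ref, nRegions = 3, spotsPerRegion = spotsPerRegion,
                         hetRate = hetRate, seed = seed)
    list(ref = ref, sim = sim)
}
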