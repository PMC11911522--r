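#' @useDynLib simplexDeconv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Non-negative least squares with multiple right-hand sides
#'
#' Solves `min ||A x - b||^2` subject to `x >= 0` for every column `b` of
#' `B`, by an active-set method on the shared normal equations (the
#' fast-combinatorial formulation: the Gram matrix `A'A` is computed once).
#'
#' @param A m x k design matrix.
#' @param B m x n matrix of right-hand sides.
#' @return k x n matrix of non-negative solutions.
#' @export
nnlsSolve <- function(A, B) {
    A <- as.matrix(A)
    B <- as.matrix(B)
    stopifnot(nrow(A) == nrow(B))
    X <- .nnlsMulti(A, B)
    dimnames(X) <- list(colnames(A), colnames(B))
    X
}

#' Alternating constrained least-squares factorization
#'
#' Factors a non-negative expression matrix as `Y ~ M H` with non-negative
#' profiles `M` (genes x types) and non-negative column-stochastic
#' proportions `H` (types x spots). Each iteration solves `M` by exact
#' row-wise NNLS given `H`, then solves the columns of `H` by NNLS with a
#' sum-to-one constraint and renormalizes exactly. Iteration stops when the
#' iteration count reaches `maxIter` or `||Y - M H||_F <= tolA`.
#'
#' `H` is initialized with Dirichlet(1) columns drawn under `seed`; given
#' the same data and seed the result is reproducible bit for bit.
#'
#' @param Y a [SpatialExpression-class] or genes x spots matrix.
#' @param K number of cell types, `1 <= K < S`.
#' @param maxIter iteration cap (default 1000).
#' @param tolA absolute Frobenius-error exit threshold; default
#'   `1e-6 * ||Y||_F`.
#' @param seed integer seed for the initialization.
#' @param sumWeight relative weight of the sum-to-one row in the H-update.
#' @param sumToOne constrain the columns of `H` to the probability simplex
#'   (the default). `FALSE` fits plain non-negative `H`, the
#'   parameterization whose free-parameter count matches the model-order
#'   criterion; the returned `H` is then column-renormalized only for the
#'   class contract, with the unnormalized fit kept for the error.
#' @return a [FactorPair-class].
#' @examples
#' set.seed(1)
#' M0 <- matrix(rexp(60 * 3), 60, 3)
#' H0 <- prop.table(matrix(rexp(3 * 20), 3, 20), 2)
#' fit <- deconf(M0 %*% H0, K = 3, seed = 1)
#' fit@frobErr / norm(M0 %*% H0, "F")
#' @export
deconf <- function(Y, K, maxIter = 1000L, tolA = NULL, seed = 1L,
                   sumWeight = 10, sumToOne = TRUE) {
    v <- if (methods::is(Y, "SpatialExpression")) exprValues(Y) else as.matrix(Y)
    S <- ncol(v)
    if (K < 1L) stop("K must be at least 1")
    if (K >= S) stop("K must be smaller than the number of spots (", S, ")")
    if (is.null(tolA)) tolA <- 1e-6 * norm(v, "F")
    H0 <- withSeed(seed, rdirichlet(S, rep(1, K)))  # K x S
    res <- .deconfCore(v, H0, as.integer(maxIter), tolA, sumWeight,
                       isTRUE(sumToOne))
    M <- res$M
    H <- res$H
    if (!isTRUE(sumToOne)) {
        # fold the column scales into M-direction-free form for the class
        # contract; frobErr still reflects the unconstrained fit
        cs <- colSums(H)
        cs[cs <= 0] <- 1
        H <- sweep(H, 2L, cs, "/")
    }
    dimnames(M) <- list(rownames(v), paste0("type", seq_len(K)))
    dimnames(H) <- list(paste0("type", seq_len(K)), colnames(v))
    if (res$nReinit > 0)
        message("deconf: reinitialized ", res$nReinit,
                " collapsed rows/columns during the fit")
    methods::new("FactorPair", M = M, H = H, nIter = as.integer(res$nIter),
                 frobErr = res$frobErr, errTrace = res$errTrace,
                 converged = res$converged)
}

setMethod("proportions", "FactorPair", function(x, ...) x@H)
setMethod("profiles", "FactorPair", function(x, ...) x@M)

setMethod("show", "FactorPair", function(object) {
    cat(sprintf(
        "FactorPair: %d genes x %d types x %d spots; %d iterations, ",
        nrow(object@M), ncol(object@M), ncol(object@H), object@nIter))
    cat(sprintf("||Y-MH||F = %.4g (%s)\n", object@frobErr,
                if (object@converged) "converged" else "iteration cap"))
})
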