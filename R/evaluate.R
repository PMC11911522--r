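#' Align estimated cell types to true cell types
#'
#' Reference-free outputs carry arbitrary type order; this finds the
#' bijection between estimated and true proportion rows that maximizes the
#' sum of per-pair Pearson correlations. For K up to 8 the optimum is found
#' by exhaustive permutation search; beyond that a greedy best-pair scheme
#' is used.
#'
#' @param PEst,PTrue K x S proportion matrices of equal shape.
#' @return integer permutation `p` such that `PEst[p, ]` is aligned with
#'   `PTrue` row-for-row.
#' @export
alignTypes <- function(PEst, PTrue) {
    PEst <- as.matrix(PEst)
    PTrue <- as.matrix(PTrue)
    if (!all(dim(PEst) == dim(PTrue)))
        stop("PEst and PTrue must have identical dimensions")
    K <- nrow(PEst)
    cm <- suppressWarnings(stats::cor(t(PTrue), t(PEst)))  # true x est
    cm[!is.finite(cm)] <- 0
    if (K <= 8L) {
        perms <- permutationsOf(K)
        scores <- vapply(perms, function(p)
            sum(cm[cbind(seq_len(K), p)]), numeric(1))
        perm <- perms[[which.max(scores)]]
    } else {
        perm <- integer(K)
        work <- cm
        for (i in seq_len(K)) {
            ij <- which(work == max(work), arr.ind = TRUE)[1L, ]
            perm[ij[1L]] <- ij[2L]
            work[ij[1L], ] <- -Inf
            work[, ij[2L]] <- -Inf
        }
    }
    perm
}

# All permutations of 1..n as a list (n small).
permutationsOf <- function(n) {
    if (n == 1L) return(list(1L))
    sub <- permutationsOf(n - 1L)
    out <- vector("list", n * length(sub))
    i <- 0L
    for (p in sub)
        for (pos in seq_len(n)) {
            i <- i + 1L
            out[[i]] <- append(p, n, after = pos - 1L)
        }
    out
}

# Jensen-Shannon divergence between two probability vectors, natural log,
# with the 0 log 0 := 0 convention. Bounded by ln 2.
jsdVec <- function(p, q, base = exp(1)) {
    m <- (p + q) / 2
    kl <- function(a) {
        nz <- a > 0
        sum(a[nz] * log(a[nz] / m[nz]))
    }
    (kl(p) / 2 + kl(q) / 2) / log(base)
}

#' Proportion-recovery metrics
#'
#' Computes, over aligned K x S proportion matrices: the mean absolute
#' error `sum |Phat - P| / (S K)`, the root mean square error
#' `sqrt(sum (Phat - P)^2 / (S K))`, the mean per-spot Jensen-Shannon
#' divergence between proportion columns (natural log), and the Pearson
#' correlation of the flattened matrices. Per-type correlations are also
#' reported.
#'
#' @param PEst,PTrue K x S proportion matrices; columns are renormalized
#'   with a warning when they deviate from unit sums by more than 1e-6.
#' @param aligned set `TRUE` when `PEst` rows already correspond to
#'   `PTrue` rows; otherwise [alignTypes()] is applied first.
#' @param base logarithm base for the JSD (default natural).
#' @return an [EvalReport-class].
#' @examples
#' P <- prop.table(matrix(rexp(3 * 10), 3, 10), 2)
#' proportionMetrics(P[c(2, 3, 1), ], P)@mae
#' @export
proportionMetrics <- function(PEst, PTrue, aligned = FALSE,
                              base = exp(1)) {
    PEst <- as.matrix(PEst)
    PTrue <- as.matrix(PTrue)
    if (!all(dim(PEst) == dim(PTrue)))
        stop("PEst and PTrue must have identical dimensions")
    fix <- function(P, nm) {
        cs <- colSums(P)
        if (any(abs(cs - 1) > 1e-6)) {
            warning(nm, " columns deviate from unit sums; renormalizing")
            P <- sweep(P, 2L, cs, "/")
        }
        P
    }
    PEst <- fix(PEst, "PEst")
    PTrue <- fix(PTrue, "PTrue")
    K <- nrow(PEst)
    S <- ncol(PEst)
    perm <- if (aligned) seq_len(K) else alignTypes(PEst, PTrue)
    Pe <- PEst[perm, , drop = FALSE]
    d <- Pe - PTrue
    mae <- sum(abs(d)) / (S * K)
    rmse <- sqrt(sum(d^2) / (S * K))
    perSpot <- vapply(seq_len(S), function(j)
        jsdVec(Pe[, j], PTrue[, j], base = base), numeric(1))
    pcc <- suppressWarnings(stats::cor(as.vector(Pe), as.vector(PTrue)))
    perType <- vapply(seq_len(K), function(k)
        suppressWarnings(stats::cor(Pe[k, ], PTrue[k, ])), numeric(1))
    if (!is.finite(pcc)) pcc <- 0
    methods::new("EvalReport", rmse = rmse, mae = mae,
                 jsd = mean(perSpot), pcc = pcc,
                 perTypePcc = perType, permutation = as.integer(perm),
                 perSpotJsd = perSpot)
}

setMethod("show", "EvalReport", function(object) {
    cat(sprintf(
        "EvalReport: RMSE %.4f  MAE %.4f  JSD %.4f  PCC %.4f\n",
        object@rmse, object@mae, object@jsd, object@pcc))
})
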