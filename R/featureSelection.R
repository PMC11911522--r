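#' Initial feature list by coefficient of variation
#'
#' Ranks genes by their coefficient of variation (sd/mean across spots,
#' computed on the filtered, non-log values) and returns the top `nInit`.
#' Genes with zero mean cannot be ranked and are excluded; ties are broken
#' by lexicographic gene id, so the result is deterministic.
#'
#' @param Y a [SpatialExpression-class] or genes x spots matrix.
#' @param nInit number of genes to return (default 1000).
#' @return character vector of gene ids, in decreasing CV order.
#' @export
initialFeatures <- function(Y, nInit = 1000L) {
    v <- if (methods::is(Y, "SpatialExpression")) exprValues(Y) else as.matrix(Y)
    if (nInit > nrow(v))
        stop("nInit must not exceed the number of genes (", nrow(v), ")")
    mu <- rowMeans(v)
    ok <- mu > 0
    if (!all(ok))
        message("initialFeatures: excluded ", sum(!ok), " zero-mean genes")
    cv <- apply(v[ok, , drop = FALSE], 1L, stats::sd) / mu[ok]
    ids <- rownames(v)[ok]
    ord <- order(-cv, ids)
    ids[ord][seq_len(min(nInit, length(ids)))]
}

#' Cell-type-specific features from estimated proportions
#'
#' Cross-cell-type differential analysis driven purely by the estimated
#' proportion matrix: each gene's spot vector is projected onto `H` by
#' NNLS, giving a per-type expression estimate; type `k`'s score for the
#' gene is the one-vs-rest contrast (estimate in `k` minus the maximum over
#' the other types) standardized by the NNLS residual scale. The top
#' `perType` genes per type are returned; lists may overlap.
#'
#' @param Y a [SpatialExpression-class] or genes x spots matrix.
#' @param H K x S column-stochastic proportion matrix.
#' @param perType genes to keep per cell type (default 100).
#' @return list of K character vectors of gene ids, by descending score.
#' @export
celltypeSpecificFeatures <- function(Y, H, perType = 100L) {
    v <- if (methods::is(Y, "SpatialExpression")) exprValues(Y) else as.matrix(Y)
    H <- as.matrix(H)
    K <- nrow(H)
    S <- ncol(H)
    stopifnot(ncol(v) == S)
    if (qr(t(H))$rank < K)
        stop("H is numerically rank-deficient; the estimated types are not ",
             "separable - try a smaller K or more spots")
    Mhat <- t(nnlsSolve(t(H), t(v)))            # L x K per-type estimates
    resid <- v - Mhat %*% H
    scale <- sqrt(rowSums(resid^2) / S) + 1e-8
    ids <- rownames(v)
    out <- vector("list", K)
    for (k in seq_len(K)) {
        contrast <- (Mhat[, k] -
            apply(Mhat[, -k, drop = FALSE], 1L, max)) / scale
        ord <- order(-contrast, ids)
        out[[k]] <- ids[ord][seq_len(min(perType, length(ids)))]
    }
    names(out) <- rownames(H)
    out
}

# Round-robin union of the per-type lists, capped strictly below `cap`:
# take rank-1 genes of every type, then rank-2, ..., skipping duplicates.
roundRobinUnion <- function(lists, cap = 1000L) {
    depth <- max(lengths(lists))
    seen <- character(0)
    for (r in seq_len(depth)) {
        for (l in lists) {
            if (r <= length(l) && !(l[[r]] %in% seen)) {
                seen <- c(seen, l[[r]])
                if (length(seen) >= cap - 1L) return(seen)
            }
        }
    }
    seen
}

#' Iterative cell-type-specific gene selection
#'
#' Alternates reference-free factorization and proportion-driven gene
#' re-selection: starting from the top-CV gene list, each outer iteration
#' fits [deconf()] on the current genes, recomputes the per-type specific
#' gene lists from the estimated proportions, and replaces the gene list
#' with their round-robin union (kept strictly below 1000 genes). The loop
#' stops when the reconstruction RMSE `||Y - MH||_F / sqrt(L'S)` changes by
#' at most `rmseTol` between successive iterations, or at `maxOuter`.
#'
#' @param Y a [SpatialExpression-class] or genes x spots matrix (filtered,
#'   non-log values).
#' @param K number of cell types.
#' @param nInit size of the initial CV-ranked list.
#' @param perType genes per type at each re-selection.
#' @param rmseTol absolute RMSE-change tolerance (default 1e-4).
#' @param maxOuter outer-iteration cap (default 20).
#' @param maxIter inner [deconf()] iteration cap per outer iteration.
#' @param seed integer seed driving all inner initializations.
#' @return a [FeatureSelectionResult-class].
#' @export
iterateSelection <- function(Y, K, nInit = 1000L, perType = 100L,
                             rmseTol = 1e-4, maxOuter = 20L,
                             maxIter = 300L, seed = 1L) {
    v <- if (methods::is(Y, "SpatialExpression")) exprValues(Y) else as.matrix(Y)
    S <- ncol(v)
    if (K >= S) stop("K must be smaller than the number of spots")
    genes <- initialFeatures(v, min(nInit, nrow(v)))
    rmseTrace <- numeric(0)
    perTypeGenes <- NULL
    fit <- NULL
    converged <- FALSE
    for (it in seq_len(maxOuter)) {
        vr <- v[genes, , drop = FALSE]
        fit <- deconf(vr, K, maxIter = maxIter,
                      seed = childSeed(seed, it))
        rmse <- fit@frobErr / sqrt(length(vr))
        rmseTrace <- c(rmseTrace, rmse)
        perTypeGenes <- celltypeSpecificFeatures(vr, fit@H, perType)
        if (any(lengths(perTypeGenes) == 0L))
            stop("empty per-type gene list at outer iteration ", it)
        if (it > 1L && abs(rmseTrace[it] - rmseTrace[it - 1L]) <= rmseTol) {
            converged <- TRUE
            break
        }
        if (it < maxOuter) genes <- roundRobinUnion(perTypeGenes)
    }
    methods::new("FeatureSelectionResult", genes = genes,
                 perTypeGenes = perTypeGenes, rmseTrace = rmseTrace,
                 nOuterIter = length(rmseTrace), converged = converged,
                 finalFactors = fit)
}

setMethod("selectedGenes", "FeatureSelectionResult", function(x) x@genes)

setMethod("show", "FeatureSelectionResult", function(object) {
    cat(sprintf(
        "FeatureSelectionResult: %d genes after %d outer iterations (%s)\n",
        length(object@genes), object@nOuterIter,
        if (object@converged) "RMSE converged" else "iteration cap"))
    cat("  RMSE trace:", paste(signif(object@rmseTrace, 4), collapse = " "),
        "\n")
})
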