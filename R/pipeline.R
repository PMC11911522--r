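#' Corner rescaling coefficients
#'
#' The recovered corners `Hp` are simplex vertices of the row-normalized
#' data and do not, in general, have unit column sums. The coefficients
#' `alpha` are the least-squares solution of `alpha' Hp = 1'`, so that
#' `diag(alpha) Hp` becomes (approximately) column-stochastic.
#'
#' @param Hp K x S pseudo-proportion matrix (corner rows).
#' @return numeric length-K `alpha`, with attribute `"residual"` holding
#'   the fit residual norm.
#' @export
solveAlpha <- function(Hp) {
    Hp <- as.matrix(Hp)
    K <- nrow(Hp)
    qrh <- qr(t(Hp))
    if (qrh$rank < K)
        stop("Hp is rank-deficient; corners are degenerate")
    ones <- rep(1, ncol(Hp))
    alpha <- qr.coef(qrh, ones)
    structure(as.numeric(alpha),
              residual = sqrt(sum((crossprod(Hp, alpha) - ones)^2)),
              names = rownames(Hp))
}

#' Rescale pseudo-proportions into a column-stochastic matrix
#'
#' Computes `H[k, j] = alpha[k] * Hp[k, j]`, clips negative entries (soft
#' non-negativity artifacts of the corner fit) to zero, and renormalizes
#' every column to sum exactly one. The clipped negative mass is reported
#' in the `"clippedMass"` attribute (per column, before renormalization).
#'
#' @param Hp K x S pseudo-proportion matrix.
#' @param alpha length-K coefficients from [solveAlpha()].
#' @return K x S column-stochastic matrix with attribute `"clippedMass"`.
#' @export
rescaleH <- function(Hp, alpha) {
    Hp <- as.matrix(Hp)
    stopifnot(length(alpha) == nrow(Hp), all(is.finite(alpha)))
    H <- alpha * Hp
    clipped <- colSums(pmax(-H, 0))
    H[H < 0] <- 0
    cs <- colSums(H)
    if (any(cs <= 0))
        stop("spot '", colnames(Hp)[which(cs <= 0)[1L]],
             "': simplex does not cover this spot (all-non-positive column)")
    H <- sweep(H, 2L, cs, "/")
    attr(H, "clippedMass") <- clipped
    H
}

#' Profile matrix by row-wise non-negative least squares
#'
#' Given the proportion matrix, each gene's profile row solves
#' `min ||Y[i, ] - m H||^2` over `m >= 0`. All rows share the Gram matrix
#' `H H'`, the fast-combinatorial formulation.
#'
#' @param Y a [SpatialExpression-class] or L' x S matrix over the selected
#'   genes.
#' @param H K x S column-stochastic proportion matrix of rank K.
#' @return L' x K non-negative profile matrix.
#' @export
estimateM <- function(Y, H) {
    v <- if (methods::is(Y, "SpatialExpression")) exprValues(Y) else as.matrix(Y)
    H <- as.matrix(H)
    stopifnot(ncol(v) == ncol(H))
    if (qr(t(H))$rank < nrow(H))
        stop("H is rank-deficient; cannot estimate profiles")
    M <- t(nnlsSolve(t(H), t(v)))
    dimnames(M) <- list(rownames(v), rownames(H))
    M
}

#' Rank marker genes by corner proximity
#'
#' For every corner, genes are sorted by ascending Euclidean distance
#' between their projected coordinates and the corner's projected
#' coordinates; the closest `G` are that cell type's markers. Ties are
#' broken by gene id.
#'
#' @param projected N x (K-1) projected gene coordinates (rownames = gene
#'   ids).
#' @param vertices a [SimplexVertices-class] from the same projection.
#' @param G markers per corner (default 50).
#' @return list of K character vectors of gene ids.
#' @export
rankMarkers <- function(projected, vertices, G = 50L) {
    stopifnot(methods::is(vertices, "SimplexVertices"))
    projected <- as.matrix(projected)
    ids <- rownames(projected)
    if (is.null(ids)) stop("projected gene coordinates need rownames")
    if (G > nrow(projected)) {
        warning("G exceeds the number of genes; returning all genes")
        G <- nrow(projected)
    }
    pv <- vertices@projectedVertices
    out <- lapply(seq_len(nrow(pv)), function(k) {
        d <- sqrt(colSums((t(projected) - pv[k, ])^2))
        ids[order(d, ids)][seq_len(G)]
    })
    names(out) <- rownames(pv)
    out
}

#' Reference-free deconvolution of spatial transcriptomics
#'
#' The full pipeline: detection-fraction gene filtering, optional AIC-based
#' selection of the number of cell types, iterative cell-type-specific gene
#' selection, row normalization, minimum-volume simplex corner
#' identification on genes-as-points, rescaling of the recovered corners
#' into a column-stochastic proportion matrix, row-wise NNLS recovery of
#' the profile matrix, and corner-proximity marker ranking.
#'
#' Row normalization makes every gene row a convex combination of the K
#' normalized proportion rows, so the corners recovered in the spot space
#' are the pseudo-proportion rows themselves; rescaling them by `alpha`
#' yields the column-stochastic `H`.
#'
#' @param Y a raw-count [SpatialExpression-class].
#' @param K integer number of cell types, or `"auto"` to select it by AIC
#'   over `kMin:kMax`.
#' @param config a [deconvControl()] list of tuning parameters.
#' @param seed integer master seed; all stage RNGs derive from it.
#' @return a [DeconvResult-class].
#' @examples
#' ref <- makeReference(K = 3, L = 400, seed = 7)
#' sim <- simulateSpots(ref, nRegions = 3, spotsPerRegion = 15, seed = 7)
#' res <- simplexDeconvolve(sim@Y, K = 3, seed = 7)
#' round(proportions(res)[, 1:3], 3)
#' @export
simplexDeconvolve <- function(Y, K = "auto", config = deconvControl(),
                              seed = 1L) {
    stopifnot(methods::is(Y, "SpatialExpression"))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
    }
    Yf <- stage("filter", filterGenes(Y, config$minFrac, config$maxFrac))
    vK <- exprValues(Yf)                    # AIC stage: unscaled values
    if (config$useLog) {
        Yf <- stage("lognorm", logNormalize(Yf, config$logScale))
    } else if (config$libScale) {
        Yf <- stage("library-scale", scaleLibrary(Yf))
    }
    v <- exprValues(Yf)
    S <- ncol(v)

    ks <- NULL
    if (identical(K, "auto")) {
        ks <- stage("select-k", selectK(
            vK, kMin = config$kMin, kMax = config$kMax, reps = config$reps,
            nInit = config$kInit, maxIter = config$maxIter,
            seed = childSeed(seed, 1L)))
        K <- ks@bestK
    }
    K <- as.integer(K)
    if (K >= S) stop("stage 'select-k': K must be smaller than the number of spots")

    fs <- stage("feature-selection", iterateSelection(
        v, K, nInit = config$nInit, perType = config$perType,
        rmseTol = config$rmseTol, maxOuter = config$maxOuter,
        maxIter = config$maxIter, seed = childSeed(seed, 2L)))
    vr <- v[fs@genes, , drop = FALSE]
    if (nrow(vr) <= S)
        warning("fewer selected genes (", nrow(vr), ") than spots (", S,
                "); the simplex geometry may be unstable")

    nm <- stage("row-normalize", rowNormalize(vr))
    pr <- stage("affine-project", affineProject(nm@values, K))
    sv <- stage("sisal", sisalFit(pr, K, tau = config$tau,
                                  maxIter = config$sisalIter,
                                  seed = childSeed(seed, 3L)))
    Hp <- sv@vertices                       # corner rows = pseudo-proportions
    rownames(Hp) <- paste0("type", seq_len(K))
    colnames(Hp) <- colnames(vr)
    alpha <- stage("alpha", solveAlpha(Hp))
    H <- stage("rescale", rescaleH(Hp, alpha))
    M <- stage("profiles", estimateM(vr, H))
    marks <- stage("markers", rankMarkers(pr@projected, sv,
                                          G = min(config$gMarkers, nrow(vr))))
    names(marks) <- rownames(Hp)
    rmse <- norm(vr - M %*% H, "F") / sqrt(length(vr))
    diag_ <- list(rmse = rmse,
                  clippedMass = attr(H, "clippedMass"),
                  alphaResidual = attr(alpha, "residual"),
                  seed = as.integer(seed),
                  rmseTrace = fs@rmseTrace,
                  kSelection = ks)
    attr(H, "clippedMass") <- NULL
    methods::new("DeconvResult", H = H, M = M,
                 alpha = as.numeric(alpha), markers = marks,
                 selectedGenes = fs@genes, K = K, corners = sv,
                 projection = pr, diagnostics = diag_)
}

#' Tuning parameters for [simplexDeconvolve()]
#'
#' @param minFrac,maxFrac strict detection-fraction gene-filter bounds.
#' @param useLog run the factorization on log-normalized values instead of
#'   the raw scale. Default `FALSE`: the mixing model is linear in raw
#'   expression.
#' @param libScale scale spot columns to a common library size before the
#'   factorization (linear scale only). Keeps the column-stochastic model
#'   consistent across spots with different cell counts.
#' @param logScale library-size target when `useLog = TRUE`.
#' @param kMin,kMax candidate range for `K = "auto"`.
#' @param reps seeded restarts per K candidate.
#' @param kInit gene subset size for the AIC stage (`NULL`: all filtered
#'   genes).
#' @param nInit initial CV-ranked gene list size for feature selection.
#' @param perType genes per type in each re-selection round.
#' @param gMarkers markers reported per corner.
#' @param tau hinge weight of the corner fit.
#' @param sisalIter outer iteration cap of the corner fit.
#' @param rmseTol feature-selection RMSE convergence tolerance.
#' @param maxOuter feature-selection outer iteration cap.
#' @param maxIter inner factorization iteration cap.
#' @return named list of parameters.
#' @export
deconvControl <- function(minFrac = 0.05, maxFrac = 1.0, useLog = FALSE,
                          libScale = TRUE,
                          logScale = 1e4, kMin = 2L, kMax = 8L, reps = 1L,
                          kInit = NULL,
                          nInit = 1000L, perType = 100L, gMarkers = 50L,
                          tau = 1.0, sisalIter = 100L, rmseTol = 1e-4,
                          maxOuter = 20L, maxIter = 300L) {
    as.list(environment())
}

setMethod("proportions", "DeconvResult", function(x, ...) x@H)
setMethod("profiles", "DeconvResult", function(x, ...) x@M)
setMethod("markers", "DeconvResult", function(x, ...) x@markers)
setMethod("selectedGenes", "DeconvResult", function(x) x@selectedGenes)

setMethod("show", "DeconvResult", function(object) {
    cat(sprintf(
        "DeconvResult: %d cell types x %d spots over %d selected genes\n",
        object@K, ncol(object@H), length(object@selectedGenes)))
    cat(sprintf("  reconstruction RMSE %.4g; clipped negative mass %.4g\n",
                object@diagnostics$rmse,
                sum(object@diagnostics$clippedMass)))
})
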