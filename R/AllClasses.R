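#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

#' Spatial expression container
#'
#' A genes-by-spots expression matrix with gene/spot identifiers, optional
#' spot coordinates and a log-normalization flag. Extends
#' \linkS4class{SummarizedExperiment}: the single assay holds the values,
#' spot coordinates live in \code{colData} columns \code{x}/\code{y}, and the
#' log-normalization state is kept in \code{metadata(x)$isLogNormalized}.
#'
#' Validity requires a non-negative, NA-free assay and unique, non-empty
#' gene and spot identifiers.
#'
#' @seealso [SpatialExpression()] for construction, [logNormalize()],
#'   [filterGenes()], [rowNormalize()].
#' @export
setClass("SpatialExpression", contains = "SummarizedExperiment")

setValidity("SpatialExpression", function(object) {
    if (length(SummarizedExperiment::assays(object)) < 1L)
        return("exactly one assay with the expression values is required")
    v <- SummarizedExperiment::assay(object, 1L)
    if (anyNA(v))
        return("expression values must not contain NA (fill missing with 0)")
    if (any(v < 0)) {
        bad <- which(v < 0, arr.ind = TRUE)[1L, ]
        return(sprintf("negative expression value at gene row %d, spot column %d",
                       bad[1L], bad[2L]))
    }
    gid <- rownames(object)
    sid <- colnames(object)
    if (is.null(gid) || is.null(sid))
        return("gene and spot identifiers are required as dimnames")
    if (anyDuplicated(gid))
        return(sprintf("duplicate gene id: %s", gid[duplicated(gid)][1L]))
    if (anyDuplicated(sid))
        return(sprintf("duplicate spot id: %s", sid[duplicated(sid)][1L]))
    TRUE
})

#' Row-normalized expression matrix
#'
#' Holds the row-stochastic matrix Y~ with y~_ij = y_ij / sum_s y_is together
#' with the original row sums, so that \code{diag(rowScale) \%*\% values}
#' reconstructs the input exactly.
#'
#' @slot values numeric matrix, each row summing to 1.
#' @slot rowScale positive numeric vector of original row sums.
#' @export
setClass("NormalizedMatrix",
    representation(values = "matrix", rowScale = "numeric"))

setValidity("NormalizedMatrix", function(object) {
    if (nrow(object@values) != length(object@rowScale))
        return("rowScale length must equal the number of rows")
    if (any(object@rowScale <= 0))
        return("rowScale entries must be positive")
    rs <- rowSums(object@values)
    if (any(abs(rs - 1) > 1e-10))
        return("every row must sum to 1 within 1e-10")
    TRUE
})

#' Constrained factorization result
#'
#' The output of [deconf()]: profiles `M` (genes x types, non-negative) and
#' proportions `H` (types x spots, non-negative, column-stochastic), with the
#' Frobenius error trace of the alternating solver.
#'
#' @slot M non-negative numeric matrix, genes x types.
#' @slot H non-negative column-stochastic matrix, types x spots.
#' @slot nIter number of alternating iterations performed.
#' @slot frobErr final Frobenius norm of `Y - M H`.
#' @slot errTrace per-iteration Frobenius errors.
#' @slot converged TRUE when the error tolerance was reached before the
#'   iteration cap.
#' @export
setClass("FactorPair",
    representation(M = "matrix", H = "matrix", nIter = "integer",
                   frobErr = "numeric", errTrace = "numeric",
                   converged = "logical"))

setValidity("FactorPair", function(object) {
    if (ncol(object@M) != nrow(object@H))
        return("inner dimensions of M and H must agree")
    if (any(object@M < 0) || any(object@H < 0))
        return("M and H must be non-negative")
    cs <- colSums(object@H)
    if (any(abs(cs - 1) > 1e-8))
        return("every column of H must sum to 1 within 1e-8")
    TRUE
})

#' Affine subspace projection
#'
#' Orthonormal basis of the (K-1)-dimensional affine subspace spanned by
#' centered data points, with the data mean as origin. Supports projecting
#' new points and lifting projected coordinates back to ambient space.
#'
#' @slot basis (K-1) x S matrix with orthonormal rows.
#' @slot center length-S numeric, the data mean.
#' @slot projected N x (K-1) projected coordinates of the fitted points.
#' @export
setClass("AffineProjection",
    representation(basis = "matrix", center = "numeric",
                   projected = "matrix"))

setValidity("AffineProjection", function(object) {
    if (ncol(object@basis) != length(object@center))
        return("basis column count must match center length")
    g <- tcrossprod(object@basis)
    if (max(abs(g - diag(nrow(object@basis)))) > 1e-8)
        return("basis rows must be orthonormal within 1e-8")
    TRUE
})

#' Recovered simplex corners
#'
#' The K vertices of the minimum-volume simplex fitted by [sisalFit()],
#' both in the projected (K-1)-dimensional coordinates and lifted back to
#' the ambient space of the input points.
#'
#' @slot vertices K x S matrix of corners in ambient coordinates.
#' @slot projectedVertices K x (K-1) corners in projected coordinates.
#' @slot Q K x K inverse mixing matrix in augmented projected coordinates.
#' @slot tau hinge (soft non-negativity) weight used.
#' @slot nIter accepted outer iterations.
#' @slot objectiveTrace objective value per accepted outer iteration.
#' @export
setClass("SimplexVertices",
    representation(vertices = "matrix", projectedVertices = "matrix",
                   Q = "matrix", tau = "numeric", nIter = "integer",
                   objectiveTrace = "numeric"))

setValidity("SimplexVertices", function(object) {
    K <- nrow(object@projectedVertices)
    if (ncol(object@projectedVertices) != K - 1L)
        return("projectedVertices must be K x (K-1)")
    if (nrow(object@vertices) != K)
        return("vertices must have K rows")
    d <- det(cbind(object@projectedVertices, 1))
    if (!is.finite(d) || d == 0)
        return("recovered simplex is degenerate (zero volume)")
    TRUE
})

#' Cell-type number selection
#'
#' AIC curve over candidate numbers of cell types and its argmin.
#'
#' @slot kGrid integer candidates.
#' @slot aicValues corrected AIC per candidate.
#' @slot ssrValues residual sum of squares per candidate.
#' @slot bestK candidate with the smallest AIC (ties broken to smaller K).
#' @export
setClass("KSelection",
    representation(kGrid = "integer", aicValues = "numeric",
                   ssrValues = "numeric", bestK = "integer"))

setValidity("KSelection", function(object) {
    n <- length(object@kGrid)
    if (length(object@aicValues) != n || length(object@ssrValues) != n)
        return("kGrid, aicValues and ssrValues must have equal length")
    finite <- is.finite(object@aicValues)
    if (!any(finite)) return("no finite AIC value")
    best <- object@kGrid[finite][which.min(object@aicValues[finite])]
    if (object@bestK != best)
        return("bestK must be the kGrid entry with the smallest AIC")
    TRUE
})

#' Iterative cell-type-specific gene selection result
#'
#' @slot genes selected gene ids (always fewer than 1000).
#' @slot perTypeGenes list of K cell-type-specific gene id vectors.
#' @slot rmseTrace reconstruction RMSE per outer iteration.
#' @slot nOuterIter outer iterations performed.
#' @slot converged TRUE when successive RMSEs differed by at most the
#'   tolerance.
#' @slot finalFactors the [FactorPair] from the last outer iteration.
#' @export
setClass("FeatureSelectionResult",
    representation(genes = "character", perTypeGenes = "list",
                   rmseTrace = "numeric", nOuterIter = "integer",
                   converged = "logical", finalFactors = "FactorPair"))

setValidity("FeatureSelectionResult", function(object) {
    if (length(object@genes) >= 1000L)
        return("selected gene list must stay below 1000 genes")
    if (anyDuplicated(object@genes))
        return("selected gene list must not contain duplicates")
    TRUE
})

#' Deconvolution result
#'
#' Full output of [simplexDeconvolve()]: column-stochastic proportions `H`,
#' non-negative profiles `M` over the selected genes, the corner rescaling
#' coefficients `alpha`, ranked per-type marker genes, and fit diagnostics.
#'
#' @slot H K x S column-stochastic proportion matrix.
#' @slot M L' x K non-negative profile matrix over the selected genes.
#' @slot alpha length-K rescaling coefficients for the recovered corners.
#' @slot markers list of K ranked marker gene id vectors.
#' @slot selectedGenes gene ids the deconvolution ran on.
#' @slot K number of cell types.
#' @slot corners the fitted [SimplexVertices].
#' @slot projection the [AffineProjection] of the normalized gene points.
#' @slot diagnostics list: reconstruction RMSE, clipped negative mass,
#'   seed, selection trace.
#' @export
setClass("DeconvResult",
    representation(H = "matrix", M = "matrix", alpha = "numeric",
                   markers = "list", selectedGenes = "character",
                   K = "integer", corners = "SimplexVertices",
                   projection = "AffineProjection", diagnostics = "list"))

setValidity("DeconvResult", function(object) {
    if (nrow(object@H) != object@K)
        return("H must have K rows")
    if (any(object@H < 0) || any(object@M < 0))
        return("H and M must be non-negative")
    if (any(abs(colSums(object@H) - 1) > 1e-8))
        return("columns of H must sum to 1 within 1e-8")
    if (!all(unlist(object@markers) %in% object@selectedGenes))
        return("marker genes must be a subset of the selected genes")
    TRUE
})

#' Synthetic single-cell reference
#'
#' Per-type mean expression profiles with planted exclusive marker blocks,
#' used by [simulateSpots()] to draw single cells.
#'
#' @slot meanProfiles L x K non-negative matrix of per-type means.
#' @slot typeNames K cell-type names.
#' @slot dispersion negative-binomial overdispersion of per-cell counts.
#' @slot cellsPerType nominal cells available per type (bookkeeping only).
#' @slot markerGenes list of K vectors with each type's planted marker ids.
#' @export
setClass("SyntheticReference",
    representation(meanProfiles = "matrix", typeNames = "character",
                   dispersion = "numeric", cellsPerType = "integer",
                   markerGenes = "list"))

setValidity("SyntheticReference", function(object) {
    M <- object@meanProfiles
    if (ncol(M) != length(object@typeNames))
        return("typeNames length must equal the number of profile columns")
    if (any(M < 0)) return("mean profiles must be non-negative")
    if (any(colSums(M > 0) == 0))
        return("every type needs at least one expressed gene")
    for (k in seq_len(ncol(M))) {
        mk <- object@markerGenes[[k]]
        if (length(mk) < 5L)
            return("every type needs at least 5 marker genes")
        other <- M[mk, -k, drop = FALSE]
        if (any(M[mk, k] < 3 * apply(other, 1L, max)))
            return("marker means must be at least 3x the mean in every other type")
    }
    TRUE
})

#' Simulated spatial dataset with ground truth
#'
#' @slot Y the simulated [SpatialExpression] (raw counts).
#' @slot PTrue K x S column-stochastic true proportion matrix (realized
#'   cell-count fractions).
#' @slot regionOfSpot integer region index per spot.
#' @slot dominantTypeOfRegion integer dominant type per region.
#' @slot heterogeneityMask TRUE for spots without an enforced dominant type.
#' @slot seed the seed the dataset was generated under.
#' @export
setClass("SyntheticTruth",
    representation(Y = "SpatialExpression", PTrue = "matrix",
                   regionOfSpot = "integer", dominantTypeOfRegion = "integer",
                   heterogeneityMask = "logical", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    S <- ncol(object@Y)
    if (ncol(object@PTrue) != S)
        return("PTrue must have one column per spot")
    if (any(object@PTrue < 0))
        return("true proportions must be non-negative")
    if (any(abs(colSums(object@PTrue) - 1) > 1e-10))
        return("every PTrue column must sum to 1 within 1e-10")
    if (length(object@regionOfSpot) != S ||
        length(object@heterogeneityMask) != S)
        return("per-spot annotations must have one entry per spot")
    hom <- which(!object@heterogeneityMask)
    if (length(hom)) {
        dom <- object@dominantTypeOfRegion[object@regionOfSpot[hom]]
        am <- apply(object@PTrue[, hom, drop = FALSE], 2L, which.max)
        if (any(am != dom))
            return("non-heterogeneous spots must be dominated by their region's type")
    }
    TRUE
})

#' Cell-type label assignment
#'
#' Mapping from anonymous estimated cell types to reference type names,
#' with the composite similarity (mean of Pearson correlation and
#' Naive-Bayes posterior) behind each assignment.
#'
#' @slot mapping named character: estimated type -> reference name or
#'   \code{"unassigned"}.
#' @slot scores K x R composite similarity matrix.
#' @slot pearson K x R Pearson correlations.
#' @slot posterior K x R Naive-Bayes posteriors.
#' @slot threshold minimum composite score for an assignment.
#' @export
setClass("LabelAssignment",
    representation(mapping = "character", scores = "matrix",
                   pearson = "matrix", posterior = "matrix",
                   threshold = "numeric"))

setValidity("LabelAssignment", function(object) {
    used <- object@mapping[object@mapping != "unassigned"]
    if (anyDuplicated(used))
        return("each reference type may be used at most once")
    if (any(object@pearson < -1 - 1e-9 | object@pearson > 1 + 1e-9))
        return("pearson scores must lie in [-1, 1]")
    if (any(object@posterior < -1e-9 | object@posterior > 1 + 1e-9))
        return("posterior scores must lie in [0, 1]")
    TRUE
})

#' Proportion-recovery evaluation report
#'
#' RMSE, MAE, mean Jensen-Shannon divergence (natural log) and Pearson
#' correlation between an estimated and a true proportion matrix, after
#' cell-type alignment.
#'
#' @slot rmse root mean square error over all S*K entries.
#' @slot mae mean absolute error over all S*K entries.
#' @slot jsd mean per-spot Jensen-Shannon divergence (natural log).
#' @slot pcc Pearson correlation of the flattened aligned matrices.
#' @slot perTypePcc per-type Pearson correlations across spots.
#' @slot permutation alignment applied to the estimated rows.
#' @slot perSpotJsd per-spot Jensen-Shannon divergences.
#' @export
setClass("EvalReport",
    representation(rmse = "numeric", mae = "numeric", jsd = "numeric",
                   pcc = "numeric", perTypePcc = "numeric",
                   permutation = "integer", perSpotJsd = "numeric"))

setValidity("EvalReport", function(object) {
    if (object@mae < 0 || object@rmse < 0)
        return("mae and rmse must be non-negative")
    if (any(object@perSpotJsd < -1e-12 | object@perSpotJsd > log(2) + 1e-9))
        return("per-spot JSD must lie in [0, ln 2]")
    if (!all(sort(object@permutation) == seq_along(object@permutation)))
        return("permutation must be a bijection")
    TRUE
})
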