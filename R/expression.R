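#' Construct a SpatialExpression object
#'
#' @param values genes x spots non-negative numeric matrix. `NA` entries are
#'   treated as missing and filled with zeros.
#' @param geneIds unique gene identifiers (defaults to `rownames(values)`).
#' @param spotIds unique spot identifiers (defaults to `colnames(values)`).
#' @param coords optional S x 2 matrix/data.frame of spatial x/y coordinates.
#' @param isLogNormalized whether the values are already log-normalized.
#' @return a [SpatialExpression-class] object.
#' @examples
#' y <- SpatialExpression(matrix(rpois(12, 5), 4, 3,
#'     dimnames = list(paste0("g", 1:4), paste0("s", 1:3))))
#' dim(y)
#' @export
SpatialExpression <- function(values, geneIds = rownames(values),
                              spotIds = colnames(values), coords = NULL,
                              isLogNormalized = FALSE) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(geneIds))
        geneIds <- paste0("gene", seq_len(nrow(values)))
    if (is.null(spotIds))
        spotIds <- paste0("spot", seq_len(ncol(values)))
    values[is.na(values)] <- 0
    dimnames(values) <- list(as.character(geneIds), as.character(spotIds))
    cd <- S4Vectors::DataFrame(row.names = spotIds)
    if (!is.null(coords)) {
        coords <- as.matrix(coords)
        if (nrow(coords) != ncol(values) || ncol(coords) != 2L)
            stop("coords must be an S x 2 matrix of spot coordinates")
        cd$x <- as.numeric(coords[, 1L])
        cd$y <- as.numeric(coords[, 2L])
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expression = values), colData = cd)
    out <- methods::new("SpatialExpression", se)
    S4Vectors::metadata(out)$isLogNormalized <- isLogNormalized
    methods::validObject(out)
    out
}

#' Expression values of a SpatialExpression
#'
#' @param x a [SpatialExpression-class].
#' @return the genes x spots numeric matrix.
#' @export
exprValues <- function(x) {
    stopifnot(methods::is(x, "SpatialExpression"))
    SummarizedExperiment::assay(x, 1L)
}

#' Spot coordinates
#'
#' @param x a [SpatialExpression-class].
#' @return S x 2 matrix of x/y coordinates, or `NULL` when absent.
#' @export
setMethod("spotCoords", "SpatialExpression", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!all(c("x", "y") %in% colnames(cd))) return(NULL)
    m <- cbind(x = cd$x, y = cd$y)
    rownames(m) <- colnames(x)
    m
})

#' Log-normalization state
#'
#' @param x a [SpatialExpression-class].
#' @return logical flag.
#' @export
setMethod("isLogNormalized", "SpatialExpression", function(x) {
    isTRUE(S4Vectors::metadata(x)$isLogNormalized)
})

setMethod("show", "SpatialExpression", function(object) {
    cat(sprintf("SpatialExpression: %d genes x %d spots\n",
                nrow(object), ncol(object)))
    cat(sprintf("  log-normalized: %s; coordinates: %s\n",
                isLogNormalized(object),
                if (is.null(spotCoords(object))) "absent" else "present"))
})

#' Load an expression matrix from disk
#'
#' Reads a genes x spots matrix from MatrixMarket (with companion one-column
#' gene and spot id files) or from a dense CSV/TSV whose header row holds the
#' spot ids and whose first column holds the gene ids. Missing or empty cells
#' become zeros; negative entries or duplicated identifiers are rejected.
#'
#' @param path path to the matrix file.
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`.
#' @param genesPath,spotsPath companion id files (required for MTX).
#' @param coordsPath optional TSV with columns `spot_id`, `x`, `y`.
#' @return a [SpatialExpression-class].
#' @export
loadMatrix <- function(path, format = c("csv", "tsv", "mtx"),
                       genesPath = NULL, spotsPath = NULL,
                       coordsPath = NULL) {
    format <- match.arg(format)
    if (format == "mtx" && (is.null(genesPath) || is.null(spotsPath)))
        stop("MTX input requires companion gene and spot id files")
    if (!file.exists(path))
        stop("cannot read '", path, "': no such file")
    if (format == "mtx") {
        values <- as.matrix(Matrix::readMM(path))
        geneIds <- readLines(genesPath)
        spotIds <- readLines(spotsPath)
        if (length(geneIds) != nrow(values) || length(spotIds) != ncol(values))
            stop("id file lengths do not match the matrix dimensions")
    } else {
        sep <- if (format == "csv") "," else "\t"
        tab <- utils::read.table(path, sep = sep, header = TRUE,
                                 row.names = NULL, check.names = FALSE,
                                 colClasses = NA, stringsAsFactors = FALSE)
        geneIds <- as.character(tab[[1L]])
        values <- as.matrix(tab[, -1L, drop = FALSE])
        storage.mode(values) <- "double"
        spotIds <- colnames(tab)[-1L]
    }
    if (anyDuplicated(geneIds))
        stop("duplicate gene id: ", geneIds[duplicated(geneIds)][1L])
    if (anyDuplicated(spotIds))
        stop("duplicate spot id: ", spotIds[duplicated(spotIds)][1L])
    values[is.na(values)] <- 0
    if (any(values < 0)) {
        bad <- which(values < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("negative entry at row %d (gene %s), column %d (spot %s)",
                     bad[1L], geneIds[bad[1L]], bad[2L], spotIds[bad[2L]]))
    }
    coords <- NULL
    if (!is.null(coordsPath)) {
        ct <- utils::read.table(coordsPath, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
        idx <- match(spotIds, ct$spot_id)
        if (anyNA(idx)) stop("coordinate file is missing some spot ids")
        coords <- cbind(ct$x[idx], ct$y[idx])
    }
    SpatialExpression(values, geneIds, spotIds, coords = coords)
}

#' Write an expression matrix to disk
#'
#' Inverse of [loadMatrix()]: dense CSV/TSV with spot-id header and gene-id
#' first column, or MatrixMarket plus one-column id files.
#'
#' @param x a [SpatialExpression-class].
#' @param path output matrix file.
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`.
#' @param genesPath,spotsPath id file paths (required for MTX).
#' @return invisibly, `path`.
#' @export
writeMatrix <- function(x, path, format = c("csv", "tsv", "mtx"),
                        genesPath = NULL, spotsPath = NULL) {
    format <- match.arg(format)
    v <- exprValues(x)
    if (format == "mtx") {
        if (is.null(genesPath) || is.null(spotsPath))
            stop("MTX output requires gene and spot id file paths")
        Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE), path)
        writeLines(rownames(v), genesPath)
        writeLines(colnames(v), spotsPath)
    } else {
        sep <- if (format == "csv") "," else "\t"
        tab <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                          stringsAsFactors = FALSE)
        utils::write.table(tab, path, sep = sep, quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Per-spot log-normalization
#'
#' Scales every spot (column) to a common library size and applies
#' `log1p`, the standard transcriptomics log-normalization. Zeros map to
#' zeros.
#'
#' @param Y a raw-scale [SpatialExpression-class].
#' @param scale target per-spot total before `log1p` (default 1e4).
#' @return a log-normalized [SpatialExpression-class].
#' @export
logNormalize <- function(Y, scale = 1e4) {
    stopifnot(methods::is(Y, "SpatialExpression"), scale > 0)
    if (isLogNormalized(Y))
        stop("input is already log-normalized")
    v <- exprValues(Y)
    lib <- colSums(v)
    if (any(lib == 0))
        stop("spot '", colnames(v)[which(lib == 0)[1L]],
             "' has zero total expression and cannot be normalized")
    out <- log1p(sweep(v, 2L, lib / scale, "/"))
    SpatialExpression(out, rownames(v), colnames(v), coords = spotCoords(Y),
                      isLogNormalized = TRUE)
}

#' Library-size scaling
#'
#' Scales every spot column to a common total (the mean library size by
#' default) without leaving the linear scale. Spot composition is a
#' ratio within each column, so this changes no proportion estimate, but
#' it makes the column-stochastic factorization model consistent across
#' spots that captured different numbers of cells.
#'
#' @param Y a raw-scale [SpatialExpression-class].
#' @param target common column total (default: mean library size).
#' @return a [SpatialExpression-class] with equal column sums.
#' @export
scaleLibrary <- function(Y, target = NULL) {
    stopifnot(methods::is(Y, "SpatialExpression"))
    v <- exprValues(Y)
    lib <- colSums(v)
    if (any(lib == 0))
        stop("spot '", colnames(v)[which(lib == 0)[1L]],
             "' has zero total expression")
    if (is.null(target)) target <- mean(lib)
    SpatialExpression(sweep(v, 2L, lib / target, "/"), rownames(v),
                      colnames(v), coords = spotCoords(Y),
                      isLogNormalized = isLogNormalized(Y))
}

#' Detection-fraction gene filter
#'
#' Keeps genes whose detection fraction f (share of spots with a strictly
#' positive value) satisfies `minFrac < f < maxFrac`, both bounds strict:
#' with the defaults, genes detected in more than 5% but less than 100% of
#' spots survive. Gene order is preserved.
#'
#' @param Y a [SpatialExpression-class].
#' @param minFrac,maxFrac strict detection-fraction bounds in [0, 1].
#' @return the filtered [SpatialExpression-class].
#' @export
filterGenes <- function(Y, minFrac = 0.05, maxFrac = 1.0) {
    stopifnot(methods::is(Y, "SpatialExpression"),
              minFrac >= 0, maxFrac <= 1, minFrac < maxFrac)
    v <- exprValues(Y)
    f <- rowMeans(v > 0)
    keep <- f > minFrac & f < maxFrac
    if (!any(keep))
        stop("no gene passes the detection-fraction filter; ",
             "loosen minFrac/maxFrac")
    Y[keep, ]
}

#' Row normalization
#'
#' Divides every gene row by its sum, yielding the row-stochastic matrix on
#' which simplex-corner identification operates, and records the row sums
#' so the original matrix is exactly recoverable.
#'
#' @param Y a [SpatialExpression-class] or genes x spots matrix with
#'   strictly positive row sums.
#' @return a [NormalizedMatrix-class].
#' @export
rowNormalize <- function(Y) {
    v <- if (methods::is(Y, "SpatialExpression")) exprValues(Y) else as.matrix(Y)
    rs <- rowSums(v)
    if (any(rs <= 0))
        stop("gene '", rownames(v)[which(rs <= 0)[1L]],
             "' has non-positive row sum and cannot be normalized")
    methods::new("NormalizedMatrix", values = v / rs, rowScale = rs)
}

setMethod("show", "NormalizedMatrix", function(object) {
    cat(sprintf("NormalizedMatrix: %d row-stochastic gene rows x %d spots\n",
                nrow(object@values), ncol(object@values)))
})
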