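#' Build a synthetic single-cell reference
#'
#' Creates per-type mean expression profiles with planted, mutually
#' exclusive marker blocks: baseline means are log-normal across genes, and
#' each type receives `nMarkersPerType` exclusive marker genes whose mean
#' is elevated by `markerFold` in their own type and suppressed to
#' `offFactor` of baseline in every other type, emulating the near on/off
#' expression of genuine cell-type markers in single-cell data (and well
#' above the 3x separation the validity check requires). Cells drawn from
#' this reference are negative binomial (Gamma-Poisson) around the type
#' means.
#'
#' @param K number of cell types (>= 2).
#' @param L number of genes (>= `K * nMarkersPerType`).
#' @param nMarkersPerType exclusive marker genes per type (default 20).
#' @param seed integer seed; the reference is reproducible under it.
#' @param markerFold mean fold-elevation of a marker in its own type.
#' @param offFactor residual fraction of baseline a marker keeps in the
#'   other types.
#' @param dispersion negative-binomial overdispersion of per-cell counts.
#' @return a [SyntheticReference-class].
#' @examples
#' ref <- makeReference(K = 3, L = 300, seed = 1)
#' lengths(ref@markerGenes)
#' @export
makeReference <- function(K, L, nMarkersPerType = 20L, seed = 1L,
                          markerFold = 6, offFactor = 0.1,
                          dispersion = 0.3) {
    stopifnot(K >= 2L)
    if (L < K * nMarkersPerType)
        stop("L must be at least K * nMarkersPerType = ", K * nMarkersPerType)
    geneIds <- sprintf("gene%04d", seq_len(L))
    typeNames <- paste0("type", seq_len(K))
    withSeed(seed, {
        base <- stats::rlnorm(L, meanlog = log(1.5), sdlog = 1)
        M <- matrix(base, L, K, dimnames = list(geneIds, typeNames))
        markerIdx <- matrix(sample.int(L, K * nMarkersPerType), ncol = K)
        for (k in seq_len(K)) {
            M[markerIdx[, k], ] <- base[markerIdx[, k]] * offFactor
            M[markerIdx[, k], k] <- base[markerIdx[, k]] * markerFold
        }
    })
    markerGenes <- lapply(seq_len(K), function(k) geneIds[markerIdx[, k]])
    names(markerGenes) <- typeNames
    methods::new("SyntheticReference", meanProfiles = M,
                 typeNames = typeNames, dispersion = dispersion,
                 cellsPerType = 1000L, markerGenes = markerGenes)
}

# Largest-remainder apportionment of `total` cells to `props`.
apportionCells <- function(props, total) {
    raw <- props * total
    base <- floor(raw)
    short <- total - sum(base)
    if (short > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
        base[extra] <- base[extra] + 1L
    }
    as.integer(base)
}

#' Simulate region-structured spatial spots
#'
#' Emulates a tissue with `nRegions` anatomical regions, each dominated by a
#' distinct cell type. Per spot, the number of co-occurring cell types is
#' drawn from the discrete uniform on {2, ..., min(6, K)}, their proportions
#' from a flat Dirichlet (concentration 1 for every included type), and the
#' dominant type's dominance is enforced by swapping the largest coordinate
#' onto it. A Bernoulli(`hetRate`) mask marks heterogeneous spots whose
#' proportions carry no dominance constraint. Spot expression is the sum of
#' a finite number of single cells (negative-binomial draws around the
#' reference type means) allocated to types by largest-remainder rounding;
#' the recorded ground truth is the realized cell-count fraction.
#'
#' @param ref a [SyntheticReference-class].
#' @param nRegions number of regions (<= K).
#' @param spotsPerRegion spots per region (>= 1).
#' @param hetRate heterogeneity rate in [0, 1], the fraction of spots with
#'   no enforced dominant type.
#' @param cellsPerSpot integer range (low, high) of cells per spot.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a [SyntheticTruth-class].
#' @examples
#' ref <- makeReference(K = 3, L = 300, seed = 1)
#' sim <- simulateSpots(ref, nRegions = 3, spotsPerRegion = 10,
#'                      hetRate = 0.2, seed = 1)
#' colSums(trueProportions(sim))[1:4]
#' @export
simulateSpots <- function(ref, nRegions = 3L, spotsPerRegion = 50L,
                          hetRate = 0, cellsPerSpot = c(5L, 15L),
                          seed = 1L) {
    stopifnot(methods::is(ref, "SyntheticReference"))
    K <- ncol(ref@meanProfiles)
    L <- nrow(ref@meanProfiles)
    if (nRegions > K)
        stop("nRegions must not exceed the number of cell types (", K, ")")
    if (spotsPerRegion < 1L) stop("spotsPerRegion must be at least 1")
    stopifnot(hetRate >= 0, hetRate <= 1)
    S <- nRegions * spotsPerRegion
    cmax <- min(6L, K)

    withSeed(seed, {
        dominant <- sample.int(K, nRegions)
        regionOfSpot <- rep(seq_len(nRegions), each = spotsPerRegion)
        hetMask <- stats::runif(S) < hetRate
        P <- matrix(0, K, S)
        Ncells <- matrix(0L, K, S)      # realized cells per type per spot
        coords <- matrix(0, S, 2L)
        for (j in seq_len(S)) {
            r <- regionOfSpot[j]
            c_j <- sample(2:cmax, 1L)
            if (hetMask[j]) {
                types <- sample.int(K, c_j)
                props <- as.vector(rdirichlet(1L, rep(1, c_j)))
            } else {
                dom <- dominant[r]
                types <- c(dom, sample(setdiff(seq_len(K), dom), c_j - 1L))
                props <- as.vector(rdirichlet(1L, rep(1, c_j)))
                im <- which.max(props)
                if (im != 1L) props[c(1L, im)] <- props[c(im, 1L)]
            }
            ncells <- sample(cellsPerSpot[1L]:cellsPerSpot[2L], 1L)
            counts <- apportionCells(props, ncells)
            if (!hetMask[j]) {
                # rounding can displace or tie away the dominant type;
                # restore a strict plurality for it
                full <- integer(K); full[types] <- counts
                dom <- dominant[r]
                im <- which.max(full)
                if (im != dom) {
                    tmp <- full[dom]; full[dom] <- full[im]; full[im] <- tmp
                }
                ties <- setdiff(which(full == full[dom]), dom)
                if (length(ties) && full[dom] > 0L) {
                    full[ties[1L]] <- full[ties[1L]] - 1L
                    full[dom] <- full[dom] + 1L
                }
                counts <- full[types]
            }
            Ncells[types, j] <- counts
            P[types, j] <- counts / sum(counts)
            coords[j, ] <- c(r + stats::runif(1L, -0.45, 0.45),
                             stats::runif(1L))
        }
        # summed expression per spot: a sum of n iid NB(mu, 1/dispersion)
        # cells is NB(n mu, n/dispersion); drawn per type across all spots
        Y <- matrix(0, L, S)
        for (k in seq_len(K)) {
            nk <- Ncells[k, ]
            hit <- which(nk > 0L)
            if (!length(hit)) next
            mu <- ref@meanProfiles[, k] %o% nk[hit]
            size <- rep(nk[hit] / ref@dispersion, each = L)
            Y[, hit] <- Y[, hit] +
                matrix(stats::rnbinom(L * length(hit), mu = mu, size = size),
                       L, length(hit))
        }
    })
    spotIds <- sprintf("spot%04d", seq_len(S))
    dimnames(Y) <- list(rownames(ref@meanProfiles), spotIds)
    dimnames(P) <- list(ref@typeNames, spotIds)
    se <- SpatialExpression(Y, coords = coords)
    methods::new("SyntheticTruth", Y = se, PTrue = P,
                 regionOfSpot = as.integer(regionOfSpot),
                 dominantTypeOfRegion = as.integer(dominant),
                 heterogeneityMask = hetMask, seed = as.integer(seed))
}

#' True proportion matrix of a simulated dataset
#'
#' @param x a [SyntheticTruth-class].
#' @return K x S column-stochastic matrix of realized cell-count fractions.
#' @export
setMethod("trueProportions", "SyntheticTruth", function(x) x@PTrue)

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(
        "SyntheticTruth: %d genes x %d spots, %d regions, %d cell types\n",
        nrow(object@Y), ncol(object@Y),
        length(object@dominantTypeOfRegion), nrow(object@PTrue)))
    cat(sprintf("  heterogeneous spots: %d/%d; seed %d\n",
                sum(object@heterogeneityMask),
                length(object@heterogeneityMask), object@seed))
})

setMethod("show", "SyntheticReference", function(object) {
    cat(sprintf(
        "SyntheticReference: %d genes x %d types, %d markers/type, dispersion %.2g\n",
        nrow(object@meanProfiles), ncol(object@meanProfiles),
        length(object@markerGenes[[1L]]), object@dispersion))
})
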