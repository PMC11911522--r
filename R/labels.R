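# Gaussian Naive-Bayes posteriors over reference cell types, computed in
# log space with log-sum-exp (products of hundreds of per-gene densities
# underflow otherwise). Training data are pseudo-replicates of the
# reference profiles on the log1p scale; a diffuse "background" class built
# from the across-type spread calibrates the posteriors so that a profile
# resembling no reference type receives a low posterior everywhere.
nbPosteriors <- function(profilesLog, refLog, nRep = 30L, noiseSd = 0.15,
                         seed = 1L) {
    R <- ncol(refLog)
    G <- nrow(refLog)
    classMean <- refLog
    classSd <- matrix(noiseSd * pmax(1, abs(refLog)), G, R)
    bgMean <- rowMeans(refLog)
    bgSd <- apply(refLog, 1L, stats::sd) * 1.5 + noiseSd
    withSeed(seed, {
        # per-class empirical moments from pseudo-replicates, mirroring a
        # fitted classifier rather than the exact generating parameters
        for (r in seq_len(R)) {
            reps <- classMean[, r] + matrix(
                stats::rnorm(G * nRep, sd = classSd[, r]), G, nRep)
            classMean[, r] <- rowMeans(reps)
            classSd[, r] <- apply(reps, 1L, stats::sd) + 1e-3
        }
    })
    post <- matrix(0, ncol(profilesLog), R)
    for (k in seq_len(ncol(profilesLog))) {
        x <- profilesLog[, k]
        ll <- vapply(seq_len(R), function(r)
            sum(stats::dnorm(x, classMean[, r], classSd[, r], log = TRUE)),
            numeric(1))
        llBg <- sum(stats::dnorm(x, bgMean, bgSd, log = TRUE))
        all_ <- c(ll, llBg)
        post[k, ] <- exp(ll - logSumExp(all_))
    }
    post
}

#' Assign cell-type labels from a reference panel
#'
#' Scores every (estimated type, reference type) pair by the mean of the
#' Pearson correlation between their log1p expression profiles and the
#' Gaussian Naive-Bayes posterior of the reference label given the
#' estimated profile. Assignment is an iterative greedy selection: the
#' global maximum of the score matrix is taken, its row and column are
#' removed, and the process repeats; estimated types whose best remaining
#' score falls below `threshold` are labelled `"unassigned"`.
#'
#' @param M a [DeconvResult-class] or L' x K estimated profile matrix with
#'   gene rownames.
#' @param reference genes x R reference profile matrix/data.frame with gene
#'   rownames and unique type-name colnames.
#' @param threshold minimum composite score for an assignment (default
#'   0.3).
#' @param nRep pseudo-replicates per reference type for the classifier.
#' @param seed integer seed for the pseudo-replicates.
#' @return a [LabelAssignment-class].
#' @export
assignLabels <- function(M, reference, threshold = 0.3, nRep = 30L,
                         seed = 1L) {
    if (methods::is(M, "DeconvResult")) M <- profiles(M)
    M <- as.matrix(M)
    reference <- as.matrix(reference)
    if (anyDuplicated(colnames(reference)))
        stop("duplicate reference type names")
    shared <- intersect(rownames(M), rownames(reference))
    if (length(shared) < 20L)
        stop("need at least 20 shared genes between the estimated profiles ",
             "and the reference (found ", length(shared), ")")
    # profiles and references live on different scales (spot-level sums
    # vs per-cell means); normalize each profile to a common total so the
    # similarity is about shape, not depth
    colScale <- function(x) sweep(x, 2L, colSums(x) / 1e4, "/")
    ml <- log1p(colScale(M[shared, , drop = FALSE]))
    rl <- log1p(colScale(reference[shared, , drop = FALSE]))
    K <- ncol(ml)
    R <- ncol(rl)
    pear <- stats::cor(ml, rl)
    post <- nbPosteriors(ml, rl, nRep = nRep, seed = seed)
    comp <- (pear + post) / 2
    estNames <- colnames(ml)
    if (is.null(estNames)) estNames <- paste0("type", seq_len(K))
    refNames <- colnames(rl)
    dimnames(comp) <- dimnames(pear) <- dimnames(post) <-
        list(estNames, refNames)

    mapping <- setNames(rep("unassigned", K), estNames)
    work <- comp
    repeat {
        if (all(!is.finite(work)) || max(work, na.rm = TRUE) < threshold)
            break
        ij <- which(work == max(work, na.rm = TRUE), arr.ind = TRUE)[1L, ]
        mapping[estNames[ij[1L]]] <- refNames[ij[2L]]
        work[ij[1L], ] <- -Inf
        work[, ij[2L]] <- -Inf
        if (all(work == -Inf)) break
    }
    methods::new("LabelAssignment", mapping = mapping, scores = comp,
                 pearson = pear, posterior = post, threshold = threshold)
}

setMethod("show", "LabelAssignment", function(object) {
    cat(sprintf("LabelAssignment (threshold %.2f):\n", object@threshold))
    for (k in names(object@mapping)) {
        lab <- object@mapping[[k]]
        sc <- if (lab == "unassigned") NA_real_ else object@scores[k, lab]
        cat(sprintf("  %s -> %s%s\n", k, lab,
                    if (is.na(sc)) "" else sprintf(" (score %.3f)", sc)))
    }
})
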