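#' Corrected AIC of a deconvolution fit
#'
#' The finite-sample-corrected Akaike information criterion used for
#' choosing the number of cell types:
#' \deqn{AIC_K = L S \ln(SSR_K / (L S)) + 2 p + 2 p (p + 1) / (L S - p - 1)}
#' with \eqn{p = p(K) = K (L + S)} free parameters (the entries of M and H)
#' and \eqn{L S} observations.
#'
#' @param ssr positive residual sum of squares `||Y - MH||_F^2`.
#' @param K number of cell types.
#' @param L number of genes in the fitted matrix.
#' @param S number of spots.
#' @return the AIC value.
#' @examples
#' aicValue(ssr = 250, K = 3, L = 100, S = 50)
#' @export
aicValue <- function(ssr, K, L, S) {
    p <- K * (L + S)
    n <- L * S
    if (n - p - 1 <= 0)
        stop("K too large for matrix size: L*S - p(K) - 1 = ", n - p - 1,
             " <= 0 (over-parameterized fit)")
    if (ssr <= 0)
        stop("ssr must be positive (degenerate exact fit; log undefined)")
    n * log(ssr / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Select the number of cell types by AIC
#'
#' Fits [deconf()] for every candidate K on the CV-ranked top-`nInit` gene
#' subset (for tractable repeated fits; `L` in the AIC then counts those
#' genes), computes the residual sum of squares and the corrected AIC, and
#' returns the whole curve together with its argmin. With `reps > 1` the
#' smallest SSR over seeded restarts is used for each K, which stabilizes
#' the curve against local optima.
#'
#' By default the residual is measured on the row-normalized
#' representation (each gene row scaled to unit sum — the scale on which
#' the simplex geometry is defined) with an unconstrained non-negative
#' factorization, whose free-parameter count is exactly the `p(K) =
#' K(L+S)` the criterion assumes. Row normalization equalizes gene scales,
#' so the residual is not dominated by a handful of highly expressed
#' genes; raw or log values can be supplied with `rowNorm = FALSE`.
#'
#' @param Y a [SpatialExpression-class] or genes x spots matrix (filtered,
#'   non-log values).
#' @param kMin,kMax inclusive candidate range (default 2 to 8).
#' @param reps seeded restarts per candidate (default 1).
#' @param nInit CV-ranked gene subset size used for the fits; the default
#'   `NULL` keeps all genes, which sharpens the criterion (it needs
#'   `L >> S` for margin over noise). Smaller subsets trade accuracy for
#'   runtime.
#' @param maxIter inner [deconf()] iteration cap per candidate. The SSR
#'   differences that drive the criterion stabilize within a few dozen
#'   alternations, so the default keeps repeated fits affordable.
#' @param seed integer seed.
#' @param rowNorm measure the SSR on the row-normalized gene subset.
#' @param sumToOne constrain proportions during the fits; the default
#'   `FALSE` matches the criterion's parameter count.
#' @return a [KSelection-class].
#' @export
selectK <- function(Y, kMin = 2L, kMax = 8L, reps = 1L, nInit = NULL,
                    maxIter = 80L, seed = 1L, rowNorm = TRUE,
                    sumToOne = FALSE) {
    v <- if (methods::is(Y, "SpatialExpression")) exprValues(Y) else as.matrix(Y)
    if (kMax >= ncol(v))
        stop("kMax must be smaller than the number of spots")
    if (kMin < 1L || kMin > kMax) stop("need 1 <= kMin <= kMax")
    if (is.null(nInit)) nInit <- nrow(v)
    genes <- initialFeatures(v, min(nInit, nrow(v)))
    vr <- v[genes, , drop = FALSE]
    if (rowNorm) vr <- rowNormalize(vr)@values
    L <- nrow(vr)
    S <- ncol(vr)
    kGrid <- seq.int(kMin, kMax)
    ssr <- aic <- rep(NA_real_, length(kGrid))
    errs <- character(0)
    for (i in seq_along(kGrid)) {
        K <- kGrid[i]
        res <- try({
            best <- Inf
            for (r in seq_len(reps)) {
                fit <- deconf(vr, K, maxIter = maxIter,
                              seed = childSeed(seed, K * 100L + r),
                              sumToOne = sumToOne)
                best <- min(best, fit@frobErr^2)
            }
            ssr[i] <- best
            aic[i] <- aicValue(best, K, L, S)
        }, silent = TRUE)
        if (inherits(res, "try-error"))
            errs <- c(errs, sprintf("K=%d: %s", K,
                                    conditionMessage(attr(res, "condition"))))
    }
    if (all(is.na(aic)))
        stop("no candidate K could be fitted: ",
             paste(errs, collapse = "; "))
    finite <- which(is.finite(aic))
    bestK <- kGrid[finite][which.min(aic[finite])]
    methods::new("KSelection", kGrid = kGrid, aicValues = aic,
                 ssrValues = ssr, bestK = as.integer(bestK))
}

setMethod("bestK", "KSelection", function(x) x@bestK)

#' AIC curve as a data.frame
#'
#' @param x a [KSelection-class].
#' @param ... ignored.
#' @return data.frame with columns `K`, `SSR`, `AIC` for knee inspection.
#' @export
as.data.frame.KSelection <- function(x, ...) {
    data.frame(K = x@kGrid, SSR = x@ssrValues, AIC = x@aicValues)
}

#' Plot the AIC curve
#'
#' @param x a [KSelection-class].
#' @param y ignored.
#' @param ... passed to [plot()].
#' @export
setMethod("plot", signature(x = "KSelection", y = "missing"),
    function(x, y, ...) {
        graphics::plot(x@kGrid, x@aicValues, type = "b", xlab = "K",
                       ylab = "AIC", ...)
        graphics::abline(v = x@bestK, lty = 2)
    })

setMethod("show", "KSelection", function(object) {
    cat(sprintf("KSelection over K = %d..%d: best K = %d\n",
                min(object@kGrid), max(object@kGrid), object@bestK))
    print(as.data.frame.KSelection(object), row.names = FALSE)
})
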