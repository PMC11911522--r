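#' Project points onto their (K-1)-dimensional affine subspace
#'
#' Centers the point cloud and takes the top K-1 right singular vectors of
#' the centered matrix as an orthonormal basis. Points lying exactly in a
#' (K-1)-simplex project and lift back without loss.
#'
#' @param points N x S matrix, one point per row.
#' @param K number of simplex vertices the data are assumed to span.
#' @param rankTol relative singular-value threshold for the rank check.
#' @return an [AffineProjection-class]; slot `projected` holds the
#'   N x (K-1) coordinates of `points`.
#' @export
affineProject <- function(points, K, rankTol = 1e-8) {
    points <- as.matrix(points)
    if (K < 2L) stop("K must be at least 2")
    center <- colMeans(points)
    Xc <- sweep(points, 2L, center)
    sv <- svd(Xc, nu = 0L, nv = min(K - 1L, ncol(Xc)))
    if (sv$d[1L] < 1e-12 || length(sv$d) < K - 1L ||
        sv$d[K - 1L] <= rankTol * sv$d[1L])
        stop("data do not span a (K-1)-simplex; reduce K")
    basis <- t(sv$v[, seq_len(K - 1L), drop = FALSE])
    proj <- Xc %*% t(basis)
    rownames(proj) <- rownames(points)
    methods::new("AffineProjection", basis = basis, center = center,
                 projected = proj)
}

#' @rdname affine-maps
#' @export
setMethod("projectPoints", "AffineProjection", function(x, points) {
    sweep(as.matrix(points), 2L, x@center) %*% t(x@basis)
})

#' @rdname affine-maps
#' @export
setMethod("liftPoints", "AffineProjection", function(x, points) {
    sweep(as.matrix(points) %*% x@basis, 2L, x@center, "+")
})

setMethod("show", "AffineProjection", function(object) {
    cat(sprintf("AffineProjection: %d ambient dims -> %d, %d points\n",
                length(object@center), nrow(object@basis),
                nrow(object@projected)))
})

# Vertex-component-style initialization: greedily pick the K data columns
# of the augmented matrix X (K x N) with the largest component orthogonal
# to the span of the picks so far. Deterministic; exact ties broken by a
# seeded draw.
vcaInit <- function(X, K, seed = 1L) {
    N <- ncol(X)
    idx <- integer(K)
    E <- NULL
    for (k in seq_len(K)) {
        if (is.null(E)) {
            score <- colSums(X^2)
        } else {
            qe <- qr.Q(qr(E))
            R <- X - qe %*% (t(qe) %*% X)
            score <- colSums(R^2)
        }
        score[idx[seq_len(k - 1L)]] <- -Inf
        top <- max(score)
        best <- which(score >= top - 1e-12 * max(abs(top), 1))
        idx[k] <- if (length(best) == 1L) best else
            withSeed(childSeed(seed, k), sample(best, 1L))
        E <- X[, idx[seq_len(k)], drop = FALSE]
    }
    idx
}

# Objective of the minimum-volume fit: -log|det Q| + tau * total hinge.
sisalObjective <- function(Q, X, tau) {
    d <- determinant(Q, logarithm = TRUE)
    -as.numeric(d$modulus) + tau * sum(pmax(-Q %*% X, 0))
}

#' Minimum-volume simplex fitting (split augmented Lagrangian)
#'
#' Recovers the K vertices of the simplex enclosing a projected point
#' cloud by minimizing \eqn{-\log|\det Q| + \tau \sum \mathrm{hinge}(-QX)}
#' over the inverse mixing matrix Q, where X is the projected data with an
#' appended constant-1 coordinate. The non-smooth problem is attacked as a
#' sequence of convex subproblems: each outer step linearizes the log-det
#' term at the current Q (with a proximal trust weight adapted by line
#' search) and solves the resulting hinge-regularized quadratic by ADMM
#' with the splitting Z = QX. Only objective-decreasing steps are
#' accepted, so the objective trace is non-increasing. Initialization is a
#' vertex-component-style greedy pick of extreme data points, making the
#' fit deterministic up to seeded tie-breaking.
#'
#' @param projected N x (K-1) matrix from [affineProject()], or an
#'   [AffineProjection-class] (its fitted points are used and vertices are
#'   lifted back to ambient coordinates).
#' @param K number of vertices.
#' @param tau hinge weight: small values tolerate points outside the
#'   simplex (noise), large values approach the hard constraint.
#' @param maxIter outer iteration cap (default 100).
#' @param seed integer seed (tie-breaking and restarts only).
#' @param admmIter inner ADMM iterations per outer step.
#' @param objTol relative objective-change stopping tolerance.
#' @return a [SimplexVertices-class]; vertices are ordered by descending
#'   first projected coordinate.
#' @export
sisalFit <- function(projected, K, tau = 1.0, maxIter = 100L, seed = 1L,
                     admmIter = 60L, objTol = 1e-10) {
    proj <- NULL
    if (methods::is(projected, "AffineProjection")) {
        proj <- projected
        projected <- proj@projected
    }
    projected <- as.matrix(projected)
    N <- nrow(projected)
    if (N < K) stop("need at least K points")
    if (ncol(projected) != K - 1L)
        stop("projected coordinates must have K-1 columns")
    X <- rbind(t(projected), 1)                  # K x N augmented points
    XXt <- tcrossprod(X)

    fitOnce <- function(jitter) {
        idx <- vcaInit(X, K, seed)
        M0 <- X[, idx, drop = FALSE]
        if (jitter > 0)
            M0 <- M0 + withSeed(childSeed(seed, 999L + jitter),
                                matrix(stats::rnorm(K * K, sd = jitter *
                                       stats::sd(M0)), K, K))
        if (abs(det(M0)) < 1e-300) return(NULL)
        Q <- solve(M0)
        # feasibility invariant: barycentric coordinates QX sum to 1 per
        # point, equivalent to 1'Q = e_K' in the augmented coordinates
        # (holds at the init since the last row of M0 is all ones); every
        # Q-update below re-imposes it in closed form via a Lagrange
        # multiplier, which also bounds the log-det term.
        f <- sisalObjective(Q, X, tau)
        trace <- f
        rho <- 1
        mu <- 1 / max(1, norm(Q, "F"))
        eK <- c(rep(0, K - 1L), 1)
        solveSub <- function(A0, Mfull, Minv, Zinit) {
            Z <- Zinit
            U <- matrix(0, K, N)
            Qn <- Q
            for (ad in seq_len(admmIter)) {
                C <- A0 + rho * tcrossprod(Z - U, X)
                lam <- (colSums(C) - Mfull[K, ]) / K
                Qn <- sweep(C, 2L, lam) %*% Minv
                V <- Qn %*% X + U
                Z <- ifelse(V >= 0, V,
                            ifelse(V >= -tau / rho, 0, V + tau / rho))
                U <- V - Z
            }
            Qn
        }
        for (it in seq_len(maxIter)) {
            G <- -t(solve(Q))                    # gradient of -log|det Q|
            accepted <- FALSE
            muCur <- mu
            for (ls in 1:12) {                   # proximal line search on mu
                Mfull <- (1 / muCur) * diag(K) + rho * XXt
                Minv <- solve(Mfull)
                Qn <- solveSub((1 / muCur) * Q - G, Mfull, Minv, Q %*% X)
                fn <- sisalObjective(Qn, X, tau)
                if (is.finite(fn) && fn <= f + 1e-12) {
                    accepted <- fn < f - objTol * max(1, abs(f))
                    Q <- Qn
                    f <- fn
                    trace <- c(trace, f)
                    mu <- muCur * 1.5
                    break
                }
                muCur <- muCur / 4
            }
            if (!accepted) break
        }
        list(Q = Q, f = f, trace = trace, nIter = length(trace) - 1L)
    }

    res <- NULL
    for (attempt in 0:3) {
        res <- fitOnce(jitter = attempt * 0.01)
        if (!is.null(res)) break
        if (attempt == 3L)
            stop("singular initialization after 3 perturbed restarts")
        message("sisalFit: singular initialization, restarting perturbed")
    }

    Mv <- solve(res$Q)                            # columns = vertices (augmented)
    Mv <- sweep(Mv, 2L, Mv[K, ], "/")             # exact last coordinate 1
    pv <- t(Mv[seq_len(K - 1L), , drop = FALSE])  # K x (K-1)
    ord <- order(-pv[, 1L])                       # canonical vertex order
    pv <- pv[ord, , drop = FALSE]
    Q <- solve(rbind(t(pv), 1))
    amb <- if (is.null(proj)) pv else liftPoints(proj, pv)
    rownames(amb) <- rownames(pv) <- paste0("corner", seq_len(K))
    methods::new("SimplexVertices", vertices = amb, projectedVertices = pv,
                 Q = Q, tau = tau, nIter = res$nIter,
                 objectiveTrace = res$trace)
}

setMethod("show", "SimplexVertices", function(object) {
    cat(sprintf(
        "SimplexVertices: %d corners in %d ambient dims; tau = %.3g, %d iterations\n",
        nrow(object@projectedVertices), ncol(object@vertices), object@tau,
        object@nIter))
})

#' Barycentric coordinates with respect to fitted corners
#'
#' Expresses each projected point as an affine combination of the simplex
#' vertices by solving the (K-1)+1 linear system per point. Coordinates sum
#' to one; small negatives indicate points outside the fitted simplex
#' (tolerated by the soft constraint) and are returned as-is.
#'
#' @param vertices a [SimplexVertices-class].
#' @param projected N x (K-1) matrix of projected points.
#' @return K x N matrix of barycentric coordinates (columns sum to 1).
#' @export
pseudoProportions <- function(vertices, projected) {
    stopifnot(methods::is(vertices, "SimplexVertices"))
    projected <- as.matrix(projected)
    K <- nrow(vertices@projectedVertices)
    A <- rbind(t(vertices@projectedVertices), 1)
    if (abs(det(A)) < 1e-300) stop("degenerate simplex")
    out <- solve(A, rbind(t(projected), 1))
    rownames(out) <- rownames(vertices@projectedVertices)
    colnames(out) <- rownames(projected)
    out
}
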