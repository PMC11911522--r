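test_that("affine projection round-trips noiseless simplex data", {
    fx <- simplexCloud(K = 3, N = 60, ambient = 8, seed = 3)
    pr <- affineProject(fx$points, K = 3)
    expect_lt(max(abs(tcrossprod(pr@basis) - diag(2))), 1e-10)
    lifted <- liftPoints(pr, pr@projected)
    expect_lt(max(abs(lifted - fx$points)), 1e-8)
    # degenerate cloud: all points equal
    same <- matrix(1, 10, 4)
    expect_error(affineProject(same, K = 2), "do not span")
    # rank too low for requested K
    seg <- outer(seq_len(10), c(1, 2, 3))   # rank-1 centered cloud
    expect_error(affineProject(seg, K = 3), "reduce K")
})

test_that("corner recovery is exact on noiseless data containing vertices", {
    fx <- simplexCloud(K = 3, N = 200, ambient = 8, seed = 3)
    pr <- affineProject(fx$points, K = 3)
    sv <- sisalFit(pr, K = 3, seed = 1)
    expect_lt(alignedVertexError(sv@vertices, fx$vertices), 1e-4)
    expect_true(all(diff(sv@objectiveTrace) <= 1e-9))
})

test_that("K = 2 corners are the extreme points of the 1-D projection", {
    set.seed(21)
    V <- matrix(c(0, 0, 0, 5, 5, 5), 2, 3, byrow = TRUE)
    W <- cbind(diag(2), prop.table(matrix(stats::rexp(2 * 48), 2, 48), 2))
    pts <- t(W) %*% V
    rownames(pts) <- paste0("p", 1:50)
    pr <- affineProject(pts, K = 2)
    sv <- sisalFit(pr, K = 2, seed = 1)
    lo <- pts[which.min(pr@projected[, 1]), ]
    hi <- pts[which.max(pr@projected[, 1]), ]
    err <- min(max(abs(sv@vertices - rbind(hi, lo))),
               max(abs(sv@vertices - rbind(lo, hi))))
    expect_lt(err, 1e-6)
})

test_that("a large hinge weight forces the data inside the simplex", {
    fx <- simplexCloud(K = 3, N = 80, ambient = 6, seed = 11)
    pr <- affineProject(fx$points, K = 3)
    sv <- sisalFit(pr, K = 3, tau = 1e4, seed = 1)
    bc <- pseudoProportions(sv, pr@projected)
    expect_gt(min(bc), -1e-6)   # zero hinge: nothing outside
})

test_that("minimum-volume solution agrees with exhaustive search on few points", {
    # 12 noiseless points including the 3 true vertices: brute force over
    # all vertex triples that enclose the cloud, minimal |det| wins
    fx <- simplexCloud(K = 3, N = 12, ambient = 5, seed = 13)
    pr <- affineProject(fx$points, K = 3)
    P <- pr@projected
    combs <- utils::combn(12, 3)
    bestVol <- Inf; bestIdx <- NULL
    for (i in seq_len(ncol(combs))) {
        tri <- P[combs[, i], ]
        A <- rbind(t(tri), 1)
        if (abs(det(A)) < 1e-12) next
        bc <- solve(A, rbind(t(P), 1))
        if (min(bc) >= -1e-9 && abs(det(A)) < bestVol) {
            bestVol <- abs(det(A))
            bestIdx <- combs[, i]
        }
    }
    oracleVerts <- fx$points[bestIdx, ]
    sv <- sisalFit(pr, K = 3, tau = 100, seed = 1)
    expect_lt(alignedVertexError(sv@vertices, oracleVerts), 1e-4)
})

test_that("point order only permutes the recovered corners", {
    fx <- simplexCloud(K = 3, N = 100, ambient = 6, seed = 17)
    pr1 <- affineProject(fx$points, K = 3)
    sv1 <- sisalFit(pr1, K = 3, seed = 1)
    set.seed(1)
    sh <- sample(100)
    pr2 <- affineProject(fx$points[sh, ], K = 3)
    sv2 <- sisalFit(pr2, K = 3, seed = 1)
    expect_lt(alignedVertexError(sv2@vertices, sv1@vertices), 1e-6)
})

test_that("fitted volume never exceeds the initialization volume", {
    fx <- simplexCloud(K = 4, N = 150, ambient = 9, seed = 19)
    pr <- affineProject(fx$points, K = 4)
    sv <- sisalFit(pr, K = 4, seed = 1)
    # objective decrease implies |det Q| grows, i.e. volume shrinks;
    # check directly on the trace
    expect_lte(sv@objectiveTrace[length(sv@objectiveTrace)],
               sv@objectiveTrace[1] + 1e-12)
})

test_that("barycentric coordinates honor vertex, centroid and inversion", {
    fx <- simplexCloud(K = 3, N = 50, ambient = 6, seed = 23)
    pr <- affineProject(fx$points, K = 3)
    sv <- sisalFit(pr, K = 3, tau = 100, seed = 1)
    pv <- sv@projectedVertices
    bc <- pseudoProportions(sv, pv)            # the vertices themselves
    expect_equal(unname(bc), diag(3), tolerance = 1e-8)
    centroid <- matrix(colMeans(pv), 1)
    expect_equal(as.vector(pseudoProportions(sv, centroid)),
                 rep(1 / 3, 3), tolerance = 1e-8)
    # known interior weights invert exactly
    set.seed(24)
    W <- prop.table(matrix(stats::rexp(3 * 20), 3, 20), 2)
    ptsP <- t(W) %*% pv
    expect_equal(unname(pseudoProportions(sv, ptsP)), unname(W),
                 tolerance = 1e-8)
})

test_that("identical seeds reproduce the fit bit for bit", {
    fx <- simplexCloud(K = 3, N = 80, ambient = 5, seed = 29)
    pr <- affineProject(fx$points, K = 3)
    a <- sisalFit(pr, K = 3, seed = 5)
    b <- sisalFit(pr, K = 3, seed = 5)
    expect_identical(a@vertices, b@vertices)
    expect_identical(a@objectiveTrace, b@objectiveTrace)
})
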