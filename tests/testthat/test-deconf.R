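test_that("NNLS agrees with the Lawson-Hanson reference implementation", {
    set.seed(1)
    for (rep in 1:8) {
        m <- sample(5:30, 1)
        k <- sample(2:6, 1)
        A <- matrix(stats::rnorm(m * k), m, k)
        b <- A %*% stats::runif(k, -1, 2) + stats::rnorm(m, sd = 0.2)
        got <- nnlsSolve(A, b)
        ref <- pracma::lsqnonneg(A, as.vector(b))$x
        expect_equal(as.vector(got), ref, tolerance = 1e-9)
    }
})

test_that("K = 1 reduces to the constant-column fit", {
    fx <- noiselessFactorization(L = 20, S = 10, K = 2)
    fit <- deconf(fx$Y, K = 1, maxIter = 5, seed = 1)
    expect_equal(unname(fit@H[1, ]), rep(1, 10))
    expect_equal(unname(fit@M[, 1]), unname(rowMeans(fx$Y)),
                 tolerance = 1e-10)
    expect_equal(fit@frobErr,
                 norm(fx$Y - rowMeans(fx$Y) %o% rep(1, 10), "F"),
                 tolerance = 1e-8)
})

test_that("exact factorizations are reconstructed to high accuracy", {
    fx <- noiselessFactorization(L = 60, S = 30, K = 3)
    fit <- deconf(fx$Y, K = 3, seed = 1)
    expect_lt(fit@frobErr / norm(fx$Y, "F"), 1e-3)
    expect_true(all(fit@M >= 0))
    expect_true(all(abs(colSums(fit@H) - 1) < 1e-8))
    # reconstruction is the comparable quantity (M, H only identified up to
    # positive diagonal rescaling)
    expect_equal(fit@M %*% fit@H, fx$Y,
                 tolerance = 1e-2)
})

test_that("error trace is monotone and frobErr matches the final residual", {
    fx <- noiselessFactorization(L = 40, S = 20, K = 3, seed = 9)
    fit <- deconf(fx$Y, K = 3, maxIter = 50, seed = 2)
    expect_true(all(diff(fit@errTrace) <= 1e-8 * fit@errTrace[1]))
    expect_equal(fit@frobErr, norm(fx$Y - fit@M %*% fit@H, "F"),
                 tolerance = 1e-8)
})

test_that("the exit rule honors both the iteration cap and the tolerance", {
    fx <- noiselessFactorization(L = 30, S = 15, K = 2, seed = 4)
    f1 <- deconf(fx$Y, K = 2, tolA = Inf, seed = 1)
    expect_identical(f1@nIter, 1L)
    expect_true(f1@converged)
    f2 <- deconf(fx$Y, K = 2, maxIter = 1, tolA = 0, seed = 1)
    expect_identical(f2@nIter, 1L)
    expect_false(f2@converged)
    f3 <- deconf(fx$Y, K = 2, maxIter = 7, tolA = 0, seed = 1)
    expect_identical(f3@nIter, 7L)
})

test_that("fits are deterministic under a seed and reject bad K", {
    fx <- noiselessFactorization(L = 30, S = 15, K = 2, seed = 4)
    a <- deconf(fx$Y, K = 2, maxIter = 1, seed = 11)
    b <- deconf(fx$Y, K = 2, maxIter = 1, seed = 11)
    expect_identical(a@M, b@M)
    expect_identical(a@H, b@H)
    c_ <- deconf(fx$Y, K = 2, maxIter = 1, seed = 12)
    expect_false(identical(a@M, c_@M))

    expect_error(deconf(fx$Y, K = 15), "smaller than the number of spots")
    expect_error(deconf(fx$Y, K = 0), "at least 1")
})

test_that("unconstrained fits reach the same reconstruction or better", {
    fx <- noiselessFactorization(L = 40, S = 20, K = 3, seed = 13)
    con <- deconf(fx$Y, K = 3, maxIter = 200, seed = 3)
    un <- deconf(fx$Y, K = 3, maxIter = 200, seed = 3, sumToOne = FALSE)
    expect_lte(un@frobErr, con@frobErr + 1e-6)
    expect_true(all(abs(colSums(un@H) - 1) < 1e-8))  # class contract
})
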