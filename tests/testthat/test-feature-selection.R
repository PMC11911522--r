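test_that("CV ranking matches direct computation and handles edge cases", {
    v <- rbind(g1 = c(1, 1, 1, 9), g2 = c(3, 3, 3, 3), g3 = c(0, 0, 4, 4))
    colnames(v) <- paste0("s", 1:4)
    # independent one-liner oracle
    cv <- apply(v, 1, stats::sd) / rowMeans(v)
    oracle <- names(sort(cv, decreasing = TRUE))[1:2]
    expect_identical(initialFeatures(v, 2), oracle)
    expect_identical(initialFeatures(v, 2)[1], "g1")  # CV 4/3 beats 2/sqrt(3)/2

    # constant gene has CV 0; varying gene wins
    v2 <- rbind(flat = rep(5, 6), vary = c(0, 0, 0, 0, 0, 12))
    expect_identical(initialFeatures(v2, 1), "vary")

    # zero-mean genes are excluded, not divided by zero
    v3 <- rbind(zero = rep(0, 4), ok = c(1, 2, 3, 4))
    expect_message(got <- initialFeatures(v3, 2), "zero-mean")
    expect_identical(got, "ok")

    expect_error(initialFeatures(v, 10), "must not exceed")
})

test_that("proportion-driven scores isolate constructed markers", {
    set.seed(31)
    K <- 3; S <- 40
    H <- prop.table(matrix(stats::rexp(K * S), K, S), 2)
    Y <- rbind(
        mk1 = H[1, ] * 10,          # pure type-1 signal
        mk2 = H[2, ] * 10,
        flat = rep(4, S),           # no differential signal
        mix = colSums(H * c(3, 3, 3)))
    lists <- celltypeSpecificFeatures(Y, H, perType = 4)
    # exact construction: markers first, zero-contrast genes (constant and
    # balanced mix, tie broken by id) in the middle, anti-markers last
    expect_identical(lists[[1]], c("mk1", "flat", "mix", "mk2"))
    expect_identical(lists[[2]], c("mk2", "flat", "mix", "mk1"))

    Hbad <- matrix(1 / K, K, S)
    expect_error(celltypeSpecificFeatures(Y, Hbad, 2), "rank-deficient")
})

test_that("marker blocks are recovered on reference-driven simulations", {
    fx <- simFixture(seed = 33, K = 3, L = 600, spotsPerRegion = 30,
                     hetRate = 0)
    Y <- exprValues(scaleLibrary(fx$sim@Y))
    fit <- deconf(Y, 3, maxIter = 200, seed = 33)
    lists <- celltypeSpecificFeatures(Y, fit@H, perType = 20)
    perm <- alignTypes(fit@H, fx$sim@PTrue)
    rec <- vapply(seq_len(3), function(k)
        mean(lists[[perm[k]]] %in% fx$ref@markerGenes[[k]]), numeric(1))
    expect_true(all(rec >= 0.8))
})

test_that("iterative selection obeys its loop contract", {
    fx <- noiselessFactorization(L = 80, S = 25, K = 3, seed = 35)
    one <- iterateSelection(fx$Y, K = 3, nInit = 60, perType = 15,
                            maxOuter = 1, seed = 1)
    expect_identical(one@nOuterIter, 1L)
    expect_length(one@rmseTrace, 1)

    res <- iterateSelection(fx$Y, K = 3, nInit = 60, perType = 15,
                            maxOuter = 10, seed = 1)
    expect_lt(res@rmseTrace[length(res@rmseTrace)] / mean(fx$Y), 1e-2)
    expect_lt(length(res@genes), 1000)
    expect_true(all(res@genes %in% rownames(fx$Y)))
    expect_true(all(is.finite(res@rmseTrace)))
    if (res@converged) {
        n <- length(res@rmseTrace)
        expect_lte(abs(res@rmseTrace[n] - res@rmseTrace[n - 1]), 1e-4)
    }

    # determinism across the whole loop
    res2 <- iterateSelection(fx$Y, K = 3, nInit = 60, perType = 15,
                             maxOuter = 10, seed = 1)
    expect_identical(res@genes, res2@genes)
    expect_identical(res@rmseTrace, res2@rmseTrace)
})

test_that("selected genes stay under the cap and enrich for true markers", {
    fx <- simFixture(seed = 37, K = 4, L = 3000, spotsPerRegion = 30,
                     hetRate = 0.2)
    res <- iterateSelection(exprValues(scaleLibrary(fx$sim@Y)), K = 4,
                            nInit = 1000, perType = 100, maxOuter = 3,
                            seed = 2)
    expect_lt(length(res@genes), 1000)

    truth <- unlist(fx$ref@markerGenes)
    inSelection <- mean(truth %in% res@genes)
    byChance <- length(res@genes) / 3000
    expect_gte(inSelection, 2 * byChance)
})
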