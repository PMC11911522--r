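test_that("type alignment recovers permutations and matches brute force", {
    set.seed(5)
    P <- prop.table(matrix(stats::rexp(4 * 30), 4, 30), 2)
    expect_identical(alignTypes(P, P), 1:4)

    p0 <- c(3, 1, 4, 2)
    perm <- alignTypes(P[p0, ], P)
    expect_equal(P[p0, ][perm, ], P)

    # noisy K=3 case against an explicit all-permutations oracle
    set.seed(6)
    Pt <- prop.table(matrix(stats::rexp(3 * 40), 3, 40), 2)
    Pe <- prop.table(pmax(Pt[c(2, 3, 1), ] +
                          matrix(stats::rnorm(120, sd = 0.05), 3, 40), 0), 2)
    allPerms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    cm <- stats::cor(t(Pt), t(Pe))
    oracleScores <- vapply(allPerms, function(p)
        sum(cm[cbind(1:3, p)]), numeric(1))
    oracle <- allPerms[[which.max(oracleScores)]]
    expect_equal(alignTypes(Pe, Pt), oracle)
})

test_that("metrics satisfy their identities on identity and disjoint inputs", {
    P <- prop.table(matrix(stats::rexp(3 * 15), 3, 15), 2)
    r <- proportionMetrics(P, P, aligned = TRUE)
    expect_equal(r@mae, 0)
    expect_equal(r@rmse, 0)
    expect_equal(r@jsd, 0)
    expect_equal(r@pcc, 1)

    # disjoint point masses, K=2, S=1 (alignment off: rows as given)
    r2 <- proportionMetrics(matrix(c(0, 1), 2, 1), matrix(c(1, 0), 2, 1),
                            aligned = TRUE)
    expect_equal(r2@mae, 1.0)
    expect_equal(r2@jsd, log(2))
})

test_that("MAE matches an elementwise oracle and never exceeds RMSE", {
    set.seed(8)
    for (rep in 1:5) {
        K <- sample(2:5, 1)
        S <- sample(5:40, 1)
        Pt <- prop.table(matrix(stats::rexp(K * S), K, S), 2)
        Pe <- prop.table(matrix(stats::rexp(K * S), K, S), 2)
        r <- proportionMetrics(Pe, Pt, aligned = TRUE)
        mae <- 0
        for (i in seq_len(K)) for (j in seq_len(S))
            mae <- mae + abs(Pe[i, j] - Pt[i, j])
        expect_equal(r@mae, mae / (S * K), tolerance = 1e-12)
        expect_lte(r@mae, r@rmse)
        expect_true(all(r@perSpotJsd >= 0 & r@perSpotJsd <= log(2) + 1e-12))
    }
})

test_that("metrics are invariant to shared column permutation and JSD symmetric", {
    set.seed(9)
    K <- 3; S <- 25
    Pt <- prop.table(matrix(stats::rexp(K * S), K, S), 2)
    Pe <- prop.table(matrix(stats::rexp(K * S), K, S), 2)
    r1 <- proportionMetrics(Pe, Pt)
    sh <- sample(S)
    r2 <- proportionMetrics(Pe[, sh], Pt[, sh])
    expect_equal(r1@mae, r2@mae)
    expect_equal(r1@rmse, r2@rmse)
    expect_equal(r1@jsd, r2@jsd)
    expect_equal(r1@pcc, r2@pcc)

    expect_equal(proportionMetrics(Pe, Pt, aligned = TRUE)@jsd,
                 proportionMetrics(Pt, Pe, aligned = TRUE)@jsd)
})

test_that("non-stochastic columns are renormalized with a warning", {
    P <- prop.table(matrix(stats::rexp(6), 2, 3), 2)
    expect_warning(r <- proportionMetrics(2 * P, P, aligned = TRUE),
                   "renormalizing")
    expect_equal(r@mae, 0)
    expect_error(proportionMetrics(P, P[, 1:2]), "identical dimensions")
})
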