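test_that("reference construction is seeded and markers are well separated", {
    r1 <- makeReference(K = 2, L = 100, seed = 1)
    r2 <- makeReference(K = 2, L = 100, seed = 1)
    expect_identical(r1@meanProfiles, r2@meanProfiles)
    r3 <- makeReference(K = 2, L = 100, seed = 2)
    expect_false(identical(r1@meanProfiles, r3@meanProfiles))

    m1 <- r1@markerGenes[[1]]
    expect_true(all(r1@meanProfiles[m1, 1] >= 3 * r1@meanProfiles[m1, 2]))

    big <- makeReference(K = 6, L = 2000, seed = 3)
    expect_identical(length(unlist(big@markerGenes)), 120L)
    expect_identical(anyDuplicated(unlist(big@markerGenes)), 0L)

    expect_error(makeReference(K = 4, L = 30), "at least")
})

test_that("heterogeneity limits behave and dominance holds where enforced", {
    ref <- makeReference(K = 4, L = 200, seed = 5)
    s0 <- simulateSpots(ref, nRegions = 3, spotsPerRegion = 20,
                        hetRate = 0, seed = 5)
    expect_false(any(s0@heterogeneityMask))
    dom <- s0@dominantTypeOfRegion[s0@regionOfSpot]
    expect_identical(unname(apply(s0@PTrue, 2, which.max)), dom)

    s1 <- simulateSpots(ref, nRegions = 3, spotsPerRegion = 20,
                        hetRate = 1, seed = 5)
    expect_true(all(s1@heterogeneityMask))
})

test_that("co-occurring type counts stay within the discrete uniform range", {
    ref <- makeReference(K = 6, L = 300, seed = 7)
    sim <- simulateSpots(ref, nRegions = 3, spotsPerRegion = 80,
                         hetRate = 0.3, seed = 7)
    support <- colSums(sim@PTrue > 0)
    expect_true(all(support >= 1 & support <= 6))
    # most spots keep at least two realized types (a drawn type can receive
    # zero cells after rounding, but only rarely)
    expect_gt(mean(support >= 2), 0.8)
})

test_that("the empirical heterogeneous fraction matches the rate", {
    ref <- makeReference(K = 5, L = 200, seed = 9)
    rate <- 0.4
    S <- 300
    sim <- simulateSpots(ref, nRegions = 3, spotsPerRegion = 100,
                         hetRate = rate, seed = 9)
    sd3 <- 3 * sqrt(rate * (1 - rate) / S)
    expect_lt(abs(mean(sim@heterogeneityMask) - rate), sd3)
})

test_that("expression tracks the noiseless mixture and seeds reproduce", {
    ref <- makeReference(K = 4, L = 400, seed = 11)
    sim <- simulateSpots(ref, nRegions = 3, spotsPerRegion = 40,
                         hetRate = 0.2, seed = 11)
    cells <- colSums(sim@PTrue * 0 + 1)  # placeholder to keep dims
    noiseless <- ref@meanProfiles %*% sim@PTrue
    # correlation up to per-spot cell-count scaling
    expect_gt(stats::cor(as.vector(exprValues(sim@Y)),
                         as.vector(noiseless %*%
                             diag(colSums(exprValues(sim@Y)) /
                                  colSums(noiseless)))), 0.9)

    sim2 <- simulateSpots(ref, nRegions = 3, spotsPerRegion = 40,
                          hetRate = 0.2, seed = 11)
    expect_identical(exprValues(sim2@Y), exprValues(sim@Y))
    expect_identical(sim2@heterogeneityMask, sim@heterogeneityMask)
    sim3 <- simulateSpots(ref, nRegions = 3, spotsPerRegion = 40,
                          hetRate = 0.2, seed = 12)
    expect_false(identical(sim3@heterogeneityMask, sim@heterogeneityMask))
})

test_that("invalid simulation arguments are rejected", {
    ref <- makeReference(K = 3, L = 100, seed = 1)
    expect_error(simulateSpots(ref, nRegions = 4), "must not exceed")
    expect_error(simulateSpots(ref, nRegions = 2, spotsPerRegion = 0),
                 "at least 1")
})
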