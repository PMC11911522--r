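test_that("CSV/TSV/MTX round-trips preserve values and identifiers", {
    v <- matrix(c(1.5, 0, 2, 3.25, 4, 0), 3, 2,
                dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
    y <- SpatialExpression(v)
    for (fmt in c("csv", "tsv")) {
        f <- tempfile(fileext = paste0(".", fmt))
        writeMatrix(y, f, fmt)
        y2 <- loadMatrix(f, fmt)
        expect_identical(exprValues(y2), v)
    }
    fm <- tempfile(fileext = ".mtx")
    fg <- tempfile(); fs <- tempfile()
    writeMatrix(y, fm, "mtx", genesPath = fg, spotsPath = fs)
    y3 <- loadMatrix(fm, "mtx", genesPath = fg, spotsPath = fs)
    expect_equal(exprValues(y3), v)
})

test_that("missing cells load as zero and invalid inputs are rejected", {
    f <- tempfile(fileext = ".csv")
    writeLines(c("gene_id,s1,s2", "gA,1.5,", "gB,2,3"), f)
    y <- loadMatrix(f, "csv")
    expect_identical(exprValues(y)["gA", "s2"], 0)

    fneg <- tempfile(fileext = ".csv")
    writeLines(c("gene_id,s1", "gA,-1"), fneg)
    expect_error(loadMatrix(fneg, "csv"), "negative entry")

    fdup <- tempfile(fileext = ".csv")
    writeLines(c("gene_id,s1", "gA,1", "gA,2"), fdup)
    expect_error(loadMatrix(fdup, "csv"), "duplicate gene id: gA")

    expect_error(loadMatrix(tempfile(), "csv"), "no such file")
    expect_error(loadMatrix(tempfile(), "mtx"), "companion")
    expect_error(SpatialExpression(matrix(-1, 1, 1)), "negative")
})

test_that("log-normalization scales spots to a common total then log1p", {
    v <- matrix(c(10, 10, 0, 5), 2, 2,
                dimnames = list(c("gA", "gB"), c("s1", "s2")))
    ln <- logNormalize(seFrom(v), scale = 20)
    expect_equal(exprValues(ln)[, "s1"], c(gA = log1p(10), gB = log1p(10)))
    expect_equal(round(exprValues(ln)["gA", "s1"], 4), 2.3979)
    expect_identical(exprValues(ln)["gA", "s2"], 0)  # zero stays zero
    expect_true(isLogNormalized(ln))
    expect_error(logNormalize(ln), "already")

    single <- seFrom(matrix(c(0, 7), 2, 1))
    ls <- logNormalize(single, scale = 100)
    expect_equal(unname(exprValues(ls)[, 1]), c(0, log1p(100)))

    zerocol <- seFrom(matrix(c(1, 0, 0, 0), 2, 2))
    expect_error(logNormalize(zerocol), "zero total")
})

test_that("gene filter applies strict detection-fraction bounds", {
    S <- 100
    fr <- c(0, 0.05, 0.06, 0.5, 0.99, 1.0)
    v <- t(vapply(fr, function(f)
        c(rep(1, round(f * S)), rep(0, S - round(f * S))), numeric(S)))
    rownames(v) <- paste0("g", seq_along(fr))
    y <- seFrom(v)
    kept <- filterGenes(y)
    expect_identical(rownames(kept), c("g3", "g4", "g5"))
    # idempotence
    expect_identical(exprValues(filterGenes(kept)), exprValues(kept))
    expect_error(filterGenes(y, minFrac = 0.999, maxFrac = 1),
                 "no gene passes")
})

test_that("row normalization is exact, invertible and validated", {
    y <- seFrom(matrix(c(2, 2, 4), 1, 3))
    nm <- rowNormalize(y)
    expect_equal(unname(nm@values[1, ]), c(0.25, 0.25, 0.5))
    expect_equal(unname(nm@rowScale), 8)

    already <- matrix(c(0.3, 0.7), 1, 2)
    nm2 <- rowNormalize(already)
    expect_equal(nm2@values, already)
    expect_equal(nm2@rowScale, 1)

    set.seed(7)
    v <- matrix(stats::rexp(50 * 20), 50, 20) + 1e-3
    nm3 <- rowNormalize(v)
    expect_true(all(abs(rowSums(nm3@values) - 1) < 1e-10))
    expect_equal(diag(nm3@rowScale) %*% nm3@values, v, tolerance = 1e-12)

    expect_error(rowNormalize(matrix(c(0, 1, 0, 2), 2, 2)),
                 "non-positive row sum")
})

test_that("coordinates survive loading and accessors", {
    v <- matrix(1:4, 2, 2, dimnames = list(c("gA", "gB"), c("s1", "s2")))
    f <- tempfile(fileext = ".tsv")
    fc <- tempfile(fileext = ".tsv")
    writeMatrix(seFrom(v), f, "tsv")
    writeLines(c("spot_id\tx\ty", "s2\t3\t4", "s1\t1\t2"), fc)
    y <- loadMatrix(f, "tsv", coordsPath = fc)
    co <- spotCoords(y)
    expect_equal(co["s1", ], c(x = 1, y = 2))
    expect_equal(co["s2", ], c(x = 3, y = 4))
    expect_null(spotCoords(loadMatrix(f, "tsv")))
})
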