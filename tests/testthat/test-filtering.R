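test_that("cell-level genotype gates follow depth, quality and AF", {
    expect_true(is.na(callGenotypes(depth = 9, gq = 99, af = 1.0)))
    expect_true(is.na(callGenotypes(depth = 100, gq = 29, af = 1.0)))
    expect_identical(callGenotypes(100, 99, 0.34), 0L)
    expect_identical(callGenotypes(100, 99, 0.35), 1L)
    expect_identical(callGenotypes(100, 99, 0.50), 1L)
    expect_identical(callGenotypes(100, 99, 0.89), 1L)
    expect_identical(callGenotypes(100, 99, 0.90), 2L)
    # matrix input keeps shape
    m <- callGenotypes(matrix(100, 2, 2), matrix(99, 2, 2),
                       matrix(c(0, 0.5, 0.95, 0.2), 2, 2))
    expect_identical(dim(m), c(2L, 2L))
    expect_identical(as.vector(m), c(0L, 1L, 2L, 0L))
})

test_that("each designed filter violation removes exactly its variant", {
    fx <- filterFixture()
    rep <- applyVariantFilters(fx$x)
    expect_identical(rep@surviving, "clean")
    expect_true("min3_cells" %in% failedFilters(rep, "min3"))
    expect_true("not_synonymous" %in% failedFilters(rep, "syn"))
    expect_true("not_homopolymer" %in% failedFilters(rep, "hp"))
    expect_true("proximity_300bp" %in% failedFilters(rep, "prox"))
    expect_true("proximity_300bp" %in% failedFilters(rep, "germ"))
    expect_true("not_germline" %in% failedFilters(rep, "germ"))
    expect_true("min6_cells" %in% failedFilters(rep, "min6"))
    expect_true("hom_cell_present" %in% failedFilters(rep, "hom"))
    expect_length(failedFilters(rep, "clean"), 0)
})

test_that("surviving set equals the conjunction of independent predicates", {
    fx <- filterFixture()
    d <- applyVariantFilters(fx$x)@decisions
    fcols <- setdiff(colnames(d), c("variant", "n_mutated", "pass"))
    expect_identical(d$pass, Reduce(`&`, d[, fcols]))
    # permuting the variant rows never changes the surviving set
    perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
    rep2 <- applyVariantFilters(fx$x[perm, ])
    expect_setequal(rep2@surviving, "clean")
})

test_that("co-occurring variants are exempt from the 6-cell filter", {
    # two variants mutated together in 4 cells each (5 mutated cells in
    # total): below the strict 6-cell cutoff but co-occurring in >= 3
    g <- matrix(0L, 2, 20, dimnames = list(c("vA", "vB"), NULL))
    g[, 1:4] <- 1L
    g[1, 5] <- 2L; g[2, 6] <- 2L        # one HOM cell each
    x <- makeMatrix(g)
    expect_identical(nrow(cooccurringPairs(x)), 1L)
    rep <- applyVariantFilters(x)
    expect_setequal(rep@surviving, c("vA", "vB"))
    # without the exemption they fail: raise the co-occurrence cutoff
    rep2 <- applyVariantFilters(
        x, config = runConfig(filter = list(cooccur_min_cells = 10L)))
    expect_length(rep2@surviving, 0)
    expect_true("min6_cells" %in% failedFilters(rep2, "vA"))
})

test_that("pseudobulk VAF is zygosity-aware", {
    g <- matrix(c(rep(1L, 30), rep(2L, 10), rep(0L, 60)), 1)
    expect_equal(unname(pseudobulkVAF(makeMatrix(g))), 25)
    expect_equal(unname(pseudobulkVAF(makeMatrix(matrix(1L, 1, 40)))), 50)
    expect_equal(unname(pseudobulkVAF(makeMatrix(matrix(2L, 1, 40)))), 100)
    # algebraic identity: 50 * mutated fraction + 50 * HOM fraction
    set.seed(1)
    for (i in 1:20) {
        g <- matrix(sample(c(0L, 1L, 2L, NA), 50, replace = TRUE), 1)
        if (all(is.na(g))) next
        v <- unname(pseudobulkVAF(makeMatrix(g)))
        inf <- g[!is.na(g)]
        expect_equal(v, 50 * mean(inf >= 1) + 50 * mean(inf == 2))
        expect_gte(v, 0); expect_lte(v, 100)
    }
    # no informative cells -> not assessable
    expect_true(is.na(pseudobulkVAF(makeMatrix(matrix(NA_integer_, 1, 5)))))
})

test_that("panel uniformity counts amplicons near the panel mean", {
    expect_equal(panelUniformity(rep(500, 12))$uniformity, 1)
    cov <- c(rep(1000, 7), rep(10, 3))   # 0.2 * mean = 141.4
    u <- panelUniformity(cov)
    expect_equal(u$uniformity, 0.7)
    expect_true(u$flagged)
    expect_false(panelUniformity(rep(500, 12))$flagged)
    expect_error(panelUniformity(numeric(0)), "empty")
})

test_that("force-calling bypasses variant filters but not cell QC", {
    fx <- filterFixture()
    fc <- forceCall(fx$x, "min6")        # fails the 6-cell filter
    expect_true(fc$forced)
    expect_equal(fc$vaf, unname(pseudobulkVAF(fx$x, "min6")))
    expect_error(forceCall(fx$x, "SETBP1.T1078M"), "not in panel")
    # bypass is a no-op for a variant passing all filters anyway
    fc2 <- forceCall(fx$x, "clean")
    expect_equal(fc2$vaf, unname(pseudobulkVAF(fx$x, "clean")))
    expect_identical(unname(fc2$genotypes),
                     unname(genotypes(fx$x)["clean", ]))
})
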