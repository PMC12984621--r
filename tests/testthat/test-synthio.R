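test_that("config validation rejects malformed cohorts", {
    expect_error(targetSelectionCohort(ado_rate = 1.5), "probabilities")
    cfg <- targetSelectionCohort()
    p <- cfg$patients[[1]]
    p$clones[[2]]$parent <- "nonexistent"
    expect_error(cohortConfig(list(p)), "unknown parent")
    p <- cfg$patients[[1]]
    p$clones[[1]]$diagnosis_fraction <- 0.9
    expect_error(cohortConfig(list(p)), "sums")
})

test_that("without noise every cell carries its clone genotype exactly", {
    cfg <- targetSelectionCohort(ado_rate = 0, missing_rate = 0)
    run <- simulateMultiplexRun(cfg, 400, "diagnosis", seed = 1)
    g <- genotypes(somaticRows(run$matrix))
    expect_false(anyNA(g))
    gt_tab <- scMRD:::.cloneGtTable(cfg, rownames(g))
    key <- paste0("P1/", run$truth$clone)
    for (i in seq_len(ncol(g)))
        expect_identical(unname(g[, i]), unname(gt_tab[key[i], ]))
})

test_that("a ref-loss LOH clone is homozygous-alt in all its cells", {
    cfg <- targetSelectionCohort(missing_rate = 0.02)
    run <- simulateMultiplexRun(cfg, 1000, "diagnosis", seed = 3)
    leuk <- cfg$patients[[1]]$planted$leukemic
    cells <- run$truth$barcode[run$truth$clone == "leuk2"]
    g <- genotypes(run$matrix)[leuk, cells]
    expect_true(all(g[!is.na(g)] == 2L))
})

test_that("doublet fraction stays in the exact binomial interval", {
    cfg <- defaultCohortConfig(doublet_rate = 0.05)
    run <- simulateMultiplexRun(cfg, 10000, "diagnosis", seed = 19)
    n_dbl <- sum(run$truth$is_doublet)
    ci <- qbinom(c(0.005, 0.995), 10000, 0.05)
    expect_gte(n_dbl, ci[1]); expect_lte(n_dbl, ci[2])
    # doublets carry the union of their two components' alleles
    expect_true(all(!is.na(run$truth$patient2[run$truth$is_doublet])))
})

test_that("clone fractions converge to the configured values", {
    cfg <- targetSelectionCohort()
    run <- simulateMultiplexRun(cfg, 20000, "diagnosis", seed = 23)
    frac <- table(run$truth$clone) / 20000
    expect_equal(unname(frac[["leuk1"]]), 0.35, tolerance = 0.05)
    expect_equal(unname(frac[["leuk2"]]), 0.30, tolerance = 0.05)
    expect_equal(unname(frac[["CH"]]), 0.25, tolerance = 0.05)
})

test_that("identical seeds reproduce identical cohorts", {
    cfg <- defaultCohortConfig()
    r1 <- simulateMultiplexRun(cfg, 300, "diagnosis", seed = 77)
    r2 <- simulateMultiplexRun(cfg, 300, "diagnosis", seed = 77)
    expect_identical(genotypes(r1$matrix), genotypes(r2$matrix))
    expect_identical(antibodyCounts(r1$matrix),
                     antibodyCounts(r2$matrix))
    expect_identical(r1$truth, r2$truth)
    r3 <- simulateMultiplexRun(cfg, 300, "diagnosis", seed = 78)
    expect_false(identical(genotypes(r1$matrix), genotypes(r3$matrix)))
})

test_that("ddPCR simulation tracks the true VAF", {
    traj <- data.frame(day = c(30, 90), tissue = "PB",
                       true_vaf = c(0, 0))
    s <- simulateDdpcrSeries(traj, assay = list(lod = 0.01, fp_rate = 0),
                             seed = 1)
    expect_equal(mrdSamples(s)$vaf, c(0, 0))
    # 50% VAF measured within the exact binomial 99% CI
    traj2 <- data.frame(day = 30, tissue = "PB", true_vaf = 50)
    s2 <- simulateDdpcrSeries(traj2, assay = list(lod = 0.01),
                              replicates = 1,
                              dna_copies_per_well = 10000, seed = 2)
    ci <- qbinom(c(0.005, 0.995), 20000, 0.5) / 20000 * 100
    v <- mrdSamples(s2)$vaf
    expect_gte(v, ci[1]); expect_lte(v, ci[2])
    expect_error(simulateDdpcrSeries(
        data.frame(day = c(90, 30), tissue = "PB", true_vaf = 0),
        assay = list(lod = 0.01)), "strictly increasing")
})

test_that("a simulated relapse trajectory is called at the true day", {
    traj <- relapseTrajectory(base_vaf = 0.05, relapse_day = 210)
    s <- simulateDdpcrSeries(traj, assay = list(lod = 0.01), seed = 4)
    call <- callRelapse(s)
    expect_true(call@relapse)
    expect_equal(call@day, attr(traj, "true_relapse_day"))
})

test_that("EC-NGS count simulation matches its oracles", {
    z <- simulateEcngsCounts(0, 10000, 0, seed = 1, n_sites = 5)
    expect_true(all(z$supporting_fwd == 0 & z$supporting_rev == 0))
    # error-only: mean supporting ~ 1 per strand at 1e-4 x 10,000
    e <- simulateEcngsCounts(0, 10000, 1e-4, dispersion = 1e-5,
                             seed = 2, n_sites = 2000)
    expect_equal(mean(c(e$supporting_fwd, e$supporting_rev)), 1,
                 tolerance = 0.15)
    # 0.1% VAF: expected supporting ~ 10 per strand
    v <- simulateEcngsCounts(0.001, 10000, 0, seed = 3, n_sites = 2000)
    expect_equal(mean(c(v$supporting_fwd, v$supporting_rev)), 10,
                 tolerance = 0.05 * 10)
    expect_true(all(v$uao == v$supporting_fwd + v$supporting_rev))
})
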