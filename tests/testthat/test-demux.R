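test_that("profile database holds singlet and pairwise doublet profiles", {
    pr <- rbind(A = c(0L, 1L, 2L), B = c(1L, 1L, 0L), C = c(2L, 0L, 1L))
    db <- buildProfileDatabase(pr)
    expect_equal(sum(db@kind == "singlet"), 3)
    expect_equal(sum(db@kind == "doublet"), 3)   # C(3,2)
    # het + hom-alt -> expected dosage 1.5
    expect_equal(unname(db@expected["A+C", 1]), 1)
    expect_equal(unname(db@expected["A+B", 3]), 1)
    pr2 <- rbind(A = c(0L, 1L), B = c(0L, 1L))
    expect_warning(buildProfileDatabase(pr2), "indistinguishable")
    expect_error(buildProfileDatabase(pr[1, , drop = FALSE]),
                 "at least 2")
})

test_that("perfect-match cells score to their patient with 0 discrepancies", {
    set.seed(5)
    pr <- matrix(sample(0:2, 3 * 50, replace = TRUE, prob = c(.4, .4, .2)),
                 3, 50, dimnames = list(c("A", "B", "C"),
                                        paste0("snp", 1:50)))
    db <- buildProfileDatabase(pr)
    sc <- scoreCell(setNames(pr["A", ], colnames(pr)), db)
    expect_identical(sc$best_match, "A")
    expect_identical(sc$n_discrepancies, 0L)
    expect_identical(sc$kind, "singlet")
})

test_that("a mixture cell is assigned to the doublet profile", {
    set.seed(9)
    pr <- matrix(sample(0:2, 2 * 60, replace = TRUE), 2, 60,
                 dimnames = list(c("A", "B"), paste0("snp", 1:60)))
    db <- buildProfileDatabase(pr)
    # observed genotype = called mixture of A and B allele dosages
    d <- (pr["A", ] + pr["B", ]) / 2
    obs <- as.integer(floor(d + 0.5 * rbinom(60, 1, 0.5)))
    obs <- pmin(pmax(obs, 0L), 2L)
    obs[abs(d - round(d)) < 1e-9] <- as.integer(d[abs(d - round(d)) < 1e-9])
    sc <- scoreCell(setNames(obs, colnames(pr)), db)
    # brute-force likelihood dominance over all profiles
    eps <- runConfig()$demux$error_rate
    ll <- vapply(rownames(db@expected), function(p)
        bruteLogLik(obs, db@expected[p, ], eps), numeric(1))
    expect_identical(sc$best_match, names(which.max(ll)))
    expect_identical(sc$best_match, "A+B")
    expect_equal(unname(sc$log_likelihood), unname(max(ll)))
})

test_that("permuting SNP order never changes assignments", {
    set.seed(21)
    pr <- matrix(sample(0:2, 3 * 40, replace = TRUE), 3, 40,
                 dimnames = list(c("A", "B", "C"), paste0("snp", 1:40)))
    db <- buildProfileDatabase(pr)
    gt <- matrix(sample(c(0:2, NA), 40 * 30, replace = TRUE), 40, 30,
                 dimnames = list(paste0("snp", 1:40),
                                 paste0("cell", 1:30)))
    s1 <- scoreCells(gt, db)
    s2 <- scoreCells(gt[sample(40), ], db)
    expect_identical(s1$best_match, s2$best_match)
    expect_identical(s1$n_discrepancies, s2$n_discrepancies)
})

test_that("cell-removal rules fire on the documented thresholds", {
    mk <- function(n_geno, n_disc, kind = "singlet", amb = FALSE)
        data.frame(barcode = "b", best_match = "A", kind = kind,
                   n_genotyped_snps = n_geno, n_discrepancies = n_disc,
                   discrepancy_fraction = n_disc / n_geno,
                   log_likelihood = -1, ambiguous = amb)
    total <- 100
    # genotyped in 25% of the database SNPs: removed
    qc <- applyDemuxQC(mk(25, 0), total)
    expect_identical(qc$decision, "remove")
    expect_match(qc$reason, "low genotyping")
    # 9 discrepancies over 40 SNPs (22.5%), 40% genotyped of 100: kept
    expect_identical(applyDemuxQC(mk(40, 9), total)$decision, "keep")
    # 10 discrepancies over 100 SNPs: removed
    qc <- applyDemuxQC(mk(100, 10), total)
    expect_identical(qc$decision, "remove")
    expect_match(qc$reason, "discrepanc")
    # 30% discrepancy fraction: removed
    expect_identical(applyDemuxQC(mk(30, 9), total)$decision, "remove")
    # doublet match and ambiguity remove regardless
    expect_match(applyDemuxQC(mk(90, 0, kind = "doublet"), total)$reason,
                 "doublet")
    expect_match(applyDemuxQC(mk(90, 0, amb = TRUE), total)$reason,
                 "ambiguous")
    # zero genotyped SNPs
    qc <- applyDemuxQC(
        data.frame(barcode = "b", best_match = NA, kind = "none",
                   n_genotyped_snps = 0L, n_discrepancies = NA,
                   discrepancy_fraction = NA, log_likelihood = NA,
                   ambiguous = FALSE), total)
    expect_match(qc$reason, "no informative SNPs")
})

test_that("demultiplexing conserves barcodes and recovers truth", {
    cfg <- defaultCohortConfig(ado_rate = 0, missing_rate = 0,
                               doublet_rate = 0)
    run <- simulateMultiplexRun(cfg, 600, "diagnosis", seed = 2)
    db <- buildProfileDatabase(run$profiles)
    dx <- demultiplexRun(run$matrix, db)
    assigned <- sum(vapply(dx$partitions, ncol, integer(1)))
    expect_equal(assigned + nrow(dx$removed), 600)
    # noise-free: partition equals the truth partition exactly
    for (p in names(dx$partitions)) {
        want <- run$truth$barcode[run$truth$patient == p]
        expect_setequal(colnames(dx$partitions[[p]]), want)
    }
    # with doublets, conservation still holds
    cfg2 <- defaultCohortConfig(doublet_rate = 0.05)
    run2 <- simulateMultiplexRun(cfg2, 800, "diagnosis", seed = 3)
    dx2 <- demultiplexRun(run2$matrix, buildProfileDatabase(run2$profiles))
    expect_equal(sum(vapply(dx2$partitions, ncol, integer(1))) +
                 nrow(dx2$removed), 800)
    # empty input
    empty <- demultiplexRun(run$matrix[, 0], db)
    expect_length(empty$partitions, 0)
})
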