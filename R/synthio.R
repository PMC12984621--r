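## Run expr with a temporary RNG state seeded from `seed`, restoring the
## caller's state afterwards. All generator randomness flows through this.
withSeed <- function(seed, expr) {
    has_old <- exists(".Random.seed", envir = globalenv())
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has_old) assign(".Random.seed", old,
                                envir = globalenv()))
    set.seed(seed)
    expr
}

#' The 17-marker AML surface-protein panel
#'
#' Marker names of the antibody-oligonucleotide panel emulated by the
#' generator.
#' @return character vector of 17 marker names.
#' @export
amlMarkerPanel <- function() {
    c("CD3", "CD7", "CD11b", "CD13", "CD14", "CD19", "CD33", "CD34",
      "CD38", "CD45", "CD45RA", "CD56", "CD64", "CD90", "CD117",
      "CD123", "HLA-DR")
}

#' Expected antibody-count profiles for common cell states
#'
#' \code{markerMeans} builds a mean-count vector over the panel: all
#' markers at \code{base} except those named in \code{...}.
#' \code{normalMarkerMeans} is a maturing-myeloid normal profile;
#' \code{blastMarkerMeans} an immature CD34+/CD117+ blast profile with
#' cross-lineage CD7 expression (a classic leukemia-associated
#' immunophenotype).
#'
#' @param base baseline mean count for unlisted markers.
#' @param ... named marker means overriding the baseline.
#' @return named numeric vector over \code{\link{amlMarkerPanel}}.
#' @export
markerMeans <- function(base = 12, ...) {
    mm <- setNames(rep(base, 17), amlMarkerPanel())
    ov <- c(...)
    mm[names(ov)] <- ov
    mm
}

#' @rdname markerMeans
#' @export
normalMarkerMeans <- function() {
    markerMeans(CD45 = 400, CD33 = 180, CD13 = 150, CD38 = 120,
                CD64 = 90, CD14 = 70, CD11b = 130, `HLA-DR` = 160)
}

#' @rdname markerMeans
#' @export
blastMarkerMeans <- function() {
    markerMeans(CD34 = 350, CD117 = 300, CD7 = 220, CD38 = 100,
                CD123 = 90, `HLA-DR` = 140, CD45 = 60, CD33 = 90)
}

#' Assemble and validate a synthetic-cohort configuration
#'
#' A cohort holds per-patient clone trees over somatic variants plus the
#' global noise parameters. Each patient is a list with \code{id},
#' \code{variants} (data.frame: \code{id}, \code{chrom}, \code{pos},
#' \code{ref}, \code{alt}, \code{gene}, \code{protein_change},
#' \code{synonymous}, \code{homopolymer}, \code{pop_af},
#' \code{germline_flag}), \code{clones} (list of clones, each with
#' \code{id}, \code{parent} (\code{"WT"} for roots), \code{gt} named
#' integer genotype vector over the patient's variants, optional
#' \code{loh} data.frame, \code{stage}, \code{markers} named mean vector,
#' \code{diagnosis_fraction}, \code{remission_fraction}),
#' \code{normal_markers}, and optionally \code{planted} (named list
#' tagging the planted leukemic / clonal-hematopoiesis / LOH-lost variant
#' ids used as test oracles).
#'
#' @param patients list of patient configurations.
#' @param n_germline_snps germline SNPs shared by all patients.
#' @param ado_rate per-allele allelic-dropout probability.
#' @param missing_rate per cell-locus missing probability.
#' @param doublet_rate per emitted barcode doublet probability.
#' @param ab_dispersion negative-binomial size of antibody counts.
#' @return validated cohort configuration (class \code{"CohortConfig"}).
#' @export
cohortConfig <- function(patients, n_germline_snps = 50, ado_rate = 0.05,
                         missing_rate = 0.01, doublet_rate = 0.05,
                         ab_dispersion = 10) {
    probs <- c(ado_rate, missing_rate, doublet_rate)
    if (any(probs < 0 | probs > 1))
        stop("rates must be probabilities in [0, 1]")
    for (p in patients) {
        ids <- vapply(p$clones, `[[`, character(1), "id")
        if (anyDuplicated(ids)) stop("duplicate clone ids in ", p$id)
        for (cl in p$clones) {
            if (!identical(cl$parent, "WT") && !cl$parent %in% ids)
                stop("clone ", cl$id, " of ", p$id,
                     " has unknown parent ", cl$parent)
            if (!all(names(cl$gt) %in% p$variants$id))
                stop("clone genotype over unknown variants in ", p$id)
        }
        ## walk to root: rooted tree, no cycles
        for (cl in p$clones) {
            seen <- character(0); cur <- cl$id
            while (!identical(cur, "WT")) {
                if (cur %in% seen) stop("clone tree cycle in ", p$id)
                seen <- c(seen, cur)
                cur <- p$clones[[match(cur, ids)]]$parent
            }
        }
        for (tp in c("diagnosis_fraction", "remission_fraction")) {
            s <- sum(vapply(p$clones, `[[`, numeric(1), tp))
            if (s > 1 + 1e-9)
                stop(tp, " of ", p$id, " sums to ", s, " (> 1)")
        }
    }
    structure(list(patients = patients,
                   n_germline_snps = n_germline_snps,
                   ado_rate = ado_rate, missing_rate = missing_rate,
                   doublet_rate = doublet_rate,
                   ab_dispersion = ab_dispersion),
              class = "CohortConfig")
}

## one synthetic AML patient: a clonal-hematopoiesis branch plus a
## two-clone leukemia in which the founder variant undergoes ref-loss LOH
## (becoming homozygous) and a passenger is lost by alt-loss LOH in the
## advanced subclone.
.defaultPatient <- function(id, chrom_offset = 0) {
    vid <- function(g) paste0(id, ":", g)
    variants <- data.frame(
        id = vid(c("DNMT3A.G707D", "IDH2.R140Q", "TET2.I1139L",
                   "IDH1.R132C")),
        chrom = paste0("chr", 2 + chrom_offset),
        pos = c(25467000, 25469000, 25471000, 25473000) + chrom_offset,
        ref = c("C", "G", "A", "C"), alt = c("T", "A", "C", "T"),
        gene = c("DNMT3A", "IDH2", "TET2", "IDH1"),
        protein_change = c("p.G707D", "p.R140Q", "p.I1139L", "p.R132C"),
        synonymous = FALSE, homopolymer = FALSE, pop_af = 0,
        germline_flag = FALSE, stringsAsFactors = FALSE)
    gt0 <- setNames(rep(0L, 4), variants$id)
    gt <- function(...) { g <- gt0; ov <- c(...); g[names(ov)] <-
        as.integer(ov); g }
    leuk <- vid("DNMT3A.G707D"); sub <- vid("IDH2.R140Q")
    ch <- vid("TET2.I1139L"); loh <- vid("IDH1.R132C")
    clones <- list(
        list(id = "CH", parent = "WT",
             gt = gt(setNames(1L, ch)),
             stage = "clonal hematopoiesis",
             markers = normalMarkerMeans(),
             diagnosis_fraction = 0.25, remission_fraction = 0.20),
        list(id = "leuk1", parent = "WT",
             gt = gt(setNames(c(1L, 1L), c(leuk, loh))),
             stage = "immature blast",
             markers = blastMarkerMeans(),
             diagnosis_fraction = 0.35, remission_fraction = 0),
        list(id = "leuk2", parent = "leuk1",
             gt = gt(setNames(c(2L, 0L, 1L), c(leuk, loh, sub))),
             loh = data.frame(variant = c(leuk, loh),
                              lost_allele = c("ref", "alt")),
             stage = "immature blast",
             markers = blastMarkerMeans(),
             diagnosis_fraction = 0.30, remission_fraction = 0))
    list(id = id, variants = variants, clones = clones,
         normal_markers = normalMarkerMeans(),
         planted = list(leukemic = leuk, ch = ch, loh_lost = loh,
                        subclonal = sub))
}

#' Default synthetic cohorts
#'
#' \code{defaultCohortConfig} builds the standard multi-patient multiplex
#' scenario (3 patients by default, 5\% doublets, 5\% per-allele ADO).
#' \code{targetSelectionCohort} is the single-patient target-selection
#' scenario used for parameter-recovery studies: one planted
#' leukemia-specific variant (cleared at remission, carried only by
#' immature aberrant clones, with a ref-loss LOH subclone), one persistent
#' clonal-hematopoiesis variant, and one variant lost by alt-loss LOH in
#' the advanced subclone.
#'
#' @param n_patients number of multiplexed patients.
#' @param ... overrides passed to \code{\link{cohortConfig}}.
#' @return a \code{CohortConfig}.
#' @export
defaultCohortConfig <- function(n_patients = 3, ...) {
    pts <- lapply(seq_len(n_patients), function(i)
        .defaultPatient(paste0("P", i), chrom_offset = i - 1))
    cohortConfig(pts, ...)
}

#' @rdname defaultCohortConfig
#' @export
targetSelectionCohort <- function(...) {
    args <- list(patients = list(.defaultPatient("P1")),
                 doublet_rate = 0)
    over <- list(...)
    args[names(over)] <- over
    do.call(cohortConfig, args)
}

## genotype lookup matrix (patient:clone x all variants) incl. the normal
## ("WT") state of each patient
.cloneGtTable <- function(config, var_ids) {
    rows <- list()
    for (p in config$patients) {
        base <- setNames(rep(0L, length(var_ids)), var_ids)
        rows[[paste0(p$id, "/WT")]] <- base
        for (cl in p$clones) {
            g <- base
            g[names(cl$gt)] <- cl$gt
            rows[[paste0(p$id, "/", cl$id)]] <- g
        }
    }
    do.call(rbind, rows)
}

## marker-mean lookup (patient:clone x markers)
.cloneMarkerTable <- function(config) {
    rows <- list()
    for (p in config$patients) {
        rows[[paste0(p$id, "/WT")]] <- p$normal_markers
        for (cl in p$clones)
            rows[[paste0(p$id, "/", cl$id)]] <- cl$markers
    }
    do.call(rbind, rows)
}

#' Simulate a multiplexed single-cell DNA + protein run
#'
#' Emits the requested number of barcodes from the configured patients:
#' each barcode is a doublet with probability \code{doublet_rate} (its two
#' component cells drawn independently, allele observations summed before
#' genotype calling), otherwise a singlet. Component cells draw a clone
#' from the patient's stage-specific clone fractions (remainder = normal
#' cells). Heterozygous alleles drop independently with \code{ado_rate},
#' so het sites can appear homozygous-alt or wildtype; entries are
#' additionally set missing with \code{missing_rate}. Antibody counts are
#' negative-binomial around the clone's marker means. Germline-SNP
#' genotypes (shared locus set, per-locus allele frequencies 0.1--0.5,
#' Hardy-Weinberg per patient) occupy the \code{germline_snp} rows.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param n_barcodes number of emitted barcodes.
#' @param timepoint \code{"diagnosis"} or \code{"remission"}, either a
#'   single value or named per patient.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param patient_weights sampling weights over patients (default equal).
#' @return list with \code{matrix} (a \linkS4class{CellGenotypeMatrix}
#'   with antibody counts in \code{altExp}), \code{profiles} (patients x
#'   germline-SNP genotype matrix), \code{truth} (per-barcode labels:
#'   patient, clone, doublet partner, doublet flag) and \code{planted}
#'   (per-patient planted-variant tags).
#' @export
simulateMultiplexRun <- function(config, n_barcodes = 5000,
                                 timepoint = "diagnosis", seed = 1,
                                 patient_weights = NULL) {
    stopifnot(inherits(config, "CohortConfig"))
    withSeed(seed, {
        pts <- vapply(config$patients, `[[`, character(1), "id")
        if (length(timepoint) == 1)
            timepoint <- setNames(rep(timepoint, length(pts)), pts)
        if (is.null(patient_weights))
            patient_weights <- setNames(rep(1, length(pts)), pts)

        nsnp <- config$n_germline_snps
        maf <- runif(nsnp, 0.1, 0.5)
        profiles <- matrix(rbinom(length(pts) * nsnp, 2,
                                  rep(maf, each = length(pts))),
                           nrow = length(pts),
                           dimnames = list(pts, paste0("snp", seq_len(nsnp))))

        var_tab <- do.call(rbind, lapply(config$patients, `[[`, "variants"))
        var_ids <- var_tab$id
        gt_tab <- .cloneGtTable(config, var_ids)
        mk_tab <- .cloneMarkerTable(config)

        drawCells <- function(n) {
            pat <- sample(pts, n, replace = TRUE, prob = patient_weights)
            key <- character(n)
            for (p in pts) {
                idx <- which(pat == p)
                pc <- config$patients[[match(p, pts)]]
                fr_field <- paste0(timepoint[p], "_fraction")
                fr <- vapply(pc$clones, `[[`, numeric(1), fr_field)
                labs <- c(vapply(pc$clones, `[[`, character(1), "id"),
                          "WT")
                key[idx] <- paste0(p, "/",
                    sample(labs, length(idx), replace = TRUE,
                           prob = c(fr, 1 - sum(fr))))
            }
            key
        }

        is_dbl <- runif(n_barcodes) < config$doublet_rate
        cell1 <- drawCells(n_barcodes)
        cell2 <- rep(NA_character_, n_barcodes)
        cell2[is_dbl] <- drawCells(sum(is_dbl))

        L <- nsnp + length(var_ids)
        patOf <- sub("/.*", "", cell1)
        ## alt dosage per locus per barcode (component 1)
        alt <- rbind(t(profiles[patOf, , drop = FALSE]),
                     t(gt_tab[cell1, , drop = FALSE]))
        ref <- 2L - alt
        if (any(is_dbl)) {
            p2 <- sub("/.*", "", cell2[is_dbl])
            alt2 <- rbind(t(profiles[p2, , drop = FALSE]),
                          t(gt_tab[cell2[is_dbl], , drop = FALSE]))
            alt[, is_dbl] <- alt[, is_dbl] + alt2
            ref[, is_dbl] <- ref[, is_dbl] + (2L - alt2)
        }
        ## per-allele dropout
        a <- config$ado_rate
        salt <- matrix(rbinom(length(alt), alt, 1 - a), L, n_barcodes)
        sref <- matrix(rbinom(length(ref), ref, 1 - a), L, n_barcodes)
        tot <- salt + sref
        af <- ifelse(tot > 0, salt / tot, 0)
        missing <- tot == 0 |
            matrix(runif(L * n_barcodes) < config$missing_rate,
                   L, n_barcodes)
        ## observed assays consistent with the genotype caller's gates
        af_obs <- pmin(pmax(af + rnorm(L * n_barcodes, 0, 0.015), 0), 1)
        depth <- matrix(rnbinom(L * n_barcodes, mu = 70, size = 8) + 10,
                        L, n_barcodes)
        depth[missing] <- sample(0:9, sum(missing), replace = TRUE)
        gq <- matrix(99, L, n_barcodes)

        barcodes <- sprintf("BC%05d", seq_len(n_barcodes))
        loci_names <- c(colnames(profiles), var_ids)
        dimnames(af_obs) <- dimnames(depth) <- dimnames(gq) <-
            list(loci_names, barcodes)
        rd <- DataFrame(
            chrom = c(rep("chr1", nsnp), var_tab$chrom),
            pos = c(seq(1e6, by = 2000, length.out = nsnp), var_tab$pos),
            ref = c(rep("A", nsnp), var_tab$ref),
            alt = c(rep("G", nsnp), var_tab$alt),
            gene = c(rep(NA_character_, nsnp), var_tab$gene),
            protein_change = c(rep(NA_character_, nsnp),
                               var_tab$protein_change),
            synonymous = c(rep(FALSE, nsnp), var_tab$synonymous),
            homopolymer = c(rep(FALSE, nsnp), var_tab$homopolymer),
            pop_af = c(maf, var_tab$pop_af),
            germline_flag = c(rep(TRUE, nsnp), var_tab$germline_flag),
            role = c(rep("germline_snp", nsnp),
                     rep("somatic", length(var_ids))),
            row.names = loci_names)

        mu_ab <- t(mk_tab[cell1, , drop = FALSE])
        ab <- matrix(rnbinom(length(mu_ab), mu = mu_ab,
                             size = config$ab_dispersion),
                     nrow(mu_ab), n_barcodes,
                     dimnames = list(rownames(mu_ab), barcodes))
        if (any(is_dbl)) {
            mu2 <- t(mk_tab[cell2[is_dbl], , drop = FALSE])
            ab[, is_dbl] <- ab[, is_dbl] +
                matrix(rnbinom(length(mu2), mu = mu2,
                               size = config$ab_dispersion),
                       nrow(mu2), sum(is_dbl))
        }

        x <- CellGenotypeMatrix(
            genotype = callGenotypes(depth, gq, af_obs),
            depth = depth, GQ = gq, AF = af_obs, rowData = rd,
            antibody = ab)
        truth <- data.frame(
            barcode = barcodes,
            patient = patOf,
            clone = sub(".*/", "", cell1),
            patient2 = sub("/.*", "", cell2),
            clone2 = sub(".*/", "", cell2),
            is_doublet = is_dbl,
            stringsAsFactors = FALSE)
        planted <- lapply(config$patients, `[[`, "planted")
        names(planted) <- pts
        list(matrix = x, profiles = profiles, truth = truth,
             planted = planted, timepoint = timepoint)
    })
}

#' Simulate a longitudinal ddPCR measurement series
#'
#' Per sample, mutant droplet events are binomial over the assessable
#' alleles at rate \code{true_vaf + fp_rate} (the assay's wildtype noise),
#' pooled over replicates; the measured VAF is
#' \code{100 * mutant / alleles}.
#'
#' @param trajectory data.frame with \code{day} (strictly increasing per
#'   tissue), \code{tissue}, \code{true_vaf} (percent).
#' @param assay list with \code{lod} (percent) and \code{fp_rate}
#'   (per-allele false-positive probability; default 0).
#' @param replicates wells per sample.
#' @param dna_copies_per_well assessable genome copies per well (2 alleles
#'   each).
#' @param seed integer seed.
#' @param config a \code{\link{runConfig}} list.
#' @return An \linkS4class{MrdSeries}.
#' @export
simulateDdpcrSeries <- function(trajectory, assay, replicates = 2,
                                dna_copies_per_well = 10000, seed = 1,
                                config = runConfig()) {
    for (tis in unique(trajectory$tissue))
        if (is.unsorted(trajectory$day[trajectory$tissue == tis],
                        strictly = TRUE))
            stop("trajectory days must be strictly increasing per tissue")
    fp <- if (is.null(assay$fp_rate)) 0 else assay$fp_rate
    withSeed(seed, {
        alleles <- 2 * dna_copies_per_well * replicates
        p <- pmin(trajectory$true_vaf / 100 + fp, 1)
        mut <- rbinom(nrow(trajectory), alleles, p)
        MrdSeries(day = trajectory$day, tissue = trajectory$tissue,
                  vaf = 100 * mut / alleles, lod = assay$lod,
                  alleles = alleles,
                  target = if (is.null(assay$target)) "target"
                           else assay$target,
                  config = config)
    })
}

#' Canonical monitoring trajectories
#'
#' \code{relapseTrajectory} falls from a diagnostic VAF to sustained
#' positivity and then rises exponentially (>= 10-fold between
#' consecutive samples) from \code{relapse_day};
#' \code{stableTrajectory} holds a constant low-level positive VAF (no
#' relapse). The true relapse day travels with the trajectory as the
#' \code{true_relapse_day} attribute (\code{NA} for stable).
#'
#' @param days sampling days.
#' @param tissue tissue label recycled over days.
#' @param base_vaf stable low-level VAF (percent).
#' @param relapse_day first day of the exponential rise.
#' @return data.frame trajectory with attribute \code{true_relapse_day}.
#' @export
relapseTrajectory <- function(days = c(30, 90, 150, 210, 270),
                              tissue = "PB", base_vaf = 0.05,
                              relapse_day = 210) {
    vaf <- rep(base_vaf, length(days))
    rising <- days >= relapse_day
    vaf[rising] <- base_vaf * 12 ^ seq_len(sum(rising))
    structure(data.frame(day = days, tissue = tissue, true_vaf = vaf),
              true_relapse_day = relapse_day)
}

#' @rdname relapseTrajectory
#' @export
stableTrajectory <- function(days = c(30, 90, 150, 210, 270),
                             tissue = "PB", base_vaf = 0.05) {
    structure(data.frame(day = days, tissue = tissue,
                         true_vaf = base_vaf),
              true_relapse_day = NA_real_)
}

#' Simulate error-corrected NGS per-strand counts
#'
#' Per strand, supporting reads are true-variant draws (binomial at
#' \code{true_vaf}) plus error draws from a beta-binomial background with
#' the stated mean rate and overdispersion. Each supporting read
#' constitutes its own consensus family, so the unique-alternative-
#' observation (UAO) count equals the total supporting count.
#'
#' @param true_vaf variant allele fraction (proportion, not percent).
#' @param depth_per_strand total reads per strand.
#' @param error_rate_per_strand mean background error rate (in [0, 1)).
#' @param dispersion beta-binomial overdispersion rho in (0, 1).
#' @param seed integer seed.
#' @param n_sites number of independent sites to simulate.
#' @return data.frame with \code{site}, \code{supporting_fwd},
#'   \code{total_fwd}, \code{supporting_rev}, \code{total_rev},
#'   \code{uao}.
#' @export
simulateEcngsCounts <- function(true_vaf, depth_per_strand,
                                error_rate_per_strand, dispersion = 1e-5,
                                seed = 1, n_sites = 1) {
    stopifnot(depth_per_strand > 0,
              error_rate_per_strand >= 0, error_rate_per_strand < 1)
    withSeed(seed, {
        rbb <- function(n) {
            if (error_rate_per_strand == 0) return(integer(n))
            a <- error_rate_per_strand * (1 - dispersion) / dispersion
            b <- (1 - error_rate_per_strand) * (1 - dispersion) /
                dispersion
            rbinom(n, depth_per_strand, stats::rbeta(n, a, b))
        }
        truef <- rbinom(n_sites, depth_per_strand, true_vaf)
        truer <- rbinom(n_sites, depth_per_strand, true_vaf)
        sf <- pmin(truef + rbb(n_sites), depth_per_strand)
        sr <- pmin(truer + rbb(n_sites), depth_per_strand)
        data.frame(site = paste0("site", seq_len(n_sites)),
                   supporting_fwd = sf, total_fwd = depth_per_strand,
                   supporting_rev = sr, total_rev = depth_per_strand,
                   uao = sf + sr)
    })
}
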