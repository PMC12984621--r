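#' Build the germline-SNP expected-genotype database
#'
#' Constructs one expected alt-allele-dosage vector per patient and one
#' per unordered patient pair: the doublet profile at a locus is the mean
#' of the two patients' allele dosages (a het + hom-alt pair has expected
#' dosage 1.5). All patients must share the same locus set.
#'
#' @param profiles integer matrix, patients x loci, of alt-allele copies
#'   in \{0, 1, 2\}; rownames are patient ids.
#' @param loci optional data.frame of locus annotations (chrom, pos, ref,
#'   alt) with one row per column of \code{profiles}.
#' @return A \linkS4class{DemuxDB} with \code{n + choose(n, 2)} profiles.
#' @export
buildProfileDatabase <- function(profiles, loci = NULL) {
    if (nrow(profiles) < 2)
        stop("need at least 2 patient profiles")
    if (is.null(rownames(profiles)))
        rownames(profiles) <- paste0("patient", seq_len(nrow(profiles)))
    if (anyDuplicated(apply(profiles, 1, paste, collapse = "")))
        warning("indistinguishable patients: identical germline profiles")
    if (is.null(loci))
        loci <- data.frame(chrom = "chr1",
                           pos = seq_len(ncol(profiles)),
                           ref = "N", alt = "N")
    pts <- rownames(profiles)
    pairs <- combn(pts, 2)
    doublet <- t(apply(pairs, 2, function(pr)
        (profiles[pr[1], ] + profiles[pr[2], ]) / 2))
    rownames(doublet) <- apply(pairs, 2, paste, collapse = "+")
    expected <- rbind(profiles, doublet)
    methods::new("DemuxDB",
        expected = expected,
        kind = c(rep("singlet", length(pts)),
                 rep("doublet", ncol(pairs))),
        members = c(as.list(pts),
                    lapply(seq_len(ncol(pairs)), function(i) pairs[, i])),
        loci = loci)
}

## log observation probabilities for each profile x locus x observed
## genotype, under a symmetric genotyping-error rate eps. Integer expected
## dosages put 1 - eps on the matching genotype; half-integer (doublet)
## dosages split 1 - eps over the two adjacent genotypes.
.demuxLogProb <- function(db, eps) {
    E <- db@expected
    logp <- array(log(eps / 2), dim = c(nrow(E), ncol(E), 3))
    for (o in 0:2) {
        exact <- abs(E - o) < 1e-9
        adj <- abs(E - o) == 0.5
        logp[, , o + 1][exact] <- log(1 - eps)
        logp[, , o + 1][adj] <- log((1 - eps) / 2)
    }
    half <- abs(E - round(E)) == 0.5
    for (o in 0:2)
        logp[, , o + 1][half & abs(E - o) > 0.5] <- log(eps)
    logp
}

#' Score cells against the demultiplexing database
#'
#' Each cell's germline-SNP genotypes are scored against every singlet and
#' doublet profile with a per-locus categorical observation model
#' (symmetric genotyping-error rate \code{demux$error_rate}); missing loci
#' contribute nothing. The best match is the maximum-likelihood profile;
#' ties are marked ambiguous. Discrepancies count non-missing SNPs whose
#' observed genotype differs from the best profile's expected genotype
#' (off by more than half a dosage unit for doublet profiles).
#'
#' @param gt integer matrix, loci x cells, of observed germline-SNP
#'   genotypes (\code{NA} = missing). Row order may be any permutation of
#'   the database loci (matched by rowname when present).
#' @param db a \linkS4class{DemuxDB}.
#' @param config a \code{\link{runConfig}} list.
#' @return data.frame with one row per cell: \code{barcode},
#'   \code{best_match}, \code{kind} (\code{singlet}/\code{doublet}/
#'   \code{none}), \code{n_genotyped_snps}, \code{n_discrepancies},
#'   \code{discrepancy_fraction}, \code{log_likelihood}, \code{ambiguous}.
#' @export
scoreCells <- function(gt, db, config = runConfig()) {
    eps <- config$demux$error_rate
    L <- ncol(db@expected)
    if (!is.null(rownames(gt)) && !is.null(colnames(db@expected))) {
        ord <- match(colnames(db@expected), rownames(gt))
        if (anyNA(ord)) stop("cell matrix is missing database loci")
        gt <- gt[ord, , drop = FALSE]
    }
    if (nrow(gt) != L) stop("locus count mismatch with database")
    nc <- ncol(gt)
    logp <- .demuxLogProb(db, eps)
    ll <- matrix(0, nrow(db@expected), nc)
    for (o in 0:2) {
        I <- matrix(0, L, nc)
        I[!is.na(gt) & gt == o] <- 1
        ll <- ll + logp[, , o + 1] %*% I
    }
    n_geno <- colSums(!is.na(gt))
    best <- integer(nc); amb <- logical(nc)
    for (j in seq_len(nc)) {
        if (n_geno[j] == 0) { best[j] <- NA_integer_; next }
        mx <- max(ll[, j])
        w <- which(ll[, j] >= mx - 1e-9)
        best[j] <- w[1]
        amb[j] <- length(w) > 1
    }
    n_disc <- integer(nc)
    for (j in seq_len(nc)) {
        if (is.na(best[j])) { n_disc[j] <- NA_integer_; next }
        e <- db@expected[best[j], ]
        seen <- !is.na(gt[, j])
        n_disc[j] <- sum(abs(gt[seen, j] - e[seen]) > 0.5 + 1e-9)
    }
    data.frame(
        barcode = if (is.null(colnames(gt))) paste0("cell", seq_len(nc))
                  else colnames(gt),
        best_match = ifelse(is.na(best), NA_character_,
                            rownames(db@expected)[best]),
        kind = ifelse(is.na(best), "none", db@kind[best]),
        n_genotyped_snps = n_geno,
        n_discrepancies = n_disc,
        discrepancy_fraction = ifelse(n_geno > 0, n_disc / n_geno, NA),
        log_likelihood = ifelse(is.na(best), NA_real_,
                                ll[cbind(best, seq_len(nc))]),
        ambiguous = amb,
        stringsAsFactors = FALSE)
}

#' @rdname scoreCells
#' @param cell_genotypes named integer vector for a single cell.
#' @export
scoreCell <- function(cell_genotypes, db, config = runConfig()) {
    gt <- matrix(cell_genotypes, ncol = 1,
                 dimnames = list(names(cell_genotypes), "cell"))
    scoreCells(gt, db, config)[1, ]
}

#' Apply the cell-removal rules to demultiplexing assignments
#'
#' A cell is removed when it was genotyped in fewer than 30\% of the
#' database germline SNPs, when its genotype discrepancies against the
#' best-matching patient number 10 or more, or when the discrepancy
#' percentage is 30\% or more (any violated rule removes under the default
#' \code{demux$rule_combine = "or"}; \code{"and"} requires the low
#' genotyping rate together with a discrepancy violation). Doublet-matched
#' and ambiguous cells are removed regardless.
#'
#' @param scores data.frame from \code{\link{scoreCells}}.
#' @param total_db_snps total number of genotyped germline SNPs in the
#'   database.
#' @param config a \code{\link{runConfig}} list.
#' @return \code{scores} with added \code{decision} (\code{"keep"}/
#'   \code{"remove"}) and \code{reason} columns.
#' @export
applyDemuxQC <- function(scores, total_db_snps, config = runConfig()) {
    dc <- config$demux
    frac_geno <- scores$n_genotyped_snps / total_db_snps
    low_geno <- frac_geno < dc$min_genotyped_fraction
    many_disc <- !is.na(scores$n_discrepancies) &
        scores$n_discrepancies >= dc$max_discrepancies
    high_frac <- !is.na(scores$discrepancy_fraction) &
        scores$discrepancy_fraction >= dc$max_discrepancy_fraction
    qc_fail <- if (identical(dc$rule_combine, "and"))
        low_geno & (many_disc | high_frac)
    else low_geno | many_disc | high_frac
    reason <- rep(NA_character_, nrow(scores))
    reason[qc_fail & low_geno] <- "low genotyping rate"
    reason[qc_fail & many_disc] <- "too many discrepancies"
    reason[qc_fail & high_frac & is.na(reason)] <-
        "high discrepancy fraction"
    reason[qc_fail & low_geno & (many_disc | high_frac)] <-
        "low genotyping rate + discrepancies"
    no_snp <- scores$n_genotyped_snps == 0
    reason[no_snp] <- "no informative SNPs"
    reason[scores$ambiguous & is.na(reason)] <- "ambiguous"
    is_doublet <- scores$kind == "doublet"
    reason[is_doublet & is.na(reason)] <- "doublet"
    remove <- qc_fail | no_snp | scores$ambiguous | is_doublet
    scores$decision <- ifelse(remove, "remove", "keep")
    scores$reason <- reason
    scores
}

#' Demultiplex a multiplexed run into per-patient matrices
#'
#' Scores every barcode against the germline database, applies the
#' removal rules, and partitions the run (genotype and antibody data
#' together) by assigned patient. Every input barcode lands in exactly one
#' output partition or in the removal report.
#'
#' @param x a \linkS4class{CellGenotypeMatrix} containing germline-SNP
#'   rows (\code{role == "germline_snp"}).
#' @param db a \linkS4class{DemuxDB}.
#' @param config a \code{\link{runConfig}} list.
#' @return list with \code{partitions} (named list of
#'   \code{CellGenotypeMatrix}, one per patient with retained cells),
#'   \code{assignments} (full per-barcode table) and \code{removed}
#'   (removal report).
#' @export
demultiplexRun <- function(x, db, config = runConfig()) {
    if (ncol(x) == 0)
        return(list(partitions = list(),
                    assignments = data.frame(), removed = data.frame()))
    gt <- genotypes(germlineRows(x))
    scores <- scoreCells(gt, db, config)
    scores <- applyDemuxQC(scores, ncol(db@expected), config)
    keep <- scores$decision == "keep"
    pts <- rownames(db@expected)[db@kind == "singlet"]
    partitions <- list()
    for (p in pts) {
        sel <- keep & scores$best_match == p
        if (any(sel)) partitions[[p]] <- x[, scores$barcode[sel]]
    }
    removed <- scores[!keep, , drop = FALSE]
    stopifnot(sum(vapply(partitions, ncol, integer(1))) + nrow(removed)
              == ncol(x))
    list(partitions = partitions, assignments = scores, removed = removed)
}
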