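#' Evaluate the five MRD target-selection criteria
#'
#' For each candidate variant surviving the diagnosis-run filters (or
#' force-called), the criteria are:
#' \enumerate{
#'   \item present in a large clone at diagnosis: pseudobulk VAF across
#'     clones >= 10\% (a heterozygous variant carried by all blasts at the
#'     20\% blast-fraction diagnostic minimum gives exactly 10\%);
#'   \item reduced to < 1\% VAF after the first treatment course (absent
#'     from the remission output but covered by the panel counts as 0);
#'   \item carried only by clones with a distinct immature (CD34+ and/or
#'     CD117+) immunophenotype displaying aberrant characteristics, per
#'     the DfN + LAIP classification;
#'   \item not missing or lost in any clone at a more advanced stage
#'     (wildtype in a descendant, e.g. through alt-loss LOH; ref-loss LOH
#'     to homozygosity does not lose the target);
#'   \item not in a gene known to occasionally become negative at relapse
#'     (blacklist; RAS/FLT3 by default).
#' }
#' A variant is eligible iff all five criteria pass.
#'
#' @param variants candidate variant ids (default: all somatic rows of
#'   \code{diagnosis}).
#' @param diagnosis a \linkS4class{CellGenotypeMatrix} of the diagnosis
#'   run (filtered).
#' @param remission the remission-run \code{CellGenotypeMatrix}, or
#'   \code{NULL} when no remission sample exists (criterion 2 then not
#'   assessable; variant ineligible with reason).
#' @param clone_graph a \linkS4class{CloneGraph} over the diagnosis
#'   clones.
#' @param immuno_profiles named list (clone id -> result of
#'   \code{\link{classifyAberrant}}) for the diagnosis clones.
#' @param config a \code{\link{runConfig}} list (criteria thresholds,
#'   \code{vaf_mode}, \code{aberrant_mode}, \code{blacklist}).
#' @return A \code{DataFrame} with per-variant evidence (diagnosis and
#'   remission VAF, carrying/violating clone ids), the five criterion
#'   booleans \code{c1}..\code{c5}, \code{eligible}, and \code{reasons}.
#' @export
evaluateCriteria <- function(variants = NULL, diagnosis, remission,
                             clone_graph, immuno_profiles,
                             config = runConfig()) {
    cr <- config$criteria
    if (is.null(variants)) variants <- rownames(somaticRows(diagnosis))
    cs <- clone_graph@clones
    gt <- cs@genotype
    rd <- rowData(diagnosis)

    diag_vaf_all <- pseudobulkVAF(diagnosis, variants)
    rem_vaf <- rep(NA_real_, length(variants))
    names(rem_vaf) <- variants
    if (!is.null(remission)) {
        covered <- variants[variants %in% rownames(remission)]
        if (length(covered))
            rem_vaf[covered] <- pseudobulkVAF(remission, covered)
        rem_vaf[setdiff(variants, covered)] <- NA_real_
    }

    res <- lapply(variants, function(v) {
        dv <- if (identical(cr$vaf_mode, "largest_clone") && nrow(gt)) {
            carrying <- rownames(gt)[gt[, v] >= 1L]
            if (length(carrying)) {
                asn <- cs@assignments
                n_inf <- sum(!is.na(genotypes(diagnosis)[v, ]))
                max(vapply(carrying, function(cl) {
                    cells <- names(asn)[asn == cl]
                    g <- genotypes(diagnosis)[v, cells]
                    100 * sum(g, na.rm = TRUE) / (2 * n_inf)
                }, numeric(1)))
            } else 0
        } else unname(diag_vaf_all[v])
        c1 <- isTRUE(dv >= cr$min_diagnosis_vaf)

        rv <- rem_vaf[v]
        c2 <- if (is.null(remission) || is.na(rv)) NA
              else rv < cr$max_remission_vaf

        carrying <- if (nrow(gt) && v %in% colnames(gt))
            rownames(gt)[gt[, v] >= 1L] else character(0)
        flags <- vapply(carrying, function(cl) {
            pr <- immuno_profiles[[cl]]
            isTRUE(pr$immature) && isTRUE(pr$aberrant)
        }, logical(1))
        c3 <- if (!length(carrying)) FALSE
              else if (identical(cr$aberrant_mode, "any")) any(flags)
              else all(flags)

        loh <- clone_graph@loh
        lost_edges <- loh[loh$variant == v & loh$lost_allele == "alt", ,
                          drop = FALSE]
        violating <- unique(lost_edges$child)
        c4 <- nrow(lost_edges) == 0

        gene <- rd[v, "gene"]
        c5 <- !(gene %in% cr$blacklist)

        reasons <- c(if (!c1) "c1: diagnosis VAF below threshold",
                     if (is.na(c2)) "c2: remission not assessable"
                     else if (!c2) "c2: persists at remission",
                     if (!c3) "c3: carried by non-aberrant clone",
                     if (!c4) "c4: lost in descendant clone",
                     if (!c5) "c5: blacklisted gene")
        DataFrame(variant = v, gene = gene,
                  diagnosis_vaf = dv, remission_vaf = unname(rv),
                  c1 = c1, c2 = isTRUE(c2), c2_assessable = !is.na(c2),
                  c3 = c3, c4 = c4, c5 = c5,
                  carrying_clones = paste(carrying, collapse = ","),
                  violating_clones = paste(violating, collapse = ","),
                  eligible = c1 && isTRUE(c2) && c3 && c4 && c5,
                  reasons = paste(reasons, collapse = "; "))
    })
    out <- do.call(rbind, res)
    rownames(out) <- out$variant
    out
}

#' Rank eligible MRD targets
#'
#' Eligible variants are ranked by ascending assay limit of detection
#' when LoDs are supplied (prioritizing assay sensitivity), otherwise by
#' descending diagnosis VAF. All eligible variants are returned; the top
#' row is the preferred single-assay MRD target.
#'
#' @param results the \code{DataFrame} from \code{\link{evaluateCriteria}}.
#' @param assay_lods optional named numeric vector (variant id -> LoD in
#'   VAF percent); variants without an LoD sort after those with one.
#' @return \code{DataFrame} of eligible variants in rank order (possibly
#'   zero rows), with attribute \code{"failure_reasons"} naming why each
#'   ineligible variant failed.
#' @export
selectTargets <- function(results, assay_lods = NULL) {
    elig <- results[results$eligible, , drop = FALSE]
    if (nrow(elig)) {
        if (!is.null(assay_lods)) {
            lod <- assay_lods[elig$variant]
            elig <- elig[order(is.na(lod), lod, -elig$diagnosis_vaf), ,
                         drop = FALSE]
            elig$assay_lod <- assay_lods[elig$variant]
        } else {
            elig <- elig[order(-elig$diagnosis_vaf), , drop = FALSE]
        }
    }
    fails <- results[!results$eligible, , drop = FALSE]
    attr(elig, "failure_reasons") <-
        setNames(as.character(fails$reasons), fails$variant)
    elig
}
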