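#' Diagnose-and-select analysis for one patient
#'
#' Runs the per-patient analysis chain on demultiplexed (or
#' single-patient) runs: variant-level filtering of the diagnosis run,
#' clonal reconstruction with LOH-aware developmental ordering, CLR
#' immunophenotyping with a different-from-normal reference derived from
#' the run's own wildtype cells, five-criterion evaluation, and target
#' ranking.
#'
#' @param diagnosis diagnosis-run \linkS4class{CellGenotypeMatrix}.
#' @param remission remission-run matrix or \code{NULL}.
#' @param config a \code{\link{runConfig}} list.
#' @param assay_lods optional named LoD vector for ranking.
#' @param laip_rules optional LAIP rule list for
#'   \code{\link{classifyAberrant}}.
#' @param force_variants variant ids to force-call past the filters
#'   (e.g. after a low-uniformity run).
#' @return list with \code{filter_report}, \code{clones}, \code{graph},
#'   \code{profiles} (per-clone aberrancy classifications),
#'   \code{criteria}, \code{targets}, \code{reference_ranges}.
#' @export
analyzePatient <- function(diagnosis, remission = NULL,
                           config = runConfig(), assay_lods = NULL,
                           laip_rules = NULL, force_variants = NULL) {
    report <- applyVariantFilters(diagnosis, config = config)
    surviving <- union(report@surviving,
                       intersect(force_variants, rownames(diagnosis)))
    keep_rows <- rownames(diagnosis) %in% surviving |
        rowData(diagnosis)$role == "germline_snp"
    dg <- diagnosis[keep_rows, ]

    clones <- inferClones(dg, config = config)
    if (!nrow(clones@genotype))
        return(list(filter_report = report, clones = clones,
                    graph = NULL, profiles = list(),
                    criteria = NULL, targets = NULL,
                    reference_ranges = NULL))
    graph <- buildCloneGraph(clones)

    ab <- antibodyCounts(diagnosis)
    profiles <- list(); ranges <- NULL
    if (!is.null(ab)) {
        clr <- clrTransform(ab, config$immuno$pseudocount)
        asn <- clones@assignments
        wt_cells <- names(asn)[asn == "WT"]
        if (!length(wt_cells)) {
            warning("no wildtype cells; DfN reference from all cells")
            wt_cells <- colnames(clr)
        }
        ranges <- deriveReferenceRanges(clr, wt_cells, config)
        for (cl in rownames(clones@genotype)) {
            cells <- names(asn)[asn == cl]
            pr <- cloneImmunophenotype(clr, cells, cl, config)
            profiles[[cl]] <- classifyAberrant(pr, ranges, laip_rules,
                                               config)
        }
    }

    criteria <- evaluateCriteria(surviving, dg, remission, graph,
                                 profiles, config)
    targets <- selectTargets(criteria, assay_lods)
    list(filter_report = report, clones = clones, graph = graph,
         profiles = profiles, criteria = criteria, targets = targets,
         reference_ranges = ranges)
}

#' Longitudinal MRD monitoring for one patient
#'
#' Applies the ELN-style relapse rules to a measurement series and, when
#' a relapse is called, computes lead times against conventional
#' detection methods.
#'
#' @param series an \linkS4class{MrdSeries}.
#' @param comparator_days optional named list of conventional-method
#'   detection days.
#' @param config a \code{\link{runConfig}} list.
#' @return list with \code{call} (an \linkS4class{MrdCall}) and
#'   \code{lead_times}.
#' @export
monitorPatient <- function(series, comparator_days = NULL,
                           config = runConfig()) {
    call <- callRelapse(series, config)
    lead <- if (call@relapse && !is.null(comparator_days))
        leadTime(call@day, comparator_days) else list()
    list(call = call, lead_times = lead)
}

#' End-to-end pipeline on a synthetic cohort
#'
#' Simulates multiplexed diagnosis and remission runs, demultiplexes both
#' against the germline-SNP database, and runs
#' \code{\link{analyzePatient}} per patient. Deterministic given the
#' seed. With a single-patient cohort (no multiplexing possible) the runs
#' are analyzed directly.
#'
#' @param cohort a \code{\link{cohortConfig}}.
#' @param n_diagnosis,n_remission barcodes per run.
#' @param seed integer seed for all randomness.
#' @param config a \code{\link{runConfig}} list.
#' @return list with per-patient \code{reports}, the demux results, the
#'   truth labels of both runs, and the config echo (for provenance,
#'   thresholds travel with every report).
#' @export
runPipeline <- function(cohort = defaultCohortConfig(),
                        n_diagnosis = 4000, n_remission = 1500,
                        seed = 1, config = runConfig()) {
    diag_run <- simulateMultiplexRun(cohort, n_diagnosis, "diagnosis",
                                     seed = seed)
    rem_run <- simulateMultiplexRun(cohort, n_remission, "remission",
                                    seed = seed + 1)
    pts <- vapply(cohort$patients, `[[`, character(1), "id")
    if (length(pts) > 1) {
        db <- buildProfileDatabase(diag_run$profiles)
        dd <- demultiplexRun(diag_run$matrix, db, config)
        dr <- demultiplexRun(rem_run$matrix, db, config)
        diag_parts <- dd$partitions
        rem_parts <- dr$partitions
        demux <- list(diagnosis = dd, remission = dr)
    } else {
        diag_parts <- setNames(list(diag_run$matrix), pts)
        rem_parts <- setNames(list(rem_run$matrix), pts)
        demux <- NULL
    }
    reports <- lapply(pts, function(p)
        analyzePatient(diag_parts[[p]], rem_parts[[p]], config))
    names(reports) <- pts
    list(reports = reports, demux = demux,
         truth = list(diagnosis = diag_run$truth,
                      remission = rem_run$truth),
         planted = diag_run$planted, config = config)
}
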