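#' Default pipeline configuration
#'
#' All thresholds used across the pipeline, each config-exposed with the
#' published analysis values as defaults. Override entries via \code{...};
#' unknown keys are rejected.
#'
#' @param ... named overrides of any default.
#' @return A named list with components:
#' \describe{
#'   \item{demux}{\code{min_genotyped_fraction} 0.30,
#'     \code{max_discrepancies} 10, \code{max_discrepancy_fraction} 0.30,
#'     \code{error_rate} 0.01 (genotyping-error rate of the likelihood
#'     model), \code{rule_combine} \code{"or"} (any violated rule removes).}
#'   \item{filter}{cell-level \code{min_depth} 10, \code{min_gq} 30,
#'     \code{min_cell_af} 0.35, \code{hom_af} 0.90; variant-level
#'     \code{min_mutated_cells} 3, \code{min_mutated_cells_strict} 6,
#'     \code{proximity_bp} 300, \code{max_pop_af} 0.001,
#'     \code{require_hom_cell} TRUE, \code{cooccur_min_cells} 3,
#'     \code{min_uniformity} 0.80, \code{uniformity_low_cov} 0.2 (fraction
#'     of panel mean).}
#'   \item{clones}{\code{min_clone_size} 6, \code{ado_hom_threshold} 0.3
#'     (apparent-HOM fraction below which HOM cells in a HET clone are
#'     absorbed as allelic dropout rather than split off),
#'     \code{assumed_ado} 0.05 (per-allele dropout rate assumed by the
#'     clone-assignment observation model), \code{artifact_fold} 3
#'     (a genotype group is absorbed when its size is within this factor
#'     of the dropout inflow expected from larger clones).}
#'   \item{immuno}{\code{pseudocount} 1, \code{positivity_clr} 1.0,
#'     \code{immature_markers} CD34/CD117, \code{cross_lineage_markers}
#'     CD3/CD7/CD19/CD56, \code{reference_quantiles} c(0.025, 0.975).}
#'   \item{criteria}{\code{min_diagnosis_vaf} 10 (percent),
#'     \code{max_remission_vaf} 1 (percent), \code{vaf_mode}
#'     \code{"aggregate"} (pool clones; \code{"largest_clone"} available),
#'     \code{aberrant_mode} \code{"all"} (every variant-carrying clone must
#'     be immature + aberrant; \code{"any"} available), \code{blacklist}
#'     NRAS/KRAS/FLT3.}
#'   \item{mrd}{\code{lod_z} 3.08, \code{rot_events} 3,
#'     \code{boundary_positive} TRUE (VAF exactly at threshold is
#'     positive), \code{fold_change} 10, \code{tenfold_same_tissue} FALSE,
#'     \code{rot_unit} \code{"alleles"}.}
#'   \item{ecngs}{\code{posterior_threshold} 0.01, \code{uao_min} 3,
#'     \code{floor_rate} 1e-6, \code{trim} 0 (trimmed-mean fraction for
#'     background fitting).}
#' }
#' @examples
#' cfg <- runConfig(filter = list(min_depth = 20))
#' cfg$filter$min_depth
#' @export
runConfig <- function(...) {
    cfg <- list(
        demux = list(
            min_genotyped_fraction = 0.30,
            max_discrepancies = 10L,
            max_discrepancy_fraction = 0.30,
            error_rate = 0.01,
            rule_combine = "or"),
        filter = list(
            min_depth = 10, min_gq = 30, min_cell_af = 0.35, hom_af = 0.90,
            min_mutated_cells = 3L, min_mutated_cells_strict = 6L,
            proximity_bp = 300L, max_pop_af = 0.001,
            require_hom_cell = TRUE, cooccur_min_cells = 3L,
            min_uniformity = 0.80, uniformity_low_cov = 0.2),
        clones = list(min_clone_size = 6L, ado_hom_threshold = 0.3,
                      assumed_ado = 0.05, artifact_fold = 3),
        immuno = list(
            pseudocount = 1, positivity_clr = 1.0,
            immature_markers = c("CD34", "CD117"),
            cross_lineage_markers = c("CD3", "CD7", "CD19", "CD56"),
            reference_quantiles = c(0.025, 0.975)),
        criteria = list(
            min_diagnosis_vaf = 10, max_remission_vaf = 1,
            vaf_mode = "aggregate", aberrant_mode = "all",
            blacklist = c("NRAS", "KRAS", "FLT3")),
        mrd = list(
            lod_z = 3.08, rot_events = 3, boundary_positive = TRUE,
            fold_change = 10, tenfold_same_tissue = FALSE,
            rot_unit = "alleles"),
        ecngs = list(
            posterior_threshold = 0.01, uao_min = 3L, floor_rate = 1e-6,
            trim = 0))
    over <- list(...)
    for (grp in names(over)) {
        if (!grp %in% names(cfg))
            stop("unknown config group: ", grp)
        bad <- setdiff(names(over[[grp]]), names(cfg[[grp]]))
        if (length(bad))
            stop("unknown config key(s) in ", grp, ": ",
                 paste(bad, collapse = ", "))
        cfg[[grp]][names(over[[grp]])] <- over[[grp]]
    }
    cfg
}
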