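#' Cell-level genotype calling from depth, quality and allele fraction
#'
#' Applies the cell-level quality gates: an entry is \code{NA} (missing)
#' when depth < \code{min_depth} or genotype quality < \code{min_gq};
#' otherwise the cell is called mutated when its allele fraction reaches
#' \code{min_cell_af} (homozygous at \code{hom_af} and above, heterozygous
#' below) and wildtype otherwise. The allele-fraction gate is a
#' \emph{cell-level} threshold: it decides whether a single cell counts as
#' mutated, not a pseudobulk cutoff.
#'
#' @param depth,gq,af numeric scalars, vectors or matrices (recycled
#'   together).
#' @param config a \code{\link{runConfig}} list (only \code{$filter} used).
#' @return Integer genotype codes (see \code{\link{GT_CODES}}), same shape
#'   as the inputs.
#' @examples
#' callGenotypes(depth = 9, gq = 99, af = 1.0)    # NA: depth gate
#' callGenotypes(depth = 100, gq = 99, af = 0.34) # 0: below 35% AF
#' callGenotypes(depth = 100, gq = 99, af = 0.50) # 1: heterozygous
#' @export
callGenotypes <- function(depth, gq, af, config = runConfig()) {
    fc <- config$filter
    stopifnot(all(af >= 0 & af <= 1, na.rm = TRUE))
    g <- ifelse(af >= fc$hom_af, 2L, ifelse(af >= fc$min_cell_af, 1L, 0L))
    g[depth < fc$min_depth | gq < fc$min_gq] <- NA_integer_
    if (is.matrix(af)) {
        g <- matrix(as.integer(g), nrow(af), ncol(af), dimnames = dimnames(af))
    } else g <- as.integer(g)
    g
}

#' Re-derive the genotype assay of a matrix from its QC assays
#'
#' @param x a \linkS4class{CellGenotypeMatrix}.
#' @inheritParams callGenotypes
#' @return \code{x} with the \code{genotype} assay recomputed.
#' @export
applyGenotypeQC <- function(x, config = runConfig()) {
    g <- callGenotypes(assay(x, "depth"), assay(x, "GQ"), assay(x, "AF"),
                       config)
    SummarizedExperiment::assay(x, "genotype") <- g
    x
}

#' FilterReport: per-variant record of every variant-level filter decision
#'
#' @slot decisions data.frame, one row per candidate variant, one logical
#'   column per filter (TRUE = passed), plus \code{n_mutated} and
#'   \code{pass} (all filters passed).
#' @slot surviving character vector of surviving variant ids.
#' @export
setClass("FilterReport",
         representation(decisions = "data.frame", surviving = "character"))

setMethod("show", "FilterReport", function(object) {
    cat("FilterReport:", nrow(object@decisions), "candidate variants,",
        length(object@surviving), "surviving\n")
    fcols <- setdiff(colnames(object@decisions),
                     c("variant", "n_mutated", "pass"))
    for (f in fcols) {
        fail <- object@decisions$variant[!object@decisions[[f]]]
        if (length(fail))
            cat("  failed", f, ":", paste(fail, collapse = ", "), "\n")
    }
})

#' @describeIn FilterReport names of the filters a variant failed.
#' @param report a \code{FilterReport}.
#' @param variant variant id.
#' @export
failedFilters <- function(report, variant) {
    d <- report@decisions[report@decisions$variant == variant, ,
                          drop = FALSE]
    if (!nrow(d)) stop("unknown variant: ", variant)
    fcols <- setdiff(colnames(d), c("variant", "n_mutated", "pass"))
    fcols[!unlist(d[1, fcols])]
}

#' Variant pairs mutated together in at least k cells
#'
#' Used to exempt genuinely co-occurring variants from the strict 6-cell
#' and proximity filters.
#'
#' @param x a \linkS4class{CellGenotypeMatrix} (somatic rows are used).
#' @param min_cells minimum shared mutated cells (default from config, 3).
#' @param config a \code{\link{runConfig}} list.
#' @return two-column character matrix of variant-id pairs (0 rows if
#'   none).
#' @export
cooccurringPairs <- function(x, min_cells = NULL, config = runConfig()) {
    if (is.null(min_cells)) min_cells <- config$filter$cooccur_min_cells
    g <- genotypes(somaticRows(x))
    mut <- !is.na(g) & g >= 1L
    shared <- mut %*% t(mut)
    idx <- which(upper.tri(shared) & shared >= min_cells, arr.ind = TRUE)
    cbind(rownames(shared)[idx[, 1]], rownames(shared)[idx[, 2]])
}

#' Apply the variant-level filter cascade
#'
#' Candidate somatic variants are screened, in order, for: (1) mutated in
#' >= 3 cells; (2) not synonymous; (3) not adjacent to a homopolymer;
#' (4) no second variant within 300 bp (both members of an offending pair
#' are removed unless the pair co-occurs); (5) mutated in >= 6 cells unless
#' the variant belongs to a co-occurring pair; (6) at least one homozygous
#' cell (apparent homozygotes are expected from allelic dropout, so their
#' complete absence flags an artifact); (7) not germline, i.e. population
#' allele frequency < 0.1\% and no user germline flag. Every decision is
#' recorded; a variant survives iff all filters pass.
#'
#' @param x a \linkS4class{CellGenotypeMatrix} whose rowData carries
#'   \code{synonymous}, \code{homopolymer}, \code{pop_af},
#'   \code{germline_flag}, \code{chrom}, \code{pos}.
#' @param user_pairs optional two-column matrix of user-declared
#'   co-occurring variant-id pairs.
#' @param config a \code{\link{runConfig}} list.
#' @return A \linkS4class{FilterReport}.
#' @export
applyVariantFilters <- function(x, user_pairs = NULL, config = runConfig()) {
    fc <- config$filter
    x <- somaticRows(x)
    g <- genotypes(x)
    rd <- as.data.frame(rowData(x))
    v <- rownames(x)
    n_mut <- rowSums(!is.na(g) & g >= 1L)
    n_hom <- rowSums(!is.na(g) & g == 2L)

    co <- cooccurringPairs(x, config = config)
    if (!is.null(user_pairs) && nrow(user_pairs))
        co <- rbind(co, user_pairs)
    pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    co_keys <- if (nrow(co)) pairKey(co[, 1], co[, 2]) else character(0)
    in_cooccur <- v %in% c(co)

    prox_ok <- rep(TRUE, length(v))
    if (length(v) > 1) {
        for (i in seq_along(v)) for (j in seq_along(v)) {
            if (i >= j) next
            if (rd$chrom[i] == rd$chrom[j] &&
                abs(rd$pos[i] - rd$pos[j]) <= fc$proximity_bp &&
                !(pairKey(v[i], v[j]) %in% co_keys))
                prox_ok[c(i, j)] <- FALSE
        }
    }

    dec <- data.frame(
        variant = v,
        n_mutated = n_mut,
        min3_cells = n_mut >= fc$min_mutated_cells,
        not_synonymous = !rd$synonymous,
        not_homopolymer = !rd$homopolymer,
        proximity_300bp = prox_ok,
        min6_cells = n_mut >= fc$min_mutated_cells_strict | in_cooccur,
        hom_cell_present = if (fc$require_hom_cell) n_hom >= 1L
                           else rep(TRUE, length(v)),
        not_germline = !(ifelse(is.na(rd$pop_af), 0, rd$pop_af) >=
                           fc$max_pop_af | rd$germline_flag),
        row.names = NULL)
    dec$pass <- Reduce(`&`, dec[, setdiff(colnames(dec),
                                          c("variant", "n_mutated"))])
    methods::new("FilterReport", decisions = dec,
                 surviving = v[dec$pass])
}

#' Zygosity-aware pseudobulk variant allele frequency
#'
#' The pseudobulk VAF of a variant is the fraction of mutated allele
#' observations among cells passing quality filters:
#' \deqn{VAF = 100 (n_{HET} + 2 n_{HOM}) / (2 n_{informative})}
#'
#' @param x a \linkS4class{CellGenotypeMatrix}.
#' @param variants variant ids (default: all somatic rows).
#' @return Named numeric vector of VAF percentages; \code{NA} when a
#'   variant has no informative (non-missing) cell.
#' @examples
#' # 30 HET + 10 HOM + 60 WT cells -> (30 + 20) / 200 = 25%
#' @export
pseudobulkVAF <- function(x, variants = NULL) {
    g <- genotypes(x)
    if (is.null(variants)) variants <- rownames(somaticRows(x))
    g <- g[variants, , drop = FALSE]
    n_inf <- rowSums(!is.na(g))
    vaf <- 100 * rowSums(g, na.rm = TRUE) / (2 * n_inf)
    vaf[n_inf == 0] <- NA_real_
    setNames(vaf, variants)
}

#' Panel uniformity of per-amplicon coverage
#'
#' Fraction of amplicons whose mean coverage is at least 0.2x the panel
#' mean. Runs below the uniformity cutoff (default 80\%) remain trustworthy
#' for reported variants but are prone to false negatives, so they raise a
#' force-call advisory.
#'
#' @param coverage numeric vector of per-amplicon mean coverage.
#' @param config a \code{\link{runConfig}} list.
#' @return list with \code{uniformity} (fraction), \code{flagged}
#'   (logical), and \code{advisory} (character or NA).
#' @export
panelUniformity <- function(coverage, config = runConfig()) {
    if (!length(coverage)) stop("empty coverage vector")
    u <- mean(coverage >= config$filter$uniformity_low_cov * mean(coverage))
    flagged <- u < config$filter$min_uniformity
    list(uniformity = u, flagged = flagged,
         advisory = if (flagged)
             "low panel uniformity: force-call known true variants"
         else NA_character_)
}

#' Force-call a known variant, bypassing variant-level filters
#'
#' Cell-level genotype QC still applies; only the variant-level filter
#' cascade is skipped. Used when a run with low panel uniformity is prone
#' to false negatives and a variant known from bulk sequencing must be
#' quantified anyway.
#'
#' @param x a \linkS4class{CellGenotypeMatrix}.
#' @param variant a variant id present in the panel.
#' @return list with \code{variant}, \code{genotypes} (per-cell integer
#'   codes), \code{vaf} (pseudobulk percent), \code{forced = TRUE}.
#' @export
forceCall <- function(x, variant) {
    if (!variant %in% rownames(x))
        stop("not in panel: ", variant)
    list(variant = variant,
         genotypes = genotypes(x)[variant, ],
         vaf = unname(pseudobulkVAF(x, variant)),
         forced = TRUE)
}
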