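#' CellGenotypeMatrix: per-cell, per-locus genotypes with QC assays
#'
#' An extension of \linkS4class{SingleCellExperiment} holding a targeted
#' single-cell DNA panel: rows are panel loci (germline SNPs used for
#' demultiplexing plus candidate somatic variants), columns are cell barcodes.
#' Four assays are required:
#' \describe{
#'   \item{\code{genotype}}{integer codes per \code{\link{GT_CODES}}
#'     (0 WT / 1 HET / 2 HOM, \code{NA} missing).}
#'   \item{\code{depth}}{read depth at the locus in the cell.}
#'   \item{\code{GQ}}{genotype quality.}
#'   \item{\code{AF}}{cell-level variant allele fraction in [0, 1].}
#' }
#' \code{rowData} carries the variant annotations (\code{chrom}, \code{pos},
#' \code{ref}, \code{alt}, \code{gene}, \code{protein_change},
#' \code{consequence}, \code{synonymous}, \code{pop_af},
#' \code{homopolymer}, \code{germline_flag}, and \code{role}, which is
#' \code{"germline_snp"} or \code{"somatic"}). Antibody-tag counts, when
#' present, live in \code{altExp(x, "antibody")} with markers as rows.
#'
#' @export
setClass("CellGenotypeMatrix", contains = "SingleCellExperiment")

setValidity("CellGenotypeMatrix", function(object) {
    msg <- character(0)
    need <- c("genotype", "depth", "GQ", "AF")
    miss <- setdiff(need, assayNames(object))
    if (length(miss))
        msg <- c(msg, paste("missing assay(s):", paste(miss, collapse = ", ")))
    if (!"role" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain a 'role' column")
    if ("genotype" %in% assayNames(object)) {
        g <- assay(object, "genotype")
        if (!all(g %in% c(0L, 1L, 2L, NA)))
            msg <- c(msg, "genotype codes must be 0/1/2/NA")
    }
    if ("AF" %in% assayNames(object)) {
        af <- assay(object, "AF")
        if (any(af < 0 | af > 1, na.rm = TRUE))
            msg <- c(msg, "AF must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CellGenotypeMatrix
#'
#' @param genotype integer matrix (loci x cells) of \code{\link{GT_CODES}}.
#' @param depth,GQ,AF numeric matrices of the same dimension.
#' @param rowData a \code{DataFrame}/\code{data.frame} of locus annotations;
#'   must include a \code{role} column (\code{"germline_snp"} or
#'   \code{"somatic"}).
#' @param antibody optional integer matrix of antibody-tag counts
#'   (markers x cells), stored as \code{altExp(x, "antibody")}.
#' @return A \linkS4class{CellGenotypeMatrix}.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(c("v1", "v2"), c("c1", "c2")))
#' d <- matrix(50, 2, 2); q <- matrix(99, 2, 2); a <- matrix(0.5, 2, 2)
#' rd <- S4Vectors::DataFrame(role = c("somatic", "somatic"))
#' CellGenotypeMatrix(g, d, q, a, rd)
#' @export
CellGenotypeMatrix <- function(genotype, depth, GQ, AF, rowData,
                               antibody = NULL) {
    storage.mode(genotype) <- "integer"
    sce <- SingleCellExperiment(
        assays = list(genotype = genotype, depth = depth, GQ = GQ, AF = AF),
        rowData = rowData)
    if (!is.null(antibody)) {
        stopifnot(ncol(antibody) == ncol(genotype))
        altExp(sce, "antibody") <- SingleCellExperiment(
            assays = list(counts = antibody))
    }
    methods::new("CellGenotypeMatrix", sce)
}

#' @describeIn CellGenotypeMatrix genotype assay accessor.
#' @param x a \code{CellGenotypeMatrix}.
#' @export
genotypes <- function(x) assay(x, "genotype")

#' @describeIn CellGenotypeMatrix antibody-count accessor (\code{NULL} when
#'   absent).
#' @export
antibodyCounts <- function(x) {
    if (!"antibody" %in% altExpNames(x)) return(NULL)
    assay(altExp(x, "antibody"), "counts")
}

#' @describeIn CellGenotypeMatrix rows with \code{role == "somatic"}.
#' @export
somaticRows <- function(x) x[rowData(x)$role == "somatic", ]

#' @describeIn CellGenotypeMatrix rows with \code{role == "germline_snp"}.
#' @export
germlineRows <- function(x) x[rowData(x)$role == "germline_snp", ]

setMethod("show", "CellGenotypeMatrix", function(object) {
    rl <- table(rowData(object)$role)
    cat("CellGenotypeMatrix:", ncol(object), "cells,",
        nrow(object), "loci (",
        paste(names(rl), rl, sep = "=", collapse = ", "), ")\n")
    if ("antibody" %in% altExpNames(object))
        cat("  antibody panel:", nrow(altExp(object, "antibody")),
            "markers\n")
})

#' DemuxDB: expected-genotype database for demultiplexing
#'
#' One expected alt-allele-dosage vector per patient (singlet) and per
#' unordered patient pair (doublet; per-locus mean of the two patients'
#' dosages). Built by \code{\link{buildProfileDatabase}}.
#'
#' @slot expected numeric matrix, profiles x loci, entries in [0, 2]
#'   (half-integer for doublets).
#' @slot kind character, \code{"singlet"} or \code{"doublet"} per profile.
#' @slot members list of patient-id character vectors per profile.
#' @slot loci data.frame of locus annotations (chrom, pos, ref, alt).
#' @export
setClass("DemuxDB", representation(
    expected = "matrix", kind = "character", members = "list",
    loci = "data.frame"))

setValidity("DemuxDB", function(object) {
    if (nrow(object@expected) != length(object@kind))
        return("kind length must match profile count")
    if (any(object@expected < 0 | object@expected > 2))
        return("expected dosages must lie in [0, 2]")
    TRUE
})

setMethod("show", "DemuxDB", function(object) {
    cat("DemuxDB:", sum(object@kind == "singlet"), "patients,",
        sum(object@kind == "doublet"), "doublet profiles,",
        ncol(object@expected), "germline SNPs\n")
})

#' CloneSet: genotype-defined clones with cell assignments
#'
#' Result of \code{\link{inferClones}}. Clone genotypes are complete
#' (no missing entries) integer vectors over the surviving somatic variants;
#' the fully wildtype population is tracked separately from subclones.
#'
#' @slot genotype integer matrix, clones x variants (codes per
#'   \code{\link{GT_CODES}}); zero rows when only wildtype cells exist.
#' @slot nCells integer vector of clone sizes.
#' @slot assignments character vector, one entry per input cell: a clone id,
#'   \code{"WT"}, or \code{"unassigned"}.
#' @slot nWildtype,nUnassigned integer counts.
#' @slot variants character vector of variant ids (columns of genotype).
#' @export
setClass("CloneSet", representation(
    genotype = "matrix", nCells = "integer", assignments = "character",
    nWildtype = "integer", nUnassigned = "integer", variants = "character"))

setValidity("CloneSet", function(object) {
    if (nrow(object@genotype) != length(object@nCells))
        return("nCells must match clone count")
    if (anyNA(object@genotype))
        return("clone genotype vectors must be complete (no NA)")
    TRUE
})

#' @describeIn CloneSet number of non-wildtype clones (the subclone count
#'   reported per sample).
#' @param clones a \code{CloneSet}.
#' @export
countSubclones <- function(clones) nrow(clones@genotype)

#' @describeIn CloneSet clone ids.
#' @param x a \code{CloneSet}.
#' @export
cloneIds <- function(x) rownames(x@genotype)

#' @describeIn CloneSet per-cell clone assignments.
#' @export
cloneAssignments <- function(x) x@assignments

setMethod("show", "CloneSet", function(object) {
    cat("CloneSet:", nrow(object@genotype), "subclone(s) over",
        length(object@variants), "variants;",
        object@nWildtype, "wildtype and",
        object@nUnassigned, "unassigned cells\n")
    if (nrow(object@genotype))
        for (i in seq_len(nrow(object@genotype)))
            cat(sprintf("  %s: n=%d [%s]\n", rownames(object@genotype)[i],
                object@nCells[i],
                paste(object@genotype[i, ], collapse = "")))
})

#' CloneGraph: developmental ordering of clones with LOH annotations
#'
#' Directed parent-to-child edges over the clones of a \code{CloneSet};
#' roots attach to the wildtype population (\code{parent == "WT"}). An edge
#' is valid when the child's mutated-variant set contains the parent's, or
#' every missing variant is explained by a loss-of-heterozygosity event.
#'
#' @slot clones the underlying \linkS4class{CloneSet}.
#' @slot edges data.frame with columns \code{parent}, \code{child}.
#' @slot loh data.frame with columns \code{parent}, \code{child},
#'   \code{variant}, \code{lost_allele} (\code{"ref"} or \code{"alt"}).
#' @slot nonTree logical; \code{TRUE} when some clone had ambiguous
#'   parentage (several incomparable maximal ancestors), in which case all
#'   candidate edges are recorded.
#' @export
setClass("CloneGraph", representation(
    clones = "CloneSet", edges = "data.frame", loh = "data.frame",
    nonTree = "logical"))

setMethod("show", "CloneGraph", function(object) {
    cat("CloneGraph:", nrow(object@clones@genotype), "clone(s),",
        nrow(object@edges), "edge(s)",
        if (isTRUE(object@nonTree)) "(non-tree: ambiguous parentage)" else "",
        "\n")
    if (nrow(object@edges))
        for (i in seq_len(nrow(object@edges))) {
            l <- object@loh[object@loh$parent == object@edges$parent[i] &
                            object@loh$child == object@edges$child[i], ]
            cat(sprintf("  %s -> %s%s\n", object@edges$parent[i],
                object@edges$child[i],
                if (nrow(l)) paste0("  [LOH: ",
                    paste(l$variant, l$lost_allele, sep = ":",
                          collapse = ", "), "]") else ""))
        }
})

#' @describeIn CloneGraph LOH-event table accessor.
#' @param x a \code{CloneGraph}.
#' @export
lohEvents <- function(x) x@loh

#' @describeIn CloneGraph edge-table accessor.
#' @export
cloneEdges <- function(x) x@edges

#' MrdSeries: a longitudinal ddPCR MRD measurement series
#'
#' Time-ordered VAF measurements for one target with the thresholds that
#' determine positivity: the assay limit of detection (LoD) and, for
#' DNA-limited samples, the rule-of-three (RoT) floor.
#'
#' @slot samples data.frame with columns \code{day}, \code{tissue}
#'   (\code{"PB"}/\code{"BM"}), \code{vaf} (percent), \code{alleles}
#'   (assessable allele observations), \code{dna_limited} (logical),
#'   \code{rot} (percent), \code{positive} (logical).
#' @slot lod assay limit of detection (VAF percent).
#' @slot target target label.
#' @export
setClass("MrdSeries", representation(
    samples = "data.frame", lod = "numeric", target = "character"))

setValidity("MrdSeries", function(object) {
    s <- object@samples
    for (tis in unique(s$tissue))
        if (is.unsorted(s$day[s$tissue == tis], strictly = TRUE))
            return("days must be strictly increasing within a tissue")
    TRUE
})

setMethod("show", "MrdSeries", function(object) {
    cat("MrdSeries:", object@target, "| LoD", object@lod, "% |",
        nrow(object@samples), "samples,",
        sum(object@samples$positive), "MRD(+)\n")
})

#' @describeIn MrdSeries sample-table accessor.
#' @param x an \code{MrdSeries}.
#' @export
mrdSamples <- function(x) x@samples

#' MrdCall: outcome of ELN-style relapse calling
#'
#' @slot relapse logical.
#' @slot day day of the first sample indicating relapse (\code{NA} if none).
#' @slot mechanism \code{"conversion"}, \code{"tenfold"}, or \code{"none"}.
#' @slot confirmingDay day of the confirming/second sample (\code{NA} if
#'   none).
#' @export
setClass("MrdCall", representation(
    relapse = "logical", day = "numeric", mechanism = "character",
    confirmingDay = "numeric"))

setValidity("MrdCall", function(object) {
    if (object@relapse && !object@mechanism %in% c("conversion", "tenfold"))
        return("relapse calls need mechanism 'conversion' or 'tenfold'")
    if (object@relapse && is.na(object@confirmingDay))
        return("relapse calls need a confirming sample day")
    TRUE
})

setMethod("show", "MrdCall", function(object) {
    if (object@relapse)
        cat(sprintf("MrdCall: RELAPSE by %s at day %g (confirmed day %g)\n",
            object@mechanism, object@day, object@confirmingDay))
    else cat("MrdCall: no MRD relapse\n")
})

#' EcngsBackground: per-site, per-strand beta-binomial error model
#'
#' Estimated from reference (variant-negative) samples by
#' \code{\link{fitBackground}}. The beta-binomial is parameterized by mean
#' error rate \code{mu} and overdispersion \code{rho} in (0, 1); \code{rho
#' -> 0} is binomial.
#'
#' @slot sites data.frame with columns \code{site}, \code{mu_fwd},
#'   \code{rho_fwd}, \code{mu_rev}, \code{rho_rev}.
#' @slot floorRate lower bound applied to the mean error rate.
#' @export
setClass("EcngsBackground", representation(
    sites = "data.frame", floorRate = "numeric"))

setValidity("EcngsBackground", function(object) {
    s <- object@sites
    if (any(c(s$mu_fwd, s$mu_rev) <= 0 | c(s$mu_fwd, s$mu_rev) >= 1))
        return("mu must lie in (0, 1)")
    if (any(c(s$rho_fwd, s$rho_rev) <= 0))
        return("rho must be positive")
    TRUE
})

setMethod("show", "EcngsBackground", function(object) {
    cat("EcngsBackground:", nrow(object@sites), "site(s); mean error",
        signif(mean(c(object@sites$mu_fwd, object@sites$mu_rev)), 3),
        "per strand\n")
})
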