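#' Centered log-ratio (CLR) transform of antibody-tag counts
#'
#' Per cell, \code{CLR_i = log(c_i + pc) - mean_j log(c_j + pc)}; each
#' cell's CLR vector sums to zero. This is the standard compositional
#' normalization for oligonucleotide-conjugated antibody counts.
#'
#' @param counts numeric matrix, markers x cells (or a vector for one
#'   cell).
#' @param pseudocount added before the log (default 1).
#' @return CLR matrix of the same shape.
#' @examples
#' clrTransform(matrix(c(5, 5, 5), 3, 1))  # all zero
#' @export
clrTransform <- function(counts, pseudocount = 1) {
    if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1)
    lg <- log(counts + pseudocount)
    sweep(lg, 2, colMeans(lg), "-")
}

#' ImmunophenotypeProfile: per-clone surface-marker summary
#'
#' @slot cloneId clone label.
#' @slot markerMeans named numeric vector of per-marker mean CLR values.
#' @slot positive named logical marker-positivity calls.
#' @slot nCells number of cells with antibody data.
#' @slot assessable logical; FALSE when the clone had no antibody data.
#' @export
setClass("ImmunophenotypeProfile", representation(
    cloneId = "character", markerMeans = "numeric", positive = "logical",
    nCells = "integer", assessable = "logical"))

setMethod("show", "ImmunophenotypeProfile", function(object) {
    if (!object@assessable) {
        cat("ImmunophenotypeProfile:", object@cloneId, "(not assessable)\n")
        return(invisible(NULL))
    }
    pos <- names(object@positive)[object@positive]
    cat("ImmunophenotypeProfile:", object@cloneId, "(", object@nCells,
        "cells ) positive:",
        if (length(pos)) paste(pos, collapse = ", ") else "none", "\n")
})

#' Summarize a clone's immunophenotype from CLR values
#'
#' The clone immunophenotype is the per-marker mean CLR over the clone's
#' cells; marker positivity is \code{mean CLR >= threshold}. Within-clone
#' heterogeneity (a minority subpopulation positive for a marker) does not
#' flip the clone-level call, since the mean is dominated by the majority.
#'
#' @param clr CLR matrix (markers x cells) from \code{\link{clrTransform}}.
#' @param cells logical/integer/character index of the clone's cells into
#'   the columns of \code{clr}.
#' @param clone_id clone label.
#' @param config a \code{\link{runConfig}} list; \code{immuno$positivity_clr}
#'   may be a scalar or a named per-marker vector of CLR cutoffs.
#' @return An \linkS4class{ImmunophenotypeProfile}.
#' @export
cloneImmunophenotype <- function(clr, cells, clone_id = "clone",
                                 config = runConfig()) {
    sub <- clr[, cells, drop = FALSE]
    if (!ncol(sub))
        return(methods::new("ImmunophenotypeProfile", cloneId = clone_id,
                            markerMeans = numeric(0), positive = logical(0),
                            nCells = 0L, assessable = FALSE))
    mm <- rowMeans(sub)
    thr <- config$immuno$positivity_clr
    thr <- if (length(thr) == 1) setNames(rep(thr, length(mm)), names(mm))
           else thr[names(mm)]
    methods::new("ImmunophenotypeProfile", cloneId = clone_id,
                 markerMeans = mm, positive = mm >= thr,
                 nCells = ncol(sub), assessable = TRUE)
}

#' Reference CLR ranges from a normal cell population
#'
#' Per-marker quantile ranges (default 2.5--97.5\%) of CLR values across
#' normal (wildtype) cells, used as the different-from-normal (DfN)
#' reference in \code{\link{classifyAberrant}}.
#'
#' @param clr CLR matrix (markers x cells).
#' @param cells index of normal cells (default: all columns).
#' @param config a \code{\link{runConfig}} list.
#' @return data.frame with columns \code{marker}, \code{lo}, \code{hi}.
#' @export
deriveReferenceRanges <- function(clr, cells = seq_len(ncol(clr)),
                                  config = runConfig()) {
    q <- config$immuno$reference_quantiles
    sub <- clr[, cells, drop = FALSE]
    data.frame(marker = rownames(sub),
               lo = apply(sub, 1, quantile, probs = q[1]),
               hi = apply(sub, 1, quantile, probs = q[2]),
               row.names = NULL)
}

#' Classify a clone immunophenotype as immature and/or aberrant
#'
#' Immaturity means positivity for CD34 and/or CD117. Aberrancy follows a
#' different-from-normal (DfN) approach integrated with diagnostic
#' leukemia-associated immunophenotype (LAIP) rules; a clone is aberrant
#' when any configured rule fires:
#' \itemize{
#'   \item cross-lineage marker positivity (lymphoid markers such as CD3,
#'     CD7, CD19, CD56 on a myeloid clone);
#'   \item a declarative LAIP rule (all required-positive markers positive
#'     and all required-negative markers negative);
#'   \item any marker mean CLR outside its DfN reference range.
#' }
#'
#' @param profile an \linkS4class{ImmunophenotypeProfile}.
#' @param reference_ranges data.frame from
#'   \code{\link{deriveReferenceRanges}}; required (no DfN reference is an
#'   error).
#' @param laip_rules optional list of rules, each a list with \code{id},
#'   \code{positive} (required-positive markers) and optional
#'   \code{negative}.
#' @param config a \code{\link{runConfig}} list.
#' @return list with \code{immature}, \code{aberrant} (logicals) and
#'   \code{matched_rules} (character).
#' @export
classifyAberrant <- function(profile, reference_ranges, laip_rules = NULL,
                             config = runConfig()) {
    if (!profile@assessable)
        stop("profile not assessable (no antibody data)")
    if (missing(reference_ranges) || is.null(reference_ranges))
        stop("no DfN reference")
    im <- config$immuno
    pos <- profile@positive
    immature <- any(pos[intersect(im$immature_markers, names(pos))])
    matched <- character(0)
    cross <- intersect(im$cross_lineage_markers, names(pos))
    if (length(cross) && any(pos[cross]))
        matched <- c(matched, paste0("cross_lineage:",
                                     cross[which(pos[cross])]))
    for (rule in laip_rules) {
        p_ok <- all(pos[rule$positive], na.rm = FALSE)
        n_ok <- is.null(rule$negative) || !any(pos[rule$negative])
        if (isTRUE(p_ok) && isTRUE(n_ok))
            matched <- c(matched, paste0("laip:", rule$id))
    }
    mm <- profile@markerMeans
    rr <- reference_ranges[match(names(mm), reference_ranges$marker), ]
    out <- !is.na(rr$lo) & (mm < rr$lo | mm > rr$hi)
    if (any(out))
        matched <- c(matched, paste0("dfn:", names(mm)[out]))
    list(immature = isTRUE(immature), aberrant = length(matched) > 0,
         matched_rules = matched)
}
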