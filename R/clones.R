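## Genotype-observation model under per-allele allelic dropout (ADO).
## Rows: true clone genotype (WT/HET/HOM); cols: observed genotype.
## A heterozygote can appear homozygous (ref allele dropped) or wildtype
## (alt allele dropped); WT/HOM cells cannot gain or lose the alternate
## allele, so those transitions have probability zero.
.adoObsMatrix <- function(a) {
    rbind(
        WT  = c(1, 0, 0),
        HET = c(a * (1 - a), (1 - a)^2, a * (1 - a)),
        HOM = c(0, 0, 1))
}

#' Group cells into genotype-defined clones
#'
#' Cells with complete (non-missing) genotype vectors over the surviving
#' somatic variants are grouped by identical genotype. Candidate genotype
#' groups are then screened against allelic-dropout artifacts, largest
#' first:
#' \itemize{
#'   \item a group differing from an accepted clone only by HET-to-HOM
#'     changes is absorbed as ADO when its share of the combined
#'     population is below \code{clones$ado_hom_threshold} (a genuine
#'     ref-loss LOH subclone above the threshold is kept);
#'   \item a group reachable from accepted clones by HET-to-WT/HOM drops
#'     is absorbed when its size does not exceed
#'     \code{clones$artifact_fold} times the dropout inflow expected under
#'     \code{clones$assumed_ado};
#'   \item remaining groups of at least \code{clones$min_clone_size} cells
#'     become clones.
#' }
#' Every cell is then assigned: complete cells by maximum posterior under
#' the ADO observation model with clone-size priors; cells with missing
#' entries to the single clone consistent with all their non-missing
#' genotypes, or \code{"unassigned"} when none or several are. The fully
#' wildtype population is reported separately, never as a subclone.
#'
#' @param x a \linkS4class{CellGenotypeMatrix}; only somatic rows are used
#'   (subset to the filter-surviving variants first).
#' @param min_clone_size minimum cells per clone (default from config, 6).
#' @param config a \code{\link{runConfig}} list.
#' @return A \linkS4class{CloneSet}.
#' @export
inferClones <- function(x, min_clone_size = NULL, config = runConfig()) {
    cc <- config$clones
    if (is.null(min_clone_size)) min_clone_size <- cc$min_clone_size
    g <- genotypes(somaticRows(x))
    if (!ncol(g) || !nrow(g))
        return(methods::new("CloneSet",
            genotype = matrix(integer(0), 0, nrow(g),
                              dimnames = list(NULL, rownames(g))),
            nCells = integer(0),
            assignments = setNames(rep("unassigned", ncol(g)),
                                   colnames(g)),
            nWildtype = 0L, nUnassigned = ncol(g),
            variants = rownames(g)))
    V <- nrow(g)
    complete <- colSums(is.na(g)) == 0L
    keys <- apply(g[, complete, drop = FALSE], 2, paste, collapse = "")
    tab <- sort(table(keys), decreasing = TRUE)
    pats <- do.call(rbind, lapply(names(tab),
        function(k) as.integer(strsplit(k, "")[[1]])))
    wt_key <- paste(rep(0L, V), collapse = "")

    a <- cc$assumed_ado
    dropP <- function(from, to) {      # per-variant artifact drop prob
        ifelse(from == to, ifelse(from == 1L, (1 - a)^2, 1),
        ifelse(from == 1L & to != 1L, a * (1 - a), 0))
    }
    accepted <- integer(0)             # row indices into pats
    counts <- as.integer(tab)
    for (i in seq_along(counts)) {
        if (names(tab)[i] == wt_key) next
        pat <- pats[i, ]
        hom_only <- NA_integer_; inflow <- 0
        for (j in accepted) {
            pj <- pats[j, ]
            d <- pat != pj
            if (!any(d)) next
            if (all(pj[d] == 1L)) {    # reachable by dropout from j
                inflow <- inflow + counts[j] * prod(dropP(pj, pat))
                if (all(pat[d] == 2L) && is.na(hom_only)) hom_only <- j
            }
        }
        if (!is.na(hom_only)) {        # HET->HOM only: LOH vs ADO rule
            frac <- counts[i] / (counts[i] + counts[hom_only])
            if (frac < cc$ado_hom_threshold) next        # absorbed
        } else if (inflow > 0 && counts[i] <= cc$artifact_fold * inflow) {
            next                                         # dropout artifact
        }
        if (counts[i] >= min_clone_size) accepted <- c(accepted, i)
    }

    if (!length(accepted)) {
        asn <- setNames(rep("unassigned", ncol(g)), colnames(g))
        all_wt <- apply(g, 2, function(col) all(col == 0L, na.rm = TRUE)) &
            colSums(!is.na(g)) > 0
        asn[all_wt] <- "WT"
        return(methods::new("CloneSet",
            genotype = matrix(integer(0), 0, V,
                              dimnames = list(NULL, rownames(g))),
            nCells = integer(0), assignments = asn,
            nWildtype = sum(asn == "WT"),
            nUnassigned = sum(asn == "unassigned"),
            variants = rownames(g)))
    }

    clone_gt <- pats[accepted, , drop = FALSE]
    rownames(clone_gt) <- paste0("clone_", seq_along(accepted))
    colnames(clone_gt) <- rownames(g)
    ## assignment: clones + wildtype pseudo-clone, size priors
    nWT0 <- if (wt_key %in% names(tab)) as.integer(tab[wt_key]) else 0L
    prior_sizes <- c(counts[accepted], max(nWT0, 1L))
    full_gt <- rbind(clone_gt, WT = rep(0L, V))
    obsM <- .adoObsMatrix(a)
    logT <- log(obsM)                  # -Inf for impossible transitions

    asn <- setNames(rep("unassigned", ncol(g)), colnames(g))
    gc_ <- g[, complete, drop = FALSE]
    ll <- matrix(-Inf, nrow(full_gt), ncol(gc_))
    for (r in seq_len(nrow(full_gt))) {
        lt <- matrix(logT[cbind(rep(full_gt[r, ] + 1L, ncol(gc_)),
                                as.vector(gc_) + 1L)],
                     V, ncol(gc_))
        ll[r, ] <- colSums(lt) + log(prior_sizes[r])
    }
    best <- apply(ll, 2, which.max)
    bestval <- ll[cbind(best, seq_len(ncol(gc_)))]
    lab <- rownames(full_gt)[best]
    lab[!is.finite(bestval)] <- "unassigned"
    asn[complete] <- lab

    if (any(!complete)) {
        gi <- g[, !complete, drop = FALSE]
        lab2 <- vapply(seq_len(ncol(gi)), function(cix) {
            obs <- gi[, cix]
            seen <- !is.na(obs)
            if (!any(seen)) return("unassigned")
            hits <- which(apply(full_gt, 1, function(cg)
                all(cg[seen] == obs[seen])))
            if (length(hits) == 1L) rownames(full_gt)[hits]
            else "unassigned"
        }, character(1))
        asn[!complete] <- lab2
    }

    n_by <- table(factor(asn, levels = rownames(clone_gt)))
    keep <- as.integer(n_by) >= min_clone_size
    if (!all(keep)) {
        asn[asn %in% rownames(clone_gt)[!keep]] <- "unassigned"
        clone_gt <- clone_gt[keep, , drop = FALSE]
        rownames(clone_gt) <- paste0("clone_", seq_len(nrow(clone_gt)))
        return(inferClonesFinalize(clone_gt, asn, rownames(g)))
    }
    inferClonesFinalize(clone_gt, asn, rownames(g))
}

## assemble a CloneSet from a genotype matrix and raw assignment labels
inferClonesFinalize <- function(clone_gt, asn, variants) {
    ids <- rownames(clone_gt)
    nC <- as.integer(table(factor(asn, levels = ids)))
    ord <- order(nC, decreasing = TRUE)
    clone_gt <- clone_gt[ord, , drop = FALSE]
    nC <- nC[ord]
    new_ids <- paste0("clone_", seq_along(ord))
    map <- setNames(new_ids, ids[ord])
    asn[asn %in% names(map)] <- map[asn[asn %in% names(map)]]
    rownames(clone_gt) <- new_ids
    methods::new("CloneSet", genotype = clone_gt, nCells = nC,
                 assignments = asn,
                 nWildtype = sum(asn == "WT"),
                 nUnassigned = sum(asn == "unassigned"),
                 variants = variants)
}

#' Detect loss of heterozygosity between parent and child genotypes
#'
#' A heterozygous parent site that is wildtype in the child lost the
#' alternate allele; one that became homozygous lost the reference allele.
#'
#' @param parent,child complete named integer genotype vectors
#'   (\code{\link{GT_CODES}}).
#' @return data.frame with columns \code{variant}, \code{lost_allele}
#'   (\code{"ref"}/\code{"alt"}); zero rows when no LOH.
#' @examples
#' detectLOH(c(v1 = 1L, v2 = 1L), c(v1 = 0L, v2 = 2L))
#' @export
detectLOH <- function(parent, child) {
    stopifnot(length(parent) == length(child), !anyNA(parent),
              !anyNA(child))
    v <- names(parent)
    alt_lost <- parent == 1L & child == 0L
    ref_lost <- parent == 1L & child == 2L
    data.frame(
        variant = c(v[alt_lost], v[ref_lost]),
        lost_allele = c(rep("alt", sum(alt_lost)),
                        rep("ref", sum(ref_lost))),
        stringsAsFactors = FALSE)
}

## cost of explaining child C as a direct descendant of parent P:
## Inf when impossible (a homozygous site cannot regain the reference
## allele), otherwise the number of LOH events required; mutation gains
## are free.
.descentCost <- function(P, C) {
    if (any(P == 2L & C < 2L)) return(Inf)
    sum(P == 1L & C != 1L)
}

#' Order clones by developmental precedence
#'
#' The parent of a clone C is the clone whose mutated-variant set is the
#' maximal proper subset of C's, allowing loss-of-heterozygosity: a parent
#' heterozygous variant may be wildtype (alt lost) or homozygous (ref
#' lost) in the child. When two clones could each descend from the other,
#' the direction requiring fewer LOH events is kept (mutation gains are
#' free). Clones with no parent attach to the wildtype population; a clone
#' with several incomparable maximal parents has all candidate edges
#' recorded and the graph is flagged non-tree.
#'
#' @param clones a \linkS4class{CloneSet} with at least one clone.
#' @return A \linkS4class{CloneGraph}; each non-root edge is annotated
#'   with its LOH events.
#' @export
buildCloneGraph <- function(clones) {
    gt <- clones@genotype
    if (!nrow(gt)) stop("need at least one clone")
    ids <- rownames(gt)
    mutsize <- rowSums(gt >= 1L)
    edges <- data.frame(parent = character(0), child = character(0))
    loh <- data.frame(parent = character(0), child = character(0),
                      variant = character(0), lost_allele = character(0))
    nonTree <- FALSE
    for (ci in seq_along(ids)) {
        C <- gt[ci, ]
        cand <- c()
        for (pi in seq_along(ids)) {
            if (pi == ci) next
            P <- gt[pi, ]
            fwd <- .descentCost(P, C)
            if (!is.finite(fwd)) next
            ## an LOH-mediated descent needs shared mutation evidence:
            ## a clone sharing no mutated variant is an independent
            ## branch, not an ancestor whose mutations were all lost
            if (fwd > 0 && !any(P >= 1L & C >= 1L)) next
            rev <- .descentCost(C, P)
            if (is.finite(rev) && rev <= fwd) next  # pi is descendant/sibling
            cand <- c(cand, pi)
        }
        if (!length(cand)) {
            edges <- rbind(edges,
                           data.frame(parent = "WT", child = ids[ci]))
            next
        }
        best <- cand[mutsize[cand] == max(mutsize[cand])]
        if (length(best) > 1) nonTree <- TRUE
        for (pi in best) {
            edges <- rbind(edges,
                           data.frame(parent = ids[pi], child = ids[ci]))
            ev <- detectLOH(gt[pi, ], C)
            if (nrow(ev))
                loh <- rbind(loh, data.frame(
                    parent = ids[pi], child = ids[ci],
                    variant = ev$variant, lost_allele = ev$lost_allele))
        }
    }
    ## validity: every edge must be subset-ordered or LOH-explained
    for (k in seq_len(nrow(edges))) {
        p <- edges$parent[k]
        if (p == "WT") next
        missing_mut <- names(which(gt[p, ] >= 1L & gt[edges$child[k], ] == 0L))
        explained <- loh$variant[loh$parent == p &
                                 loh$child == edges$child[k]]
        if (!all(missing_mut %in% explained))
            stop("invalid clone graph edge: ", p, " -> ", edges$child[k])
    }
    methods::new("CloneGraph", clones = clones, edges = edges, loh = loh,
                 nonTree = nonTree)
}
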