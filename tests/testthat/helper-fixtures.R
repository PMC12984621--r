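# Fixture builders shared across the suite. Everything is generated in
# code; genotype matrices get depth/GQ/AF assays consistent with the
# cell-level calling gates (depth 100 / GQ 99; AF 0.01 / 0.5 / 0.98 for
# WT / HET / HOM; missing entries get depth 5).

makeMatrix <- function(g, role = "somatic", pos = NULL, chrom = "chr1",
                       gene = "GENE1", synonymous = FALSE,
                       homopolymer = FALSE, pop_af = 0,
                       germline_flag = FALSE, antibody = NULL) {
    storage.mode(g) <- "integer"
    if (is.null(rownames(g)))
        rownames(g) <- paste0("v", seq_len(nrow(g)))
    if (is.null(colnames(g)))
        colnames(g) <- paste0("c", seq_len(ncol(g)))
    af <- matrix(c(0.01, 0.5, 0.98)[g + 1L], nrow(g), ncol(g),
                 dimnames = dimnames(g))
    af[is.na(g)] <- 0
    depth <- matrix(100, nrow(g), ncol(g), dimnames = dimnames(g))
    depth[is.na(g)] <- 5
    gq <- matrix(99, nrow(g), ncol(g), dimnames = dimnames(g))
    n <- nrow(g)
    rd <- S4Vectors::DataFrame(
        chrom = rep_len(chrom, n),
        pos = if (is.null(pos)) seq(1e4, by = 1e4, length.out = n)
              else pos,
        ref = rep("A", n), alt = rep("T", n),
        gene = rep_len(gene, n),
        protein_change = rep(NA_character_, n),
        synonymous = rep_len(synonymous, n),
        homopolymer = rep_len(homopolymer, n),
        pop_af = rep_len(pop_af, n),
        germline_flag = rep_len(germline_flag, n),
        role = rep_len(role, n),
        row.names = rownames(g))
    CellGenotypeMatrix(g, depth, gq, af, rd, antibody = antibody)
}

# 8-variant fixture with one designed violation per variant-level filter;
# every variant gets its own disjoint cell block so no co-occurrence
# exemption applies.
filterFixture <- function() {
    vars <- c("clean", "min3", "syn", "hp", "prox", "germ", "min6", "hom")
    blocks <- list(clean = 10, min3 = 2, syn = 10, hp = 10, prox = 10,
                   germ = 10, min6 = 5, hom = 10)
    ncell <- sum(unlist(blocks))
    g <- matrix(0L, length(vars), ncell,
                dimnames = list(vars, paste0("c", seq_len(ncell))))
    at <- 0
    for (v in vars) {
        n <- blocks[[v]]
        idx <- at + seq_len(n); at <- at + n
        gt <- if (v == "hom") rep(1L, n)           # no homozygous cell
              else c(rep(1L, n - max(1, n %/% 5)),
                     rep(2L, max(1, n %/% 5)))     # mostly HET + HOM
        g[v, idx] <- gt
    }
    pos <- c(10000, 20000, 30000, 40000, 50000, 50100, 70000, 80000)
    x <- makeMatrix(g, pos = pos,
                    synonymous = vars == "syn",
                    homopolymer = vars == "hp",
                    pop_af = ifelse(vars == "germ", 0.002, 0))
    list(x = x, vars = vars)
}

# clone-structure matrix from clone genotype rows and sizes
cloneMatrix <- function(clone_gt, sizes, n_wt = 0) {
    cols <- list()
    for (i in seq_len(nrow(clone_gt)))
        cols[[i]] <- matrix(clone_gt[i, ], ncol = sizes[i],
                            nrow = ncol(clone_gt))
    if (n_wt > 0)
        cols[[length(cols) + 1]] <- matrix(0L, ncol(clone_gt), n_wt)
    g <- do.call(cbind, cols)
    rownames(g) <- colnames(clone_gt)
    colnames(g) <- paste0("c", seq_len(ncol(g)))
    makeMatrix(g)
}

# brute-force beta-binomial upper tail by direct enumeration (independent
# of the implementation's complement shortcut)
bruteTail <- function(k, n, mu, rho) {
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    if (k > n) return(0)
    sum(vapply(k:n, function(j)
        exp(lchoose(n, j) + lbeta(j + a, n - j + b) - lbeta(a, b)),
        numeric(1)))
}

# independent brute-force demux log-likelihood (mirrors the documented
# observation model, written separately from the implementation)
bruteLogLik <- function(obs, expected, eps) {
    ll <- 0
    for (l in seq_along(obs)) {
        if (is.na(obs[l])) next
        e <- expected[l]
        p <- if (abs(e - round(e)) < 1e-9) {
            if (abs(obs[l] - e) < 1e-9) 1 - eps else eps / 2
        } else {
            if (abs(obs[l] - e) == 0.5) (1 - eps) / 2 else eps
        }
        ll <- ll + log(p)
    }
    ll
}
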