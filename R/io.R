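## ---- germline profiles: multi-sample VCF -------------------------------

#' Read and write germline-SNP profiles as multi-sample VCF
#'
#' One sample column per patient, genotypes in the GT field (0/0, 0/1,
#' 1/1). Positions are 1-based as in any VCF-facing record.
#'
#' @param profiles integer matrix, patients x loci, of alt-allele copies.
#' @param loci data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} per locus.
#' @param path file path.
#' @return \code{readGermlineVCF}: list with \code{profiles} and
#'   \code{loci}.
#' @export
writeGermlineVCF <- function(profiles, loci, path) {
    stopifnot(ncol(profiles) == nrow(loci))
    gtstr <- matrix(c("0/0", "0/1", "1/1")[profiles + 1L],
                    nrow(profiles), ncol(profiles))
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", rownames(profiles)),
                   collapse = "\t"))
    ids <- if (!is.null(colnames(profiles))) colnames(profiles)
           else paste0("snp", seq_len(ncol(profiles)))
    body <- vapply(seq_len(nrow(loci)), function(i)
        paste(c(loci$chrom[i], loci$pos[i], ids[i], loci$ref[i],
                loci$alt[i], ".", "PASS", ".", "GT", gtstr[, i]),
              collapse = "\t"), character(1))
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' @rdname writeGermlineVCF
#' @export
readGermlineVCF <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                     dimnames = dimnames(gt))
    dosage[gt %in% c("0/0", "0|0")] <- 0L
    dosage[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    dosage[gt %in% c("1/1", "1|1")] <- 2L
    fix <- vcfR::getFIX(v)
    list(profiles = t(dosage),
         loci = data.frame(chrom = fix[, "CHROM"],
                           pos = as.integer(fix[, "POS"]),
                           ref = fix[, "REF"], alt = fix[, "ALT"],
                           stringsAsFactors = FALSE))
}

## ---- cell matrices: CSV assays + MTX antibody counts -------------------

#' Write and read a CellGenotypeMatrix as plain-text files
#'
#' Assays go to CSV (one file each, \code{NA} for missing), locus
#' annotations and barcodes to TSV, antibody counts to MatrixMarket with
#' marker/barcode sidecars.
#'
#' @param x a \linkS4class{CellGenotypeMatrix}.
#' @param dir directory (created if needed).
#' @return \code{readCellGenotypeMatrix}: the reconstructed object.
#' @export
writeCellGenotypeMatrix <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (a in c("genotype", "depth", "GQ", "AF"))
        utils::write.csv(as.data.frame(assay(x, a)),
                         file.path(dir, paste0(a, ".csv")))
    write.table(as.data.frame(rowData(x)),
                file.path(dir, "loci.tsv"), sep = "\t", quote = FALSE)
    ab <- antibodyCounts(x)
    if (!is.null(ab)) {
        Matrix::writeMM(Matrix::Matrix(ab, sparse = TRUE),
                        file.path(dir, "antibody.mtx"))
        writeLines(rownames(ab), file.path(dir, "antibody.markers.txt"))
        writeLines(colnames(ab), file.path(dir, "antibody.barcodes.txt"))
    }
    invisible(dir)
}

#' @rdname writeCellGenotypeMatrix
#' @export
readCellGenotypeMatrix <- function(dir) {
    rd_assay <- function(a) as.matrix(utils::read.csv(
        file.path(dir, paste0(a, ".csv")), row.names = 1,
        check.names = FALSE))
    rd <- read.delim(file.path(dir, "loci.tsv"), row.names = 1)
    ab <- NULL
    if (file.exists(file.path(dir, "antibody.mtx"))) {
        ab <- as.matrix(Matrix::readMM(file.path(dir, "antibody.mtx")))
        rownames(ab) <- readLines(file.path(dir, "antibody.markers.txt"))
        colnames(ab) <- readLines(file.path(dir, "antibody.barcodes.txt"))
        storage.mode(ab) <- "integer"
    }
    g <- rd_assay("genotype")
    CellGenotypeMatrix(genotype = g, depth = rd_assay("depth"),
                       GQ = rd_assay("GQ"), AF = rd_assay("AF"),
                       rowData = DataFrame(rd), antibody = ab)
}

## ---- longitudinal series and comparator days ---------------------------

#' Read and write ddPCR measurement series as TSV
#'
#' Columns: \code{day}, \code{tissue}, \code{vaf_percent},
#' \code{alleles}, \code{dna_limited}. Unsorted days are sorted on read
#' with a warning.
#'
#' @param series an \linkS4class{MrdSeries}.
#' @param path file path.
#' @param lod,target,config passed to \code{\link{MrdSeries}} on read.
#' @return \code{readMrdSeriesTSV}: an \linkS4class{MrdSeries}.
#' @export
writeMrdSeriesTSV <- function(series, path) {
    s <- series@samples
    write.table(data.frame(day = s$day, tissue = s$tissue,
                           vaf_percent = s$vaf, alleles = s$alleles,
                           dna_limited = s$dna_limited),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeMrdSeriesTSV
#' @export
readMrdSeriesTSV <- function(path, lod, target = "target",
                             config = runConfig()) {
    d <- read.delim(path)
    for (tis in unique(d$tissue))
        if (is.unsorted(d$day[d$tissue == tis], strictly = TRUE)) {
            warning("series days not sorted; sorting on read")
            d <- d[order(d$day), , drop = FALSE]
            break
        }
    MrdSeries(day = d$day, tissue = d$tissue, vaf = d$vaf_percent,
              lod = lod, alleles = d$alleles,
              dna_limited = d$dna_limited, target = target,
              config = config)
}

#' Read and write conventional-method MRD detection days
#'
#' A long TSV mirroring a first-positive-day comparison table: columns
#' \code{method}, \code{day} (NA when the method never detected MRD) and
#' optional \code{testing_interval}. The reader returns the named list
#' \code{\link{leadTime}} consumes.
#'
#' @param days named list (method -> numeric days).
#' @param path file path.
#' @return \code{readComparatorDaysTSV}: named list of numeric vectors.
#' @export
writeComparatorDaysTSV <- function(days, path) {
    d <- do.call(rbind, lapply(names(days), function(m)
        data.frame(method = m, day = days[[m]])))
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeComparatorDaysTSV
#' @export
readComparatorDaysTSV <- function(path) {
    d <- read.delim(path)
    split(d$day, d$method)[unique(d$method)]
}

## ---- EC-NGS counts and background model --------------------------------

#' Read and write EC-NGS per-strand counts as TSV
#'
#' Long format: \code{variant}, \code{strand} (\code{fwd}/\code{rev}),
#' \code{supporting}, \code{total}, \code{uao}.
#'
#' @param counts wide data.frame as produced by
#'   \code{\link{simulateEcngsCounts}}.
#' @param path file path.
#' @return \code{readEcngsCountsTSV}: wide data.frame.
#' @export
writeEcngsCountsTSV <- function(counts, path) {
    long <- rbind(
        data.frame(variant = counts$site, strand = "fwd",
                   supporting = counts$supporting_fwd,
                   total = counts$total_fwd, uao = counts$uao),
        data.frame(variant = counts$site, strand = "rev",
                   supporting = counts$supporting_rev,
                   total = counts$total_rev, uao = counts$uao))
    write.table(long[order(long$variant), ], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeEcngsCountsTSV
#' @export
readEcngsCountsTSV <- function(path) {
    d <- read.delim(path)
    f <- d[d$strand == "fwd", ]
    r <- d[d$strand == "rev", ]
    r <- r[match(f$variant, r$variant), ]
    data.frame(site = f$variant,
               supporting_fwd = f$supporting, total_fwd = f$total,
               supporting_rev = r$supporting, total_rev = r$total,
               uao = f$uao)
}

#' Serialize a background error model to JSON
#'
#' @param model an \linkS4class{EcngsBackground}.
#' @param path file path.
#' @return \code{readBackgroundJSON}: an \linkS4class{EcngsBackground}.
#' @export
writeBackgroundJSON <- function(model, path) {
    jsonlite::write_json(list(floor_rate = model@floorRate,
                              sites = model@sites),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeBackgroundJSON
#' @export
readBackgroundJSON <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    methods::new("EcngsBackground", sites = as.data.frame(j$sites),
                 floorRate = j$floor_rate)
}

## ---- configuration, reports --------------------------------------------

#' Read and write pipeline configuration as YAML
#'
#' @param config a \code{\link{runConfig}} list.
#' @param path file path.
#' @return \code{readConfigYAML}: a validated config list.
#' @export
writeConfigYAML <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' @rdname writeConfigYAML
#' @export
readConfigYAML <- function(path) {
    do.call(runConfig, yaml::read_yaml(path))
}

#' Export tabular reports
#'
#' \code{writeCriteriaTSV} writes the per-candidate criteria table;
#' \code{writeCloneTableTSV} the clone table (genotype string, size,
#' parent, LOH events); \code{exportCloneGraphDOT} a Graphviz DOT
#' rendering of the clone graph; \code{writeTargetsJSON} the ranked
#' selected targets.
#'
#' @param results criteria \code{DataFrame} from
#'   \code{\link{evaluateCriteria}} (or \code{\link{selectTargets}}).
#' @param graph a \linkS4class{CloneGraph}.
#' @param path file path.
#' @export
writeCriteriaTSV <- function(results, path) {
    write.table(as.data.frame(results), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCriteriaTSV
#' @export
writeCloneTableTSV <- function(graph, path) {
    cs <- graph@clones
    gt <- cs@genotype
    parent <- setNames(graph@edges$parent, graph@edges$child)
    loh_str <- vapply(rownames(gt), function(cl) {
        l <- graph@loh[graph@loh$child == cl, ]
        if (!nrow(l)) "" else paste(l$variant, l$lost_allele,
                                    sep = ":", collapse = ",")
    }, character(1))
    d <- data.frame(clone_id = rownames(gt),
                    genotype = apply(gt, 1, paste, collapse = ""),
                    n_cells = cs@nCells,
                    parent = unname(parent[rownames(gt)]),
                    loh = loh_str)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCriteriaTSV
#' @export
exportCloneGraphDOT <- function(graph, path) {
    cs <- graph@clones
    lines <- c("digraph clones {",
               sprintf("  WT [label=\"wildtype (n=%d)\"];",
                       cs@nWildtype),
               sprintf("  %s [label=\"%s (n=%d)\"];",
                       rownames(cs@genotype), rownames(cs@genotype),
                       cs@nCells),
               sprintf("  %s -> %s;", graph@edges$parent,
                       graph@edges$child),
               "}")
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeCriteriaTSV
#' @export
writeTargetsJSON <- function(results, path) {
    jsonlite::write_json(as.data.frame(results), path,
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}
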