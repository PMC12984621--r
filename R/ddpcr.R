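#' ddPCR limit of detection from wildtype wells
#'
#' The limit of detection (LoD) of a ddPCR assay is estimated during assay
#' validation from wells containing only wildtype DNA (20 by convention):
#' \deqn{LoD = \bar{x}_{WT} + 3.08\, \sigma_{WT}}
#' with z = 3.08 corresponding to a one-tailed alpha of 0.001. The standard
#' deviation is the sample standard deviation (n - 1 denominator).
#'
#' @param wildtype_wells numeric vector of wildtype-well VAF measurements
#'   (percent); at least 2 wells.
#' @param config a \code{\link{runConfig}} list (\code{mrd$lod_z}).
#' @return LoD as a VAF percentage.
#' @examples
#' computeLoD(rep(0, 20))                 # 0
#' computeLoD(c(0.005, 0.010, 0.015))     # mean + 3.08 * sd
#' @export
computeLoD <- function(wildtype_wells, config = runConfig()) {
    if (length(wildtype_wells) < 2)
        stop("need at least 2 wildtype wells to estimate an LoD")
    mean(wildtype_wells) + config$mrd$lod_z * sd(wildtype_wells)
}

#' Rule-of-three VAF floor for DNA-limited samples
#'
#' With zero mutant events observed among n assessable allele observations,
#' the 95\% upper bound on the event rate is approximately 3/n (the rule of
#' three). Below this VAF a negative ddPCR result is uninformative, so the
#' RoT replaces the LoD as the positivity threshold whenever DNA input, not
#' assay chemistry, limits sensitivity.
#'
#' @param assessable_alleles number of assessable allele observations
#'   (> 0). With \code{config$mrd$rot_unit = "genome_equivalents"} the
#'   input is interpreted as diploid genome equivalents (2 alleles each).
#' @param config a \code{\link{runConfig}} list.
#' @return RoT threshold as a VAF percentage.
#' @examples
#' rotThreshold(10000)  # 0.03
#' rotThreshold(300)    # 1.0
#' @export
rotThreshold <- function(assessable_alleles, config = runConfig()) {
    if (any(assessable_alleles <= 0))
        stop("assessable allele count must be positive")
    n <- if (config$mrd$rot_unit == "genome_equivalents")
        2 * assessable_alleles else assessable_alleles
    100 * config$mrd$rot_events / n
}

#' Classify a single MRD sample as positive or negative
#'
#' MRD positivity is a detected VAF above the LoD, or above the
#' rule-of-three floor when DNA input is the limiting factor (i.e. the
#' threshold is the larger of LoD and RoT for DNA-limited samples). A VAF
#' exactly at the threshold is positive by default (the positivity clause
#' reads "VAF >= LoD"); set \code{mrd$boundary_positive = FALSE} for strict
#' inequality.
#'
#' @param measured_vaf measured VAF (percent); vectorized.
#' @param lod assay LoD (percent).
#' @param rot rule-of-three threshold (percent); may be \code{NA} when not
#'   DNA-limited.
#' @param dna_limited logical; was DNA input the limiting factor?
#' @param config a \code{\link{runConfig}} list.
#' @return logical positivity.
#' @export
classifySample <- function(measured_vaf, lod, rot = NA_real_,
                           dna_limited = FALSE, config = runConfig()) {
    thr <- ifelse(dna_limited, pmax(lod, rot, na.rm = TRUE), lod)
    if (config$mrd$boundary_positive) measured_vaf >= thr
    else measured_vaf > thr
}

#' Assemble an MrdSeries from longitudinal measurements
#'
#' Computes the per-sample rule-of-three threshold from the assessable
#' allele count, flags DNA-limited samples (RoT above LoD) unless flags are
#' supplied, and classifies each sample via \code{\link{classifySample}}.
#'
#' @param day integer days since diagnosis.
#' @param tissue \code{"PB"} or \code{"BM"} per sample.
#' @param vaf measured VAF percentages.
#' @param lod assay LoD (percent).
#' @param alleles assessable allele observations per sample (default 2e5,
#'   i.e. DNA never limiting for typical LoDs).
#' @param dna_limited optional logical per sample; default: RoT > LoD.
#' @param target target label.
#' @param config a \code{\link{runConfig}} list.
#' @return An \linkS4class{MrdSeries}.
#' @export
MrdSeries <- function(day, tissue, vaf, lod, alleles = 2e5,
                      dna_limited = NULL, target = "target",
                      config = runConfig()) {
    n <- length(day)
    s <- data.frame(day = day, tissue = tissue, vaf = vaf,
                    alleles = rep_len(alleles, n))
    s$rot <- rotThreshold(s$alleles, config)
    s$dna_limited <- if (is.null(dna_limited)) s$rot > lod
                     else rep_len(dna_limited, n)
    s <- s[order(s$day, s$tissue), , drop = FALSE]
    rownames(s) <- NULL
    s$positive <- classifySample(s$vaf, lod, s$rot, s$dna_limited, config)
    methods::new("MrdSeries", samples = s, lod = lod, target = target)
}

#' ELN-style MRD relapse calling on a measurement series
#'
#' Samples from all tissues are merged chronologically and scanned for two
#' mechanisms: (a) \emph{conversion} -- a transition from MRD negativity to
#' MRD positivity that is confirmed by any subsequent positive sample; and
#' (b) \emph{tenfold} -- an increase in VAF of 10-fold or higher between
#' two consecutive positive samples. The first sample indicating relapse
#' (the transition sample for conversion; the risen sample for tenfold)
#' dates the relapse; when both mechanisms fire the earlier day wins
#' (conversion on ties).
#'
#' @param series an \linkS4class{MrdSeries}.
#' @param config a \code{\link{runConfig}} list (\code{mrd$fold_change},
#'   \code{mrd$tenfold_same_tissue}).
#' @return An \linkS4class{MrdCall}.
#' @export
callRelapse <- function(series, config = runConfig()) {
    s <- series@samples
    if (!nrow(s))
        return(methods::new("MrdCall", relapse = FALSE, day = NA_real_,
                            mechanism = "none",
                            confirmingDay = NA_real_))
    noCall <- methods::new("MrdCall", relapse = FALSE, day = NA_real_,
                           mechanism = "none", confirmingDay = NA_real_)
    conv_day <- NA_real_; conv_confirm <- NA_real_
    n <- nrow(s)
    for (i in seq_len(n)[-1]) {
        if (!s$positive[i - 1] && s$positive[i] && i < n &&
            any(s$positive[(i + 1):n])) {
            conv_day <- s$day[i]
            conv_confirm <- s$day[which(s$positive &
                                        seq_len(n) > i)[1]]
            break
        }
    }
    ten_day <- NA_real_; ten_first <- NA_real_
    tenScan <- function(sub) {
        pos <- sub[sub$positive, , drop = FALSE]
        if (nrow(pos) >= 2) {
            ratio <- pos$vaf[-1] / pos$vaf[-nrow(pos)]
            ratio[pos$vaf[-nrow(pos)] == 0 & pos$vaf[-1] > 0] <- Inf
            hit <- which(ratio >= config$mrd$fold_change)
            if (length(hit))
                return(c(pos$day[hit[1] + 1], pos$day[hit[1]]))
        }
        c(NA_real_, NA_real_)
    }
    if (isTRUE(config$mrd$tenfold_same_tissue)) {
        for (tis in unique(s$tissue)) {
            r <- tenScan(s[s$tissue == tis, , drop = FALSE])
            if (!is.na(r[1]) && (is.na(ten_day) || r[1] < ten_day)) {
                ten_day <- r[1]; ten_first <- r[2]
            }
        }
    } else {
        r <- tenScan(s)
        ten_day <- r[1]; ten_first <- r[2]
    }
    if (is.na(conv_day) && is.na(ten_day)) return(noCall)
    if (!is.na(conv_day) && (is.na(ten_day) || conv_day <= ten_day))
        methods::new("MrdCall", relapse = TRUE, day = conv_day,
                     mechanism = "conversion", confirmingDay = conv_confirm)
    else
        methods::new("MrdCall", relapse = TRUE, day = ten_day,
                     mechanism = "tenfold", confirmingDay = ten_day)
}

#' Lead time of ddPCR relapse detection over conventional methods
#'
#' Signed difference (ddPCR detection day minus comparator detection day)
#' per conventional method and per relapse event; negative values mean
#' ddPCR detected relapse earlier. Events are paired by order; methods that
#' never detected MRD positivity (all \code{NA}) are skipped.
#'
#' @param ddpcr_days numeric vector of ddPCR first-positive days (one per
#'   relapse event).
#' @param comparator_days named list (method -> numeric vector of detection
#'   days, \code{NA} for not detected).
#' @return Named list of numeric lead-time vectors (days), one per
#'   comparator method with at least one detection.
#' @examples
#' leadTime(c(86, 558), list(WT1 = c(355, 673)))  # -269, -115
#' leadTime(467, list(WT1 = 805, MFC = 805))      # -338 for both
#' @export
leadTime <- function(ddpcr_days, comparator_days) {
    if (!length(ddpcr_days) || all(is.na(ddpcr_days)))
        stop("no ddPCR detection day available")
    out <- list()
    for (m in names(comparator_days)) {
        cd <- comparator_days[[m]]
        if (all(is.na(cd))) next
        k <- min(length(ddpcr_days), length(cd))
        lt <- ddpcr_days[seq_len(k)] - cd[seq_len(k)]
        out[[m]] <- lt[!is.na(lt)]
    }
    out
}
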