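#' Beta-binomial density and upper-tail probability
#'
#' Mean/overdispersion parameterization: with mean error rate \code{mu} and
#' overdispersion \code{rho} in (0, 1), the shape parameters are
#' \code{a = mu (1 - rho) / rho}, \code{b = (1 - mu)(1 - rho) / rho};
#' \code{rho -> 0} recovers the binomial.
#'
#' \code{pBetaBinomTail} returns P(X >= k). For small \code{k} it
#' complements the lower cumulative sum; when the upper tail is shorter it
#' sums the tail directly, so small instances agree with brute-force
#' enumeration to machine precision.
#'
#' @param k,n counts (k successes of n trials); vectorized over \code{k}.
#' @param mu mean success probability in (0, 1).
#' @param rho overdispersion in (0, 1).
#' @return \code{dBetaBinom}: probability mass; \code{pBetaBinomTail}:
#'   upper-tail probability P(X >= k).
#' @export
dBetaBinom <- function(k, n, mu, rho) {
    stopifnot(mu > 0, mu < 1, rho > 0, rho < 1)
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    exp(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

#' @rdname dBetaBinom
#' @export
pBetaBinomTail <- function(k, n, mu, rho) {
    vapply(k, function(ki) {
        if (ki <= 0) return(1)
        if (ki > n) return(0)
        if (ki - 1 <= n - ki + 1) {
            p <- 1 - sum(dBetaBinom(0:(ki - 1), n, mu, rho))
            max(p, 0)
        } else {
            sum(dBetaBinom(ki:n, n, mu, rho))
        }
    }, numeric(1))
}

#' Fit a per-site, per-strand beta-binomial background error model
#'
#' Method-of-moments fit from reference (variant-negative) samples. Per
#' site and strand, the mean error rate is the (optionally trimmed) mean of
#' the per-sample supporting-read fractions, floored at
#' \code{ecngs$floor_rate} to avoid degenerate zero-error sites, and the
#' overdispersion is solved from the variance of those fractions
#' (\code{Var(p) = mu (1 - mu) (1 + (n - 1) rho) / n}). Trimming (config
#' \code{ecngs$trim}, a fraction per tail) robustifies the mean against
#' outlier references while leaving the dispersion estimate on the full
#' data, so a contaminated reference inflates dispersion rather than the
#' mean.
#'
#' @param reference_counts data.frame with columns \code{site},
#'   \code{strand} (\code{"fwd"}/\code{"rev"}), \code{supporting},
#'   \code{total}; one row per reference sample per site per strand
#'   (>= 3 samples each).
#' @param config a \code{\link{runConfig}} list.
#' @return An \linkS4class{EcngsBackground}.
#' @export
fitBackground <- function(reference_counts, config = runConfig()) {
    ec <- config$ecngs
    fit1 <- function(k, n) {
        if (length(k) < 3)
            stop("need >= 3 reference samples per site and strand")
        p <- k / n
        m <- mean(p, trim = ec$trim)
        if (m <= 0) {
            warning("all-zero reference counts at a site; ",
                    "model floored at ", ec$floor_rate)
            m <- 0
        }
        mu <- max(m, ec$floor_rate)
        nbar <- mean(n)
        v <- stats::var(p)
        rho <- if (v > 0 && mu < 1)
            (v * nbar / (mu * (1 - mu)) - 1) / (nbar - 1)
        else 0
        rho <- min(max(rho, 1e-8), 0.9)
        c(mu = min(mu, 1 - 1e-12), rho = rho)
    }
    sites <- unique(reference_counts$site)
    rows <- lapply(sites, function(s) {
        d <- reference_counts[reference_counts$site == s, ]
        f <- fit1(d$supporting[d$strand == "fwd"],
                  d$total[d$strand == "fwd"])
        r <- fit1(d$supporting[d$strand == "rev"],
                  d$total[d$strand == "rev"])
        data.frame(site = s, mu_fwd = f["mu"], rho_fwd = f["rho"],
                   mu_rev = r["mu"], rho_rev = r["rho"],
                   row.names = NULL)
    })
    methods::new("EcngsBackground", sites = do.call(rbind, rows),
                 floorRate = ec$floor_rate)
}

.modelRow <- function(model, site) {
    i <- match(site, model@sites$site)
    if (is.na(i)) stop("no background model for site: ", site)
    model@sites[i, ]
}

#' Posterior error probability of an observed site under the background
#'
#' The probability that counts at least as supportive as observed arise
#' from the background beta-binomial error model. Strand direction is
#' taken into consideration: each strand is scored separately and the
#' maximum of the two strand probabilities is returned, so a site must be
#' inconsistent with background on \emph{both} strands to reach
#' significance (one-strand-only support is an artifact signature and
#' never significant).
#'
#' @param site list or one-row data.frame with \code{site},
#'   \code{supporting_fwd}, \code{total_fwd}, \code{supporting_rev},
#'   \code{total_rev}.
#' @param model an \linkS4class{EcngsBackground}.
#' @return Error probability in [0, 1]; per-strand values in attribute
#'   \code{"strand"}.
#' @export
posteriorError <- function(site, model) {
    m <- .modelRow(model, site$site)
    pf <- pBetaBinomTail(site$supporting_fwd, site$total_fwd,
                         m$mu_fwd, m$rho_fwd)
    pr <- pBetaBinomTail(site$supporting_rev, site$total_rev,
                         m$mu_rev, m$rho_rev)
    structure(max(pf, pr), strand = c(fwd = pf, rev = pr))
}

#' Call a variant from error-corrected counts
#'
#' A variant is called when its posterior error probability is below the
#' calling threshold (1\% default) \emph{and} it is supported by at least
#' \code{uao_min} unique alternative observations (distinct consensus read
#' families; default 3).
#'
#' @inheritParams posteriorError
#' @param uao_min minimum unique alternative observations.
#' @param threshold maximum posterior error probability.
#' @return logical; attributes \code{"posterior"} and \code{"uao"}.
#' @export
callVariant <- function(site, model, uao_min = 3L, threshold = 0.01) {
    p <- posteriorError(site, model)
    called <- as.numeric(p) < threshold && site$uao >= uao_min
    structure(called, posterior = as.numeric(p), uao = site$uao)
}

#' Minimal supporting reads needed to call a variant
#'
#' Probes assay sensitivity by modifying the supporting-read counts while
#' holding the per-strand totals constant: the smallest total supporting
#' count k (split across strands in proportion to their totals, each
#' supporting read counting as its own consensus family) for which
#' \code{\link{callVariant}} fires. Found by bisection, which is valid
#' because the posterior error probability is non-increasing in the
#' supporting counts at fixed totals.
#'
#' @param site_template list/one-row data.frame with \code{site},
#'   \code{total_fwd}, \code{total_rev} (supporting counts are ignored).
#' @param model an \linkS4class{EcngsBackground}.
#' @inheritParams callVariant
#' @return Minimal total supporting reads, or \code{NA} (with a message)
#'   when the variant is not callable even at k = total.
#' @export
sensitivityProbe <- function(site_template, model, uao_min = 3L,
                             threshold = 0.01) {
    nf <- site_template$total_fwd
    nr <- site_template$total_rev
    split_k <- function(k) {
        kf <- min(floor(k * nf / (nf + nr)), nf)
        c(kf, min(k - kf, nr))
    }
    fires <- function(k) {
        ks <- split_k(k)
        s <- list(site = site_template$site,
                  supporting_fwd = ks[1], total_fwd = nf,
                  supporting_rev = ks[2], total_rev = nr,
                  uao = k)
        isTRUE(as.logical(callVariant(s, model, uao_min, threshold)))
    }
    hi <- nf + nr
    if (!fires(hi)) {
        message("site not callable at any supporting count ",
                "(not-assessable)")
        return(NA_integer_)
    }
    lo <- 0L
    while (hi - lo > 1L) {      # invariant: !fires(lo), fires(hi)
        mid <- (lo + hi) %/% 2L
        if (fires(mid)) hi <- mid else lo <- mid
    }
    as.integer(hi)
}
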