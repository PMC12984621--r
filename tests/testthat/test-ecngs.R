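test_that("beta-binomial tail matches brute-force enumeration (n <= 50)", {
    set.seed(13)
    for (i in 1:60) {
        n <- sample(1:50, 1)
        k <- sample(0:n, 1)
        mu <- runif(1, 1e-4, 0.3)
        rho <- runif(1, 1e-4, 0.5)
        expect_lt(abs(pBetaBinomTail(k, n, mu, rho) -
                      bruteTail(k, n, mu, rho)), 1e-10)
    }
    expect_equal(pBetaBinomTail(0, 100, 1e-4, 0.01), 1)
    expect_equal(pBetaBinomTail(101, 100, 1e-4, 0.01), 0)
})

test_that("posterior error probability is monotone in supporting reads", {
    p <- pBetaBinomTail(0:40, 10000, 1e-4, 0.01)
    expect_true(all(diff(p) <= 1e-15))
})

test_that("background fitting recovers the simulated error rate", {
    set.seed(17)
    nsite <- 300; nref <- 5; depth <- 10000; mu <- 1e-4
    refs <- do.call(rbind, lapply(seq_len(nsite), function(s) {
        k <- rbinom(2 * nref, depth, mu)
        data.frame(site = paste0("s", s),
                   strand = rep(c("fwd", "rev"), each = nref),
                   supporting = k, total = depth)
    }))
    # a few sites draw all-zero references by chance and floor, warning
    model <- suppressWarnings(fitBackground(refs))
    mu_hat <- mean(c(model@sites$mu_fwd, model@sites$mu_rev))
    expect_gt(mu_hat, mu / 2); expect_lt(mu_hat, mu * 2)
    # all-zero references floor with a warning
    z <- data.frame(site = "z", strand = rep(c("fwd", "rev"), each = 3),
                    supporting = 0, total = 10000)
    w <- capture_warnings(mz <- fitBackground(z))   # one per strand
    expect_match(w, "floored", all = TRUE)
    expect_equal(mz@sites$mu_fwd, runConfig()$ecngs$floor_rate)
    expect_error(fitBackground(z[c(1, 4), ]), ">= 3 reference")
})

test_that("trimmed fitting routes an outlier into dispersion, not mean", {
    base <- c(1, 0, 2, 1, 1, 0, 1, 2, 1)
    out <- c(base, 400)                  # one contaminated reference
    mk <- function(k) data.frame(
        site = "s", strand = rep(c("fwd", "rev"), each = length(k)),
        supporting = rep(k, 2), total = 10000)
    cfg <- runConfig(ecngs = list(trim = 0.1))
    m_clean <- fitBackground(mk(base), cfg)
    m_out <- fitBackground(mk(out), cfg)
    expect_lt(m_out@sites$mu_fwd / m_clean@sites$mu_fwd, 2)
    expect_gt(m_out@sites$rho_fwd, m_clean@sites$rho_fwd)
})

test_that("strand-aware calling requires both strands and the UAO floor", {
    refs <- data.frame(site = "s", strand = rep(c("fwd", "rev"), each = 4),
                       supporting = c(1, 2, 1, 0, 1, 1, 2, 0),
                       total = 10000)
    model <- fitBackground(refs)
    # no supporting reads: probability 1
    s0 <- list(site = "s", supporting_fwd = 0, total_fwd = 10000,
               supporting_rev = 0, total_rev = 10000, uao = 0)
    expect_equal(as.numeric(posteriorError(s0, model)), 1)
    # support on one strand only: the strand-wise AND fails
    s1 <- list(site = "s", supporting_fwd = 30, total_fwd = 10000,
               supporting_rev = 0, total_rev = 5000, uao = 30)
    expect_equal(as.numeric(posteriorError(s1, model)), 1)
    expect_false(as.logical(callVariant(s1, model)))
    # strong support on both strands, verified against the exact tail
    s2 <- list(site = "s", supporting_fwd = 20, total_fwd = 10000,
               supporting_rev = 20, total_rev = 10000, uao = 40)
    p <- posteriorError(s2, model)
    m <- model@sites
    expect_equal(as.numeric(p),
                 max(bruteTail(20, 10000, m$mu_fwd, m$rho_fwd),
                     bruteTail(20, 10000, m$mu_rev, m$rho_rev)))
    expect_lt(as.numeric(p), 0.01)
    expect_true(as.logical(callVariant(s2, model)))
    # significance with too few unique alternative observations
    s3 <- modifyList(s2, list(uao = 2))
    expect_false(as.logical(callVariant(s3, model)))
})

test_that("detection power at 0.1% VAF and 10,000x is high", {
    # background matched to the simulation's error model
    model <- new("EcngsBackground",
                 sites = data.frame(site = "s", mu_fwd = 1e-4,
                                    rho_fwd = 1e-5, mu_rev = 1e-4,
                                    rho_rev = 1e-5),
                 floorRate = 1e-6)
    sims <- simulateEcngsCounts(0.001, 10000, 1e-4, dispersion = 1e-5,
                                seed = 29, n_sites = 200)
    sims$site <- "s"
    calls <- vapply(seq_len(nrow(sims)), function(i)
        as.logical(callVariant(as.list(sims[i, ]), model)), logical(1))
    expect_gte(mean(calls), 0.9)
})

test_that("sensitivity probing is consistent and depth-monotone", {
    refs <- data.frame(site = "s", strand = rep(c("fwd", "rev"), each = 4),
                       supporting = c(2, 1, 1, 0, 1, 2, 0, 1),
                       total = 20000)
    model <- fitBackground(refs)
    set.seed(31)
    for (i in 1:20) {
        nf <- sample(2000:20000, 1); nr <- sample(2000:20000, 1)
        tpl <- list(site = "s", total_fwd = nf, total_rev = nr)
        k <- sensitivityProbe(tpl, model)
        fire_at <- function(kk) {
            kf <- min(floor(kk * nf / (nf + nr)), nf)
            as.logical(callVariant(list(
                site = "s", supporting_fwd = kf, total_fwd = nf,
                supporting_rev = min(kk - kf, nr), total_rev = nr,
                uao = kk), model))
        }
        expect_true(fire_at(k))
        expect_false(fire_at(k - 1))
    }
    # the minimal detectable VAF (k_min relative to depth) never
    # increases as total depth grows at fixed background rate
    depths <- c(2000, 5000, 10000, 20000)
    ks <- vapply(depths, function(d) sensitivityProbe(
        list(site = "s", total_fwd = d, total_rev = d), model),
        numeric(1))
    expect_true(all(diff(ks / (2 * depths)) <= 0))
    # zero-background model: the UAO floor is binding
    zb <- suppressWarnings(fitBackground(data.frame(
        site = "z", strand = rep(c("fwd", "rev"), each = 3),
        supporting = 0, total = 10000)))
    expect_equal(sensitivityProbe(
        list(site = "z", total_fwd = 10000, total_rev = 10000), zb), 3)
})
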