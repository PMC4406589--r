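test_that("expected class spectrum has the neutral limit and B-monotone mean", {
    g0 <- expectedClassSpectrum(0, 60)
    i <- 1:59
    expect_equal(g0, 1 / i, tolerance = 1e-10)
    expect_equal(g0[1] / g0[2], 2, tolerance = 1e-8)
    ## positivity and monotone frequency-weighted mean on a B grid
    means <- vapply(-10:10, function(B) {
        g <- expectedClassSpectrum(B, 20)
        expect_true(all(g > 0))
        sum(seq_len(19) * g) / sum(g)
    }, numeric(1))
    expect_true(all(diff(means) > 0))
})

test_that("quadrature matches a dense trapezoid oracle", {
    g <- expectedClassSpectrum(2, 10)
    x <- seq(1e-9, 1 - 1e-9, length.out = 1e6)
    phi <- (1 - exp(-2 * (1 - x))) / ((1 - exp(-2)) * x * (1 - x))
    oracle <- vapply(1:9, function(i)
        pracma::trapz(x, choose(10, i) * x^i * (1 - x)^(10 - i) * phi),
        numeric(1))
    expect_equal(g, oracle, tolerance = 1e-7)
    ## stability at extreme negative B
    expect_true(all(is.finite(expectedClassSpectrum(-50, 60))))
})

test_that("observed-spectrum expectation mixes mirrored classes correctly", {
    n <- 4L
    theta <- c(WS = 100, SW = 300, N = 50)
    r1 <- rep(1, 3)
    ## e = 0, r = 1 reduces to theta * G
    E0 <- expectedObservedSpectra(2, theta, c(WS = 0, SW = 0, N = 0), r1, n)
    expect_equal(E0["WS", ], 100 * expectedClassSpectrum(2, 4),
                 tolerance = 1e-12)
    expect_equal(E0["SW", ], 300 * expectedClassSpectrum(-2, 4),
                 tolerance = 1e-12)
    ## hand-expanded mixture at e_WS = 0.1
    e <- c(WS = 0.1, SW = 0, N = 0)
    E <- expectedObservedSpectra(2, theta, e, r1, n)
    gP <- expectedClassSpectrum(2, 4); gM <- expectedClassSpectrum(-2, 4)
    expect_equal(E["WS", ], 0.9 * 100 * gP, tolerance = 1e-12)
    expect_equal(E["SW", ], 300 * gM + 0.1 * 100 * rev(gP),
                 tolerance = 1e-12)
    ## at B = 0 the WS+SW total is invariant in e (mirroring conserves mass)
    tot <- function(e) sum(expectedObservedSpectra(0, theta,
        c(WS = e, SW = e, N = 0), r1, n)[c("WS", "SW"), ])
    expect_equal(tot(0), tot(0.3), tolerance = 1e-10)
    expect_equal(tot(0), tot(0.5), tolerance = 1e-10)
    expect_error(expectedObservedSpectra(0, theta, c(WS = 0.7, SW = 0, N = 0),
                                         r1, n), "0.5")
})

test_that("the Poisson log-likelihood behaves as a Poisson log-likelihood", {
    n <- 10L
    theta <- c(WS = 200, SW = 900, N = 150)
    e <- c(WS = 0.05, SW = 0.01, N = 0)
    E <- expectedObservedSpectra(1.5, theta, e, rep(1, n - 1), n)
    sfs <- ClassSFS(E["WS", ], E["SW", ], E["N", ], n = n)
    llTruth <- gbgcLoglik(E, sfs)
    ## data equal to expectation: truth beats a grid of perturbed B
    for (B in c(0.5, 1.0, 2.0, 3.0)) {
        Eb <- expectedObservedSpectra(B, theta, e, rep(1, n - 1), n)
        expect_lt(gbgcLoglik(Eb, sfs), llTruth)
    }
    ## doubling theta and counts shifts loglik by the exact Poisson term
    c1 <- sfsCounts(sfs)
    ll2 <- gbgcLoglik(2 * E, ClassSFS(2 * c1["WS", ], 2 * c1["SW", ],
                                      2 * c1["N", ], n = n))
    delta <- sum(2 * c1 * log(2 * E) - 2 * E - lgamma(2 * c1 + 1)) -
             sum(c1 * log(E) - E - lgamma(c1 + 1))
    expect_equal(ll2 - llTruth, delta, tolerance = 1e-8)
    ## empty data: 0 - sum(E); zero expectation with positive count: -Inf
    empty <- ClassSFS(numeric(n - 1), numeric(n - 1), numeric(n - 1), n = n)
    expect_equal(gbgcLoglik(E, empty), -sum(E))
    Ez <- E; Ez[1, 1] <- 0
    expect_equal(gbgcLoglik(Ez, sfs), -Inf)
})

test_that("class spectra are tallied and stratified conservatively", {
    snps <- data.frame(k = c(1, 1, 1, 2, 5), n = 10,
                       mclass = c("WS", "WS", "WS", "SW", "WW"))
    sfs <- buildClassSFS(snps)
    expect_equal(sfsCounts(sfs)["WS", 1], 3)
    expect_equal(sum(sfsCounts(sfs)), nrow(snps))
    strat <- buildClassSFS(snps, stratum = c("a", "a", "b", "b", "b"))
    expect_equal(sum(vapply(strat, function(s) sum(sfsCounts(s)), numeric(1))),
                 nrow(snps))
    snps2 <- snps; snps2$n[1] <- 12
    expect_error(buildClassSFS(snps2), "same haploid sample size")
})

test_that("noise-free fits recover the generating parameters", {
    n <- 60L
    theta <- c(WS = 2000, SW = 12000, N = 3000)
    e <- c(WS = 0.15, SW = 0.02, N = 0.02)
    E <- expectedObservedSpectra(5.71, theta, e, rep(1, n - 1), n)
    sfs <- ClassSFS(E["WS", ], E["SW", ], E["N", ], n = n)
    f <- fitM1star(sfs, nStarts = 3, seed = 3, gc = 0.34, distortion = FALSE)
    expect_true(f@converged)
    expect_equal(gbgcB(f), 5.71, tolerance = 1e-3)
    expect_equal(unname(gbgcTheta(f)), unname(theta), tolerance = 1e-3)
    expect_equal(unname(gbgcE(f)), unname(e), tolerance = 1e-2)
    ## with a planted distortion vector, profiling recovers its shape
    r <- c(1, 1 + 0.3 * sin(seq(0.1, 3, length.out = n - 2)))
    E2 <- expectedObservedSpectra(3, theta, e, r, n)
    sfs2 <- ClassSFS(E2["WS", ], E2["SW", ], E2["N", ], n = n)
    f2 <- fitM1star(sfs2, nStarts = 3, seed = 5, gc = 0.34)
    expect_equal(gbgcB(f2), 3, tolerance = 5e-3)
    expect_gt(cor(f2@distortion, r), 0.999)
})

test_that("lambda, equilibrium GC and the scaling conversions are exact", {
    expect_equal(estimateLambda(1, 1, 0.5), 1)
    expect_equal(estimateLambda(1, 2, 0.34), 2 * 0.66 / 0.34,
                 tolerance = 1e-12)
    expect_error(estimateLambda(1, 2, 0), "strictly between")
    expect_equal(equilibriumGC(0, 3), 0.25)
    expect_equal(equilibriumGC(1e6, 11.69), 1)
    expect_equal(round(equilibriumGC(5.71, 11.69), 2), 0.96)
    expect_equal(bFromB(0.38, 1e4, "diploid"), 9.5e-6)
    expect_equal(bFromB(5.71, 5e5, "haplodiploid"), 5.71 / 1.5e6)
    expect_equal(rFromRho(390, 5e5, "haplodiploid"), 26)
    expect_error(bFromB(1, 0), "Ne")
})

test_that("fitted lambda and B reproduce the planted equilibrium GC", {
    ## plant B and lambda so GC* = 1/(1 + lambda exp(-B)); analyze at the
    ## equilibrium composition and close the loop through the fit
    B <- 2; lambda <- 3
    gcStar <- equilibriumGC(B, lambda)
    thetaWS <- 8000
    thetaSW <- lambda * thetaWS * gcStar / (1 - gcStar)
    sfs <- simulateClassSfs(B, c(WS = thetaWS, SW = thetaSW, N = 10000),
                            n = 60, seed = 31)
    f <- fitM1star(sfs, nStarts = 3, seed = 6, gc = gcStar,
                   distortion = FALSE)
    expect_equal(equilibriumGC(gbgcB(f), gbgcLambda(f)), gcStar,
                 tolerance = 0.02)
})

test_that("binned fits are independent and consistent with the global fit", {
    theta <- c(WS = 3000, SW = 9000, N = 4000)
    sfs <- simulateClassSfs(4, theta, n = 30, seed = 17)
    cnt <- sfsCounts(sfs)
    snps <- do.call(rbind, lapply(rownames(cnt), function(cl) {
        do.call(rbind, lapply(which(cnt[cl, ] > 0), function(i) {
            data.frame(k = rep(i, cnt[cl, i]), n = 30,
                       mclass = if (cl == "N") "WW" else cl)
        }))
    }))
    snps$covariate <- 0.5
    global <- fitM1star(buildClassSFS(snps), nStarts = 3, seed = 2)
    ## a single bin spanning all data equals the global fit
    bf <- binnedFits(snps, snps$covariate, c(0, 1), nStarts = 3, seed = 2)
    expect_length(bf, 1L)
    expect_equal(gbgcB(bf[[1]]), gbgcB(global), tolerance = 1e-6)
    ## an empty bin is reported absent and the run continues
    bf2 <- binnedFits(snps, snps$covariate, c(0, 0.6, 1), nStarts = 3,
                      seed = 2)
    expect_null(bf2[[2]])
    expect_equal(gbgcB(bf2[[1]]), gbgcB(global), tolerance = 1e-6)
    expect_error(binnedFits(snps, snps$covariate, c(1, 0.5)), "ascending")
})

test_that("folded spectrum test matches the exact hypergeometric oracle", {
    ## equal cells: no association
    mk <- function(nWlow, nWmid, nSlow, nSmid, n = 20) {
        kW <- c(rep(1, nWlow), rep(9, nWmid))       # MAF 0.05 and 0.45
        kS <- c(rep(1, nSlow), rep(9, nSmid))
        siteTable("c", seq_len(length(kW) + length(kS)),
                  alleleX = c(rep("G", length(kW)), rep("A", length(kS))),
                  alleleY = c(rep("A", length(kW)), rep("C", length(kS))),
                  countY = c(kW, kS), n = n,
                  outgroupAllele = "A", outgroupDepth = 9)
    }
    r0 <- foldedSpectrumTest(mk(50, 50, 50, 50))
    expect_equal(r0$odds_ratio, 1)
    expect_equal(r0$p, 1)
    ## planted excess of strong alleles at intermediate frequency
    r1 <- foldedSpectrumTest(mk(900, 100, 700, 300))
    expect_equal(r1$odds_ratio, (900 * 300) / (100 * 700), tolerance = 1e-12)
    expect_lt(r1$p, 1e-6)
    ## exact-test oracle: hypergeometric enumeration with fixed margins
    m <- 1000; nn <- 1000; kk <- 1600    # W total, S total, low total
    x <- max(0, kk - nn):min(kk, m)
    d <- dhyper(x, m, nn, kk)
    pOracle <- sum(d[d <= dhyper(900, m, nn, kk) * (1 + 1e-7)])
    expect_equal(r1$p, pOracle, tolerance = 1e-10)
    ## folding is invariant under relabelling which allele is X or Y
    s <- mk(30, 20, 25, 25)
    sSwap <- s
    sSwap$allele_x <- s$allele_y; sSwap$allele_y <- s$allele_x
    sSwap$count_y <- s$n - s$count_y
    r2 <- foldedSpectrumTest(s); r3 <- foldedSpectrumTest(sSwap)
    expect_equal(r2$spectra, r3$spectra)
    expect_equal(r2$p, r3$p)
})

test_that("class frequency summaries match neutral expectations at B = 0", {
    n <- 60
    aH <- sum(1 / seq_len(n - 1))
    snps <- rbind(neutralSnpTable(20000, mclass = "WS", seed = 1),
                  neutralSnpTable(20000, mclass = "SW", seed = 2))
    cs <- classFrequencySummaries(snps, seed = 5)
    ws <- cs$class_means[cs$class_means$mclass == "WS" &
                         cs$class_means$titv == "Ti", ]
    sw <- cs$class_means[cs$class_means$mclass == "SW" &
                         cs$class_means$titv == "Ti", ]
    neutralMean <- (n - 1) / (n * aH)
    expect_equal(ws$mean, neutralMean, tolerance = 0.02)
    ## WS and SW indistinguishable: CIs overlap
    expect_true(ws$ci_lo <= sw$ci_hi && sw$ci_lo <= ws$ci_hi)
    expect_equal(cs$ratios[["ws_sw_ti"]], 1, tolerance = 0.05)
    ## cells with no SNPs are absent
    expect_true(is.na(cs$class_means$mean[cs$class_means$mclass == "SS"][1]))
    ## relative spectra rows sum to one where occupied
    occ <- rowSums(cs$relative_spectra) > 0
    expect_equal(unname(rowSums(cs$relative_spectra)[occ]),
                 rep(1, sum(occ)))
})

test_that("gBGC restricted to transitions elevates only the Ti ratio", {
    n <- 60L
    iGrid <- seq_len(n - 1)
    drawK <- function(m, B, seed) {
        g <- expectedClassSpectrum(B, n)
        withr::with_seed(seed, sample(iGrid, m, replace = TRUE, prob = g))
    }
    mk <- function(k, mclass, titv)
        data.frame(k = k, n = n, mclass = mclass, titv = titv,
                   cpg_creating = FALSE, gpc_creating = FALSE,
                   cpg_destroying = FALSE, gpc_destroying = FALSE,
                   f_d = k / n)
    snps <- rbind(
        mk(drawK(8000, 6, 1), "WS", "Ti"), mk(drawK(8000, -6, 2), "SW", "Ti"),
        mk(drawK(8000, 0, 3), "WS", "Tv"), mk(drawK(8000, 0, 4), "SW", "Tv"))
    cs <- classFrequencySummaries(snps, seed = 9)
    expect_gt(cs$ratios[["ws_sw_ti"]], 2)
    expect_equal(cs$ratios[["ws_sw_tv"]], 1, tolerance = 0.1)
})

test_that("local bin covariates read flanks and enclosing windows", {
    genome <- DNAStringSet(c(cX = strrep("ACGT", 300)))
    snps <- data.frame(chrom = "cX", pos = c(101, 3))
    g <- localGC(snps, genome, flank = 100)
    ## periodic ACGT: GC of any flank window is 0.5 regardless of phase
    expect_equal(g, c(0.5, 0.5), tolerance = 0.01)
    rmap <- GRanges("cX", IRanges(c(1, 601), c(600, 1200)),
                    rho_per_kb = c(100, 500))
    expect_equal(localRho(snps, rmap)[2], 100)
    expect_gt(localRho(data.frame(chrom = "cX", pos = 600), rmap), 100)
})
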