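## Shared fixtures, built in code. The medium simulation is cached so that
## several test files can reuse it without regenerating.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(Biostrings)
})

uniformModel <- function(muVal = 0.01, sigVal = 0.002) {
    mu <- matrix(muVal, 4, 4); diag(mu) <- 0
    sg <- matrix(sigVal, 4, 4); diag(sg) <- 0
    SubstitutionModel(mu, sg)
}

.fixtureCache <- new.env(parent = emptyenv())

## 300 kb genome with SNPs, rate map and gene tables under default
## (study-like) generator settings.
sharedSim <- function() {
    if (is.null(.fixtureCache$sim)) {
        cfg <- simConfig(seed = 5, chromLengths = c(chr1 = 3e5))
        gs <- simulateGenome(cfg)
        sn <- simulateSnps(cfg, gs)
        rmap <- simulateRhoMap(cfg, gs)
        .fixtureCache$sim <- list(cfg = cfg, gs = gs, sn = sn, rmap = rmap)
    }
    .fixtureCache$sim
}

## Brute-force Tajima's D oracle: explicit haplotype matrix, literal
## enumeration of all pairwise differences, textbook constants.
bruteTajima <- function(km, n) {
    geno <- vapply(km, function(k) c(rep(1, k), rep(0, n - k)), numeric(n))
    pairs <- combn(n, 2)
    piTot <- mean(apply(pairs, 2, function(p)
        sum(geno[p[1], ] != geno[p[2], ]))) * choose(n, 2) * 2 / (n * (n - 1))
    S <- ncol(geno)
    i <- seq_len(n - 1)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (piTot - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

## Draw a polarized-SNP-shaped table with k sampled from the neutral SFS.
neutralSnpTable <- function(nSnps, n = 60L, mclass = "WS", titv = "Ti",
                            seed = 1L) {
    withr::with_seed(seed, {
        i <- seq_len(n - 1L)
        k <- sample(i, nSnps, replace = TRUE, prob = 1 / i)
        data.frame(chrom = "chr1", pos = seq_len(nSnps), n = n, k = k,
                   mclass = mclass, titv = titv,
                   cpg_creating = FALSE, gpc_creating = FALSE,
                   cpg_destroying = FALSE, gpc_destroying = FALSE,
                   f_d = k / n, stringsAsFactors = FALSE)
    })
}
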