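test_that("mutation classification partitions all 12 ordered base pairs", {
    pairs <- expand.grid(a = c("A", "C", "G", "T"), d = c("A", "C", "G", "T"),
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$d, ]
    cls <- classifyMutation(pairs$a, pairs$d)
    expect_equal(sum(cls$mclass == "WS"), 4)
    expect_equal(sum(cls$mclass == "SW"), 4)
    expect_equal(sum(cls$mclass == "WW"), 2)
    expect_equal(sum(cls$mclass == "SS"), 2)
    expect_equal(sum(cls$titv == "Ti"), 4)

    expect_equal(unlist(classifyMutation("A", "G")), c(mclass = "WS", titv = "Ti"))
    expect_equal(unlist(classifyMutation("C", "A")), c(mclass = "SW", titv = "Tv"))
    expect_equal(unlist(classifyMutation("G", "C")), c(mclass = "SS", titv = "Tv"))
    expect_equal(unlist(classifyMutation("A", "T")), c(mclass = "WW", titv = "Tv"))
    expect_error(classifyMutation("A", "A"), "differ")
    expect_error(classifyMutation("A", "N"), "A, C, G or T")
})

test_that("dinucleotide context flags follow the CpG/GpC definitions", {
    expect_equal(dinucleotideContext("C", "A", "A", "G")[1, ],
        c(cpg_creating = TRUE, gpc_creating = FALSE,
          cpg_destroying = FALSE, gpc_destroying = FALSE))
    expect_equal(dinucleotideContext("T", "C", "A", "G")[1, ],
        c(cpg_creating = FALSE, gpc_creating = TRUE,
          cpg_destroying = FALSE, gpc_destroying = FALSE))
    expect_equal(dinucleotideContext("C", "T", "G", "A")[1, ],
        c(cpg_creating = FALSE, gpc_creating = FALSE,
          cpg_destroying = TRUE, gpc_destroying = FALSE))
    ## missing flank contributes no flag from that side
    expect_false(any(dinucleotideContext(NA, NA, "A", "G")))
    ## flags may co-occur: C _ G with A->G creates CpG and destroys nothing;
    ## G _ C with A->G creates GpC on both sides
    ctx <- dinucleotideContext("G", "C", "A", "G")
    expect_true(ctx[1, "gpc_creating"])
})

test_that("substitution model estimation normalizes counts per opportunity", {
    poly <- matrix(10, 4, 4); diag(poly) <- 0
    fixed <- matrix(5, 4, 4); diag(fixed) <- 0
    bases <- c(A = 1000, C = 1000, G = 1000, T = 1000)
    m <- estimateSubstitutionModel(poly, fixed, bases)
    offDiag <- function(x) x[row(x) != col(x)]
    expect_true(all(offDiag(m@mu) == 0.01))
    expect_true(all(offDiag(m@sigma) == 0.005))

    m0 <- estimateSubstitutionModel(poly, fixed * 0, bases)
    expect_true(all(m0@sigma == 0))
    expect_equal(m0@mu, m@mu)

    expect_error(estimateSubstitutionModel(poly, fixed,
        c(A = 1000, C = 0, G = 1000, T = 1000)), "C")
    expect_error(estimateSubstitutionModel(-poly, fixed, bases), "nonnegative")
})

test_that("weighted parsimony reproduces the scenario-weight formula", {
    ## sigma = 0: simple parsimony limit, p = 1 whenever O matches an allele
    m0 <- uniformModel(sigVal = 0)
    s <- siteTable("c", 10, "A", "G", 10, outgroupAllele = "A",
                   outgroupDepth = 9)
    p <- polarizeSites(s, m0, pThreshold = 0.9)
    expect_equal(p$snps$p_ancestral, 1)
    expect_equal(p$snps$ancestral, "A")
    expect_equal(p$snps$k, 10L)

    ## O = X with sigma(Y->X) = 0.1 and symmetric mu: p = 1/1.1
    mu <- matrix(0.01, 4, 4); diag(mu) <- 0
    sg <- matrix(0.1, 4, 4); diag(sg) <- 0
    p2 <- polarizeSites(s, SubstitutionModel(mu, sg), pThreshold = 0.5)
    expect_equal(p2$snps$p_ancestral, 1 / 1.1, tolerance = 1e-12)

    ## outgroup matching neither allele with symmetric weights: a tie
    s3 <- siteTable("c", 10, "A", "G", 10, outgroupAllele = "T",
                    outgroupDepth = 9)
    p3 <- polarizeSites(s3, uniformModel(), pThreshold = 0.5)
    expect_equal(nrow(p3$snps), 0L)
    expect_equal(p3$unresolved$reason, "tie")

    ## derived count flips when the outgroup supports allele_y
    s4 <- siteTable("c", 10, "A", "G", 10, outgroupAllele = "G",
                    outgroupDepth = 9)
    p4 <- polarizeSites(s4, m0)
    expect_equal(p4$snps$ancestral, "G")
    expect_equal(p4$snps$k, 50L)
    expect_equal(p4$snps$mclass, "SW")

    ## missing outgroup and uninformative model reason codes
    s5 <- siteTable("c", 10, "A", "G", 10, outgroupAllele = NA,
                    outgroupDepth = 9)
    expect_equal(polarizeSites(s5, m0)$unresolved$reason, "no outgroup")
    mz <- SubstitutionModel(matrix(0, 4, 4), matrix(0, 4, 4))
    expect_equal(polarizeSites(s, mz)$unresolved$reason, "uninformative model")
})

test_that("scenario probabilities for the two orientations sum to one", {
    set.seed(42)
    mu <- matrix(runif(16, 0.001, 0.05), 4, 4); diag(mu) <- 0
    sg <- matrix(runif(16, 0.001, 0.2), 4, 4); diag(sg) <- 0
    for (og in c("A", "C", "G", "T")) {
        wX <- beeGBGC:::.parsimonyWeight("A", "G", og, mu, sg)
        wY <- beeGBGC:::.parsimonyWeight("G", "A", og, mu, sg)
        expect_equal(wX / (wX + wY) + wY / (wX + wY), 1, tolerance = 1e-12)
    }
})

test_that("site filtering removes low-depth and non-biallelic records", {
    s <- siteTable("c", 1:10, "A", "G", 5, outgroupAllele = "A",
                   outgroupDepth = c(4, 4, 4, rep(10, 7)))
    s$biallelic <- c(rep(TRUE, 9), FALSE)
    out <- filterSites(s, minOutgroupDepth = 5)
    expect_equal(nrow(out), 6L)
    expect_equal(unname(attr(out, "removed")), c(1, 3))
    expect_equal(nrow(filterSites(s, minOutgroupDepth = 0,
                                  biallelicOnly = FALSE)), 10L)
})

test_that("MAF pruning uses a strict lower bound and is idempotent", {
    s <- siteTable("c", 1:3, "A", "G", c(5, 6, 30), n = 60,
                   outgroupAllele = "A", outgroupDepth = 9)
    out <- mafPrune(s, 0.1)
    expect_equal(out$count_y, c(6L, 30L))   # 5/60 < 0.1 removed, 6/60 kept
    expect_equal(mafPrune(out, 0.1), out)
    expect_equal(mafPrune(s, 0), s)
})

test_that("per-element diversity capping subsamples to the cap", {
    ## 20 SNPs, n = 4, L = 1000: theta_w = 20/(11/6 * 1000) > 0.002;
    ## 3 SNPs give 0.00164 <= cap < 4 SNPs' 0.00218
    s <- siteTable("c", 1:20, "A", "G", 2, n = 4, outgroupAllele = "A",
                   outgroupDepth = 9)
    s$element <- "e1"
    out <- capElementDiversity(s, c(e1 = 1000), thetaCap = 0.002, seed = 3)
    expect_equal(nrow(out), 3L)
    expect_identical(capElementDiversity(s, c(e1 = 1000), thetaCap = 0.002,
                                         seed = 3), out)
    ## below the cap: unchanged
    s2 <- s[1:3, ]
    expect_equal(capElementDiversity(s2, c(e1 = 1000), thetaCap = 0.002,
                                     seed = 1), s2)
    expect_error(capElementDiversity(s, c(e1 = 1000), thetaCap = 0), "positive")
    ## recomputed theta respects the cap for every element
    s$element <- rep(c("e1", "e2"), each = 10)
    out2 <- capElementDiversity(s, c(e1 = 600, e2 = 5000), thetaCap = 0.002,
                                seed = 2)
    a3 <- sum(1 / (1:3))
    for (el in c("e1", "e2")) {
        L <- c(e1 = 600, e2 = 5000)[[el]]
        expect_lte(sum(out2$element == el) / (a3 * L), 0.002)
    }
})

test_that("WS mispolarization grows with outgroup branch length", {
    rates <- vapply(c(0.01, 0.08), function(br) {
        cfg <- simConfig(seed = 21, chromLengths = c(chr1 = 1.5e5),
                         outgroupBranch = br)
        gs <- simulateGenome(cfg)
        sn <- simulateSnps(cfg, gs)
        ti <- tallySubstitutionInputs(sn$sites, gs$genome, sn$outgroup,
                                      sn$mask)
        mod <- estimateSubstitutionModel(ti$polyCounts, ti$fixedCounts,
                                         ti$baseCounts)
        ## hard assignment: at long branches the strong AT mutation bias
        ## pushes W-ancestral sites below any confidence threshold
        pol <- polarizeSites(filterSites(sn$sites), mod, pThreshold = 0.5)
        tc <- compareToTruth(pol$snps, sn$truth)
        tc$by_class[["WS"]]
    }, numeric(1))
    expect_gt(rates[2], rates[1])
})
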