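test_that("gene CpG classification uses a strict threshold", {
    ## a gene whose CDS O/E we can compute directly
    seqs <- DNAStringSet(c(chrT = paste0(strrep("CGAT", 100),
                                         strrep("AATT", 200))))
    cds <- GRangesList(g1 = GRanges("chrT", IRanges(1, 400), strand = "+"))
    oe <- cpgOE(as.character(subseq(seqs[[1]], 1, 400)))
    out <- geneCpGClass(cds, seqs, threshold = oe)
    expect_equal(out$cds_cpg_oe, oe)
    expect_equal(out$cpg_class, "LCpG")      # exactly at threshold: LCpG
    out2 <- geneCpGClass(cds, seqs, threshold = oe - 1e-9)
    expect_equal(out2$cpg_class, "HCpG")
    ## too-short CDS is unclassified
    short <- GRangesList(g1 = GRanges("chrT", IRanges(1, 100), strand = "+"))
    expect_true(is.na(geneCpGClass(short, seqs, minLength = 200)$cpg_class))
    ## minus-strand genes are measured on the reverse complement
    minus <- GRangesList(g1 = GRanges("chrT", IRanges(1, 400), strand = "-"))
    rcOe <- cpgOE(as.character(reverseComplement(subseq(seqs[[1]], 1, 400))))
    expect_equal(geneCpGClass(minus, seqs, threshold = 1)$cds_cpg_oe, rcOe)
})

test_that("planted gene CpG classes are recovered from sequence", {
    sim <- sharedSim()
    gcd <- geneCpGClass(sim$gs$cdsByGene, sim$gs$genome, threshold = 1.04)
    truth <- sim$gs$geneTruth
    m <- merge(gcd, truth, by = "gene_id")
    ok <- !is.na(m$cpg_class.x)
    expect_gte(mean(m$cpg_class.x[ok] == m$cpg_class.y[ok]), 0.99)
})

test_that("expression class assignment handles NA, conflicts, unknown IDs", {
    genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"))
    expect_warning(expect_warning(
        out <- assignExpressionClass(genes,
            qw = list(QgtW = c("g1", "g3"), WgtQ = c("g3"), NS = "g2"),
            dw = list(DgtW = "g1", WgtD = "gX")),
        "conflicting"), "not in gene table")
    expect_equal(out$expr_qw, c("QgtW", "NS", NA, NA))
    expect_equal(out$expr_dw, c("DgtW", NA, NA, NA))
    expect_equal(attr(out, "conflicts"), "g3")
    expect_equal(attr(out, "unknown_ids"), "gX")
})

test_that("methylation metrics and median split follow the definitions", {
    ## 2 kb CDS containing exactly 50 CpG sites, 10 of them methylated
    block <- paste0("CG", strrep("A", 38))          # one CpG per 40 bp
    seqs <- DNAStringSet(c(chrM = strrep(block, 60)))
    cds <- GRangesList(g1 = GRanges("chrM", IRanges(1, 2000), strand = "+"),
                       g2 = GRanges("chrM", IRanges(2001, 2400), strand = "+"))
    mcpg <- GRanges("chrM", IRanges(40 * (0:9) + 1, width = 2))  # 10 in g1
    mm <- methylationMetrics(cds, seqs, mcpg)
    g1 <- mm[mm$gene_id == "g1", ]
    expect_equal(g1$n_cpg, 50)
    expect_equal(g1$n_mcpg, 10)
    expect_equal(g1$mcpg_per_kb, 5)
    expect_equal(g1$prop_cpg_methylated, 0.2)
    expect_equal(mm$meth_class[mm$gene_id == "g2"], "UNMET")

    ## median split leaves class sizes within one of each other: plant 21
    ## genes with 21 CpGs each and distinct methylated proportions j/21
    nGene <- 21L
    seqs2 <- DNAStringSet(c(chrN = strrep(block, 21L * nGene)))
    cdsN <- GRangesList(lapply(seq_len(nGene), function(j)
        GRanges("chrN", IRanges(840L * (j - 1L) + 1L, width = 840L),
                strand = "+")))
    names(cdsN) <- sprintf("m%02d", seq_len(nGene))
    mcAt <- unlist(lapply(seq_len(nGene), function(j)
        840L * (j - 1L) + 40L * seq_len(j) - 39L))
    mcN <- GRanges("chrN", IRanges(mcAt, width = 2L))
    mmN <- methylationMetrics(cdsN, seqs2, mcN)
    expect_equal(sort(mmN$n_mcpg), seq_len(nGene))
    tab <- table(mmN$meth_class)
    expect_lte(abs(tab[["HMET"]] - tab[["LMET"]]), 1L)
})

test_that("gene-region rho sees planted steps and truncates flanks", {
    seqlens <- c(chrR = 200000L)
    gene <- GRanges("chrR", IRanges(80001, 90000), gene_id = "g1")
    seqlengths(gene) <- seqlens
    cds <- GRangesList(g1 = GRanges("chrR", IRanges(80001, 90000),
                                    strand = "+"))
    ## constant map: all three measures equal
    const <- GRanges("chrR", IRanges(1, 200000), rho_per_kb = 250)
    rr <- geneRegionRho(gene, cds, const)
    expect_equal(unlist(rr[, -1]), c(rho_cds = 250, rho_flank_near = 250,
                                     rho_flank_far = 250))
    ## planted step: CDS at 100, everything else 400
    step <- GRanges("chrR", IRanges(c(1, 80001, 90001),
                                    c(80000, 90000, 200000)),
                    rho_per_kb = c(400, 100, 400))
    rs <- geneRegionRho(gene, cds, step)
    expect_equal(rs$rho_cds, 100)
    expect_equal(rs$rho_flank_near, 400)
    expect_equal(rs$rho_flank_far, 400)
    ## truncation at the chromosome start: gene near the origin still works
    gene2 <- GRanges("chrR", IRanges(5001, 15000), gene_id = "g2")
    seqlengths(gene2) <- seqlens
    cds2 <- GRangesList(g2 = GRanges("chrR", IRanges(5001, 15000),
                                     strand = "+"))
    r2 <- geneRegionRho(gene2, cds2, const)
    expect_equal(r2$rho_flank_far, 250)   # mean over the covered part only
    ## strand invariance: flanks are geometric
    cdsM <- GRangesList(g1 = GRanges("chrR", IRanges(80001, 90000),
                                     strand = "-"))
    expect_equal(geneRegionRho(gene, cdsM, step)$rho_flank_near, 400)
})

test_that("class comparisons recover a planted recombination difference", {
    sim <- sharedSim()
    rmapP <- simulateRhoMap(sim$cfg, sim$gs, plantGeneEffects = TRUE)
    spans <- sim$gs$annotation[sim$gs$annotation$type == "gene"]
    rr <- geneRegionRho(spans, sim$gs$cdsByGene, rmapP)
    genes <- merge(rr, sim$gs$geneTruth, by = "gene_id")
    cc <- compareGeneClasses(genes, "cpg_class", "rho_cds", seed = 11)
    lc <- cc$classes[cc$classes$class == "LCpG", ]
    hc <- cc$classes[cc$classes$class == "HCpG", ]
    expect_lt(lc$mean, hc$mean)
    expect_true(lc$ci_hi <= hc$ci_lo)    # multiplier 1/3: clearly separated
    ## rel_diff is relative to the overall mean
    overall <- mean(genes$rho_cds)
    expect_equal(lc$rel_diff, lc$mean / overall - 1, tolerance = 1e-12)
})

test_that("rho-given-theta profile classifies 1 kb windows strictly", {
    sim <- sharedSim()
    gcd <- geneCpGClass(sim$gs$cdsByGene, sim$gs$genome, threshold = 1.04)
    prof <- rhoGivenThetaProfile(sim$gs$genome, sim$gs$elements,
        sim$sn$sites, sim$rmap, cdsByGene = sim$gs$cdsByGene, geneCpG = gcd,
        nBoot = 50, seed = 3)
    expect_true(all(c("class", "bin", "mean_rho") %in% names(prof)))
    expect_true(any(prof$class == "intergenic"))
    occupied <- prof[prof$n > 0, ]
    expect_true(all(occupied$ci_lo <= occupied$mean_rho + 1e-9))
    ## when rho is a pure function of theta the class profiles coincide:
    ## build a map where rho = theta rank of the window
    n <- sim$sn$sites$n[1]
    wins <- genomeWindows(setNames(width(sim$gs$genome),
                                   names(sim$gs$genome)), 1e3, 1)
    S <- countOverlaps(wins, GRanges(sim$sn$sites$chrom,
                                     IRanges(sim$sn$sites$pos, width = 1)))
    pure <- GRanges(seqnames(wins), ranges(wins),
                    rho_per_kb = 100 + 1e5 * wattersonTheta(S, n, 1e3))
    prof2 <- rhoGivenThetaProfile(sim$gs$genome, sim$gs$elements,
        sim$sn$sites, pure, nBoot = 50, seed = 4)
    cmp <- merge(prof2[prof2$class == "coding", c("bin", "mean_rho")],
                 prof2[prof2$class == "intergenic", c("bin", "mean_rho")],
                 by = "bin")
    cmp <- cmp[stats::complete.cases(cmp), ]
    expect_true(all(abs(cmp$mean_rho.x - cmp$mean_rho.y) /
                    cmp$mean_rho.y < 0.25))
})
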