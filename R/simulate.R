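## Synthetic-data generator: genomes, annotations, recombination maps, SNPs
## with gBGC-shaped frequency spectra, outgroup alleles with mechanistic
## polarization-error structure, methylation/expression tables and ground
## truth. All randomness flows through one seeded RNG per call; equal
## configurations reproduce byte-identical output.
##
## Allele frequencies are drawn from the stationary sojourn density of the
## constant-gBGC model rather than from a coalescent or forward simulation:
## sites are independent (no linkage), which is sufficient -- and orders of
## magnitude faster -- for exercising the estimator and the pipeline.

#' Simulation configuration
#'
#' Assembles the generator parameters with defaults emulating the African
#' honeybee study system: n = 60 haploid genomes, strongly AT-biased
#' mutation (lambda = 12), gBGC acting on transitions (B_ti = 6.47) but not
#' transversions (B_tv = 0.03), outgroup divergence around 3 percent,
#' per-element GC (CDS 0.39, intron 0.23, intergenic 0.31) and a bimodal
#' gene-body CpG O/E (LCpG vs HCpG genes).
#'
#' @param seed integer seed (mandatory).
#' @param nHaplotypes haploid sample size (default 60; must be even so that
#'   diploid VCF genotypes can be emitted).
#' @param chromLengths named chromosome lengths (default one 1 Mb
#'   chromosome).
#' @param elementGC named per-element target GC proportions.
#' @param elementOE named per-element target CpG O/E (CDS given per planted
#'   gene class).
#' @param geneSpacing mean intergenic gap between genes in bp.
#' @param Bti,Btv gBGC coefficients for WS/SW transitions and transversions.
#' @param BofRho optional function(rho_per_kb) returning the transition B at
#'   a site, enabling recombination-dependent gBGC (overrides `Bti`).
#' @param lambda AT mutational bias (S->W over W->S per-site rate).
#' @param thetaWS per-W-base weak-to-strong mutation influx; the S->W influx
#'   is `lambda * thetaWS` per S base. Influxes are mutation-rate scales:
#'   the expected number of emitted (segregating) sites additionally carries
#'   the relative sojourn mass of the class's B, so that the fitted
#'   theta ratio — and hence lambda — is recoverable end-to-end. Neutral
#'   classes see exactly `theta x eligible bases`.
#' @param thetaWW,thetaSS per-base influx of the GC-conservative classes.
#' @param tiProb probability that a WS/SW mutation is a transition.
#' @param outgroupBranch expected substitutions per site on the outgroup
#'   lineage (drives both divergence and mispolarization pressure).
#' @param outgroupKappa transition/transversion rate factor of the outgroup
#'   substitution kernel.
#' @param coverageFraction fraction of the genome with adequate outgroup
#'   coverage (the BED mask).
#' @param rhoMean,rhoSdLog mean rho/kb and log-sd of the piecewise-constant
#'   recombination map.
#' @param rhoSegmentLength mean rate-interval length in bp.
#' @param rhoMultipliers named multipliers planting a CDS recombination
#'   difference between gene CpG classes.
#' @param assocStrength association (0..1) between planted CpG class and
#'   expression/methylation classes.
#' @param probHCpG probability a gene is planted HCpG.
#' @return a list of class `beeSimConfig`.
#' @export
simConfig <- function(seed,
                      nHaplotypes = 60L,
                      chromLengths = c(chr1 = 1e6),
                      elementGC = c(CDS = 0.39, intron = 0.23,
                                    intergenic = 0.31, five_prime_UTR = 0.31,
                                    three_prime_UTR = 0.24),
                      elementOE = c(CDS_LCpG = 0.6, CDS_HCpG = 1.6,
                                    intron = 1.7, intergenic = 1.7,
                                    five_prime_UTR = 1.3,
                                    three_prime_UTR = 1.2),
                      geneSpacing = 8e3,
                      Bti = 6.47, Btv = 0.03, BofRho = NULL,
                      lambda = 12,
                      thetaWS = 0.004, thetaWW = 0.004, thetaSS = 0.004,
                      tiProb = 0.7,
                      outgroupBranch = 0.03, outgroupKappa = 2,
                      coverageFraction = 0.95,
                      rhoMean = 390, rhoSdLog = 0.4,
                      rhoSegmentLength = 5e3,
                      rhoMultipliers = c(LCpG = 1/3, HCpG = 1),
                      assocStrength = 0.8,
                      probHCpG = 0.5) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(nHaplotypes %% 2 == 0, all(chromLengths > 0),
              lambda > 0, thetaWS >= 0, tiProb >= 0, tiProb <= 1,
              outgroupBranch >= 0, coverageFraction >= 0,
              coverageFraction <= 1)
    structure(list(seed = as.integer(seed), nHaplotypes = as.integer(nHaplotypes),
        chromLengths = chromLengths, elementGC = elementGC,
        elementOE = elementOE, geneSpacing = geneSpacing,
        Bti = Bti, Btv = Btv, BofRho = BofRho, lambda = lambda,
        thetaWS = thetaWS, thetaSW = lambda * thetaWS,
        thetaWW = thetaWW, thetaSS = thetaSS, tiProb = tiProb,
        outgroupBranch = outgroupBranch, outgroupKappa = outgroupKappa,
        coverageFraction = coverageFraction, rhoMean = rhoMean,
        rhoSdLog = rhoSdLog, rhoSegmentLength = rhoSegmentLength,
        rhoMultipliers = rhoMultipliers, assocStrength = assocStrength,
        probHCpG = probHCpG),
        class = "beeSimConfig")
}

## ---- first-order Markov sequence model -----------------------------------

## Transition matrix with stationary-GC knob g and CpG enrichment knob tau:
## every row is the base distribution, except that C -> G is multiplied by
## tau and the row renormalized.
.markovP <- function(g, tau) {
    q <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    P <- matrix(rep(q, each = 4L), 4L, 4L, dimnames = list(BASES, BASES))
    P["C", "G"] <- P["C", "G"] * tau
    P["C", ] <- P["C", ] / sum(P["C", ])
    P
}

.markovStationary <- function(P) {
    e <- eigen(t(P))
    v <- Re(e$vectors[, which.min(abs(e$values - 1))])
    v / sum(v)
}

.markovRealized <- function(g, tau) {
    P <- .markovP(g, tau)
    pi <- .markovStationary(P)
    names(pi) <- BASES
    gc <- pi["C"] + pi["G"]
    oe <- (pi["C"] * P["C", "G"]) / (pi["C"] * pi["G"])
    c(gc = unname(gc), oe = unname(oe))
}

## Solve (g, tau) so the stationary chain hits target GC and CpG O/E.
.solveMarkov <- function(gc, oe) {
    obj <- function(par) {
        r <- .markovRealized(stats::plogis(par[1L]), exp(par[2L]))
        ((r["gc"] - gc) / 0.005)^2 + ((r["oe"] - oe) / 0.02)^2
    }
    o <- stats::optim(c(stats::qlogis(gc), log(oe)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000L, reltol = 1e-12))
    g <- stats::plogis(o$par[1L]); tau <- exp(o$par[2L])
    r <- .markovRealized(g, tau)
    if (abs(r["gc"] - gc) > 0.01 || abs(r["oe"] - oe) > 0.05)
        stop(sprintf(paste0("infeasible (GC = %.2f, CpG O/E = %.2f) target; ",
            "closest attainable is (%.3f, %.3f)"), gc, oe, r["gc"], r["oe"]))
    .markovP(g, tau)
}

## Sample L bases from the chain (integer loop; cheap relative to the rest
## of the pipeline).
.sampleMarkov <- function(P, L) {
    if (L <= 0L) return(character(0))
    cum <- t(apply(P, 1L, cumsum))
    pi <- .markovStationary(P)
    u <- stats::runif(L)
    s <- integer(L)
    prev <- sample.int(4L, 1L, prob = pi)
    c1 <- cum[, 1L]; c2 <- cum[, 2L]; c3 <- cum[, 3L]
    for (j in seq_len(L)) {
        uj <- u[j]
        prev <- 1L + (uj > c1[prev]) + (uj > c2[prev]) + (uj > c3[prev])
        s[j] <- prev
    }
    BASES[s]
}

## ---- genome + annotation -------------------------------------------------

#' Simulate a reference genome with gene annotation
#'
#' Lays out non-overlapping genes (5' UTR, CDS exons separated by introns,
#' 3' UTR) along each chromosome and fills every element with a first-order
#' Markov sequence whose parameters are solved to hit the configured target
#' GC and CpG O/E for that element type. Each gene is planted as LCpG or
#' HCpG, which selects the CDS dinucleotide model.
#'
#' @param config a [simConfig()] object.
#' @return list with `genome` (`DNAStringSet`), `annotation` (`GRanges` of
#'   gene/CDS/UTR records with `type` and `gene_id`), `elements`
#'   ([resolveElements()] output), `cdsByGene` (`GRangesList`) and
#'   `geneTruth` (`data.frame` of planted gene classes).
#' @export
simulateGenome <- function(config) {
    stopifnot(inherits(config, "beeSimConfig"))
    withSeed(config$seed, .simulateGenomeImpl(config))
}

.simulateGenomeImpl <- function(config) {
    models <- list(
        intergenic = .solveMarkov(config$elementGC["intergenic"],
                                  config$elementOE["intergenic"]),
        intron = .solveMarkov(config$elementGC["intron"],
                              config$elementOE["intron"]),
        five_prime_UTR = .solveMarkov(config$elementGC["five_prime_UTR"],
                                      config$elementOE["five_prime_UTR"]),
        three_prime_UTR = .solveMarkov(config$elementGC["three_prime_UTR"],
                                       config$elementOE["three_prime_UTR"]),
        CDS_LCpG = .solveMarkov(config$elementGC["CDS"],
                                config$elementOE["CDS_LCpG"]),
        CDS_HCpG = .solveMarkov(config$elementGC["CDS"],
                                config$elementOE["CDS_HCpG"]))

    annRows <- list(); geneTruth <- list()
    geneCounter <- 0L
    seqList <- list()
    for (ch in names(config$chromLengths)) {
        L <- as.integer(config$chromLengths[[ch]])
        pos <- 1L; parts <- character(0); segs <- list()
        addSeg <- function(type, len) {
            segs[[length(segs) + 1L]] <<- list(type = type, start = pos,
                                               end = pos + len - 1L)
            pos <<- pos + len
        }
        while (pos < L) {
            gap <- as.integer(pmax(2000, stats::rexp(1, 1 / config$geneSpacing)))
            addSeg("intergenic", min(gap, L - pos + 1L))
            if (pos >= L - 20000L) break
            ## one gene
            geneCounter <- geneCounter + 1L
            gid <- sprintf("gene%04d", geneCounter)
            cls <- if (stats::runif(1) < config$probHCpG) "HCpG" else "LCpG"
            strand <- sample(c("+", "-"), 1L)
            gStart <- pos
            nEx <- sample(3:7, 1L)
            u5 <- sample(150:400, 1L); u3 <- sample(200:500, 1L)
            exLens <- sample(150:450, nEx, replace = TRUE)
            inLens <- sample(100:1500, nEx - 1L, replace = TRUE)
            addSeg("five_prime_UTR", u5)
            for (x in seq_len(nEx)) {
                addSeg(paste0("CDS_", cls), exLens[x])
                if (x < nEx) addSeg("intron", inLens[x])
            }
            addSeg("three_prime_UTR", u3)
            gEnd <- pos - 1L
            if (gEnd > L) break
            geneTruth[[length(geneTruth) + 1L]] <- data.frame(
                gene_id = gid, chrom = ch, strand = strand,
                cpg_class = cls, stringsAsFactors = FALSE)
            for (sg in segs[vapply(segs, function(s) s$start >= gStart,
                                   logical(1))]) {
                type <- sub("^CDS_.*", "CDS", sg$type)
                if (type %in% c("CDS", "five_prime_UTR", "three_prime_UTR"))
                    annRows[[length(annRows) + 1L]] <- data.frame(
                        chrom = ch, start = sg$start, end = sg$end,
                        type = type, gene_id = gid, strand = strand,
                        stringsAsFactors = FALSE)
            }
            annRows[[length(annRows) + 1L]] <- data.frame(
                chrom = ch, start = gStart, end = gEnd, type = "gene",
                gene_id = gid, strand = strand, stringsAsFactors = FALSE)
        }
        if (pos <= L) {
            segs[[length(segs) + 1L]] <- list(type = "intergenic",
                                              start = pos, end = L)
        }
        ## clip segments to chromosome end and emit sequence
        chSeq <- character(length(segs))
        for (j in seq_along(segs)) {
            sg <- segs[[j]]
            len <- min(sg$end, L) - sg$start + 1L
            if (len <= 0) next
            chSeq[j] <- paste(.sampleMarkov(models[[sg$type]], len),
                              collapse = "")
        }
        seqList[[ch]] <- paste(chSeq, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(unlist(seqList))
    ann <- do.call(rbind, annRows)
    ann <- ann[ann$end <= config$chromLengths[ann$chrom], , drop = FALSE]
    annotation <- GRanges(ann$chrom, IRanges(ann$start, ann$end),
                          strand = ann$strand, type = ann$type,
                          gene_id = ann$gene_id,
                          phase = ifelse(ann$type == "CDS", 0L, NA_integer_))
    GenomeInfoDb::seqlengths(annotation) <-
        config$chromLengths[GenomeInfoDb::seqlevels(annotation)]
    cds <- annotation[annotation$type == "CDS"]
    cdsByGene <- split(cds, cds$gene_id)
    list(genome = genome, annotation = annotation,
         elements = resolveElements(annotation),
         cdsByGene = cdsByGene,
         geneTruth = do.call(rbind, geneTruth))
}

## ---- recombination map ---------------------------------------------------

#' Simulate a piecewise-constant recombination map
#'
#' Tiles each chromosome with rate intervals of roughly the configured mean
#' length, drawing rho/kb from a log-normal with mean `rhoMean`. When a
#' planted gene-class effect is requested, intervals are cut at CDS
#' boundaries and CDS pieces multiplied by the class multiplier.
#'
#' @param config a [simConfig()] object.
#' @param genomeSim optional [simulateGenome()] output; required for planted
#'   gene-class effects.
#' @param plantGeneEffects multiply CDS rho by `config$rhoMultipliers` per
#'   planted gene CpG class.
#' @return a `GRanges` rate map with `rho_per_kb`, tiling each chromosome.
#' @export
simulateRhoMap <- function(config, genomeSim = NULL,
                           plantGeneEffects = FALSE) {
    stopifnot(inherits(config, "beeSimConfig"))
    withSeed(config$seed + 1L, {
        maps <- lapply(names(config$chromLengths), function(ch) {
            L <- as.integer(config$chromLengths[[ch]])
            starts <- 1L; ends <- integer(0)
            pos <- 1L
            while (pos <= L) {
                len <- as.integer(pmax(500,
                    stats::rexp(1, 1 / config$rhoSegmentLength)))
                ends <- c(ends, min(pos + len - 1L, L))
                pos <- pos + len
                if (pos <= L) starts <- c(starts, pos)
            }
            mlog <- log(config$rhoMean) - config$rhoSdLog^2 / 2
            rho <- stats::rlnorm(length(starts), mlog, config$rhoSdLog)
            GRanges(ch, IRanges(starts, ends), rho_per_kb = rho)
        })
        ## chromosomes are generated separately; merging their seqlevels is
        ## intentional
        map <- suppressWarnings(do.call(c, maps))
        GenomeInfoDb::seqlengths(map) <-
            config$chromLengths[GenomeInfoDb::seqlevels(map)]
        if (plantGeneEffects) {
            if (is.null(genomeSim))
                stop("genomeSim required to plant gene-class effects")
            for (cls in names(config$rhoMultipliers)) {
                ids <- genomeSim$geneTruth$gene_id[
                    genomeSim$geneTruth$cpg_class == cls]
                if (!length(ids)) next
                clsCds <- reduce(unlist(GRangesList(
                    as.list(genomeSim$cdsByGene[ids]))), ignore.strand = TRUE)
                pieces <- disjoin(c(granges(map), clsCds))
                ov <- findOverlaps(pieces, map)
                rho <- mcols(map)$rho_per_kb[subjectHits(ov)]
                inCds <- overlapsAny(pieces[queryHits(ov)], clsCds)
                rho[inCds] <- rho[inCds] * config$rhoMultipliers[[cls]]
                map <- pieces[queryHits(ov)]
                mcols(map)$rho_per_kb <- rho
            }
            map <- sort(map)
            GenomeInfoDb::seqlengths(map) <-
                config$chromLengths[GenomeInfoDb::seqlevels(map)]
        }
        map
    })
}

## ---- SNPs ----------------------------------------------------------------

## Discretized sojourn density on a 1e4-point grid.
.sampleFrequencies <- function(B, size, gridN = 1e4L) {
    if (size == 0L) return(numeric(0))
    x <- (seq_len(gridN) - 0.5) / gridN
    w <- .sojourn(x, B)
    sample(x, size, replace = TRUE, prob = w)
}

## Outgroup substitution kernel: transition favoured by factor kappa.
.evolveBase <- function(base, pSub, kappa) {
    ti <- c(A = "G", G = "A", C = "T", T = "C")
    out <- base
    hit <- stats::runif(length(base)) < pSub
    if (any(hit)) {
        bh <- base[hit]
        u <- stats::runif(sum(hit))
        pTi <- kappa / (kappa + 2)
        res <- character(length(bh))
        isTi <- u < pTi
        res[isTi] <- ti[bh[isTi]]
        tvPick <- stats::runif(sum(!isTi)) < 0.5
        tvs <- t(vapply(bh[!isTi], function(b) setdiff(BASES, c(b, ti[b])),
                        character(2)))
        if (length(tvPick))
            res[!isTi] <- ifelse(tvPick, tvs[, 1L], tvs[, 2L])
        out[hit] <- res
    }
    out
}

#' Simulate SNPs with class-specific gBGC-shaped frequency spectra
#'
#' Plants biallelic SNPs on the reference: per-class site counts are Poisson
#' in the class influx times the eligible (W or S ancestral) bases; derived
#' alleles follow the AT mutational bias and Ti/Tv mix; population derived
#' frequencies are drawn from the stationary sojourn density at the class B
#' (transitions vs transversions; GC-conservative classes neutral); sample
#' counts are Binomial(n, x) conditioned on segregation by rejection. The
#' outgroup allele evolves from the true ancestral base along
#' `outgroupBranch`, mechanistically creating polarization-error-inducing
#' states, and a whole-chromosome outgroup consensus plus coverage mask are
#' produced for divergence estimation.
#'
#' @param config a [simConfig()] object.
#' @param genomeSim [simulateGenome()] output.
#' @param rhoMap optional rate map; required when `config$BofRho` is set.
#' @return list with `sites` (a [siteTable()] including `outgroup_depth`),
#'   `truth` (per-SNP ground truth), `outgroup` (`DNAStringSet`), `mask`
#'   (`GRanges` of adequately covered regions) and `n`.
#' @export
simulateSnps <- function(config, genomeSim, rhoMap = NULL) {
    stopifnot(inherits(config, "beeSimConfig"))
    withSeed(config$seed + 2L, .simulateSnpsImpl(config, genomeSim, rhoMap))
}

.simulateSnpsImpl <- function(config, genomeSim, rhoMap) {
    n <- config$nHaplotypes
    genome <- genomeSim$genome
    allSites <- list(); allTruth <- list()
    outList <- list()
    maskList <- list()
    for (ch in names(genome)) {
        refChars <- strsplit(as.character(genome[[ch]]), "")[[1]]
        L <- length(refChars)
        isW <- refChars %in% WEAK
        Wpos <- which(isW); Spos <- which(!isW)
        ## theta is a mutational influx: the expected number of segregating
        ## sites scales with the sojourn mass of the class's B (favoured
        ## mutations linger at observable frequencies), normalized so the
        ## neutral classes see exactly theta x eligible bases
        BtiEff <- if (!is.null(config$BofRho)) {
            stopifnot(!is.null(rhoMap))
            config$BofRho(sum(width(rhoMap) * mcols(rhoMap)$rho_per_kb) /
                          sum(width(rhoMap)))
        } else config$Bti
        mass <- function(B) sum(expectedClassSpectrum(B, n))
        m0 <- mass(0)
        mWS <- (config$tiProb * mass(BtiEff) +
                (1 - config$tiProb) * mass(config$Btv)) / m0
        mSW <- (config$tiProb * mass(-BtiEff) +
                (1 - config$tiProb) * mass(-config$Btv)) / m0
        ## Ti fraction among observed (segregating) WS / SW SNPs
        tiObsWS <- config$tiProb * mass(BtiEff) / (m0 * mWS)
        tiObsSW <- config$tiProb * mass(-BtiEff) / (m0 * mSW)
        nWS <- stats::rpois(1, config$thetaWS * mWS * length(Wpos))
        nWW <- stats::rpois(1, config$thetaWW * length(Wpos))
        nSW <- stats::rpois(1, config$thetaSW * mSW * length(Spos))
        nSS <- stats::rpois(1, config$thetaSS * length(Spos))
        nWS <- min(nWS, length(Wpos)); nSW <- min(nSW, length(Spos))
        wPick <- sample(Wpos, min(nWS + nWW, length(Wpos)))
        sPick <- sample(Spos, min(nSW + nSS, length(Spos)))
        posWS <- wPick[seq_len(min(nWS, length(wPick)))]
        posWW <- setdiff(wPick, posWS)
        posSW <- sPick[seq_len(min(nSW, length(sPick)))]
        posSS <- setdiff(sPick, posSW)

        ti <- c(A = "G", G = "A", C = "T", T = "C")
        mkClass <- function(pos, mclass) {
            if (!length(pos)) return(NULL)
            anc <- refChars[pos]
            pTi <- switch(mclass, WS = tiObsWS, SW = tiObsSW, config$tiProb)
            isTi <- stats::runif(length(pos)) < pTi
            der <- character(length(pos))
            if (mclass %in% c("WS", "SW")) {
                der[isTi] <- ti[anc[isTi]]
                ## W->S Tv: A->C, T->G; S->W Tv: G->T, C->A
                tv <- if (mclass == "WS") c(A = "C", T = "G")
                      else c(G = "T", C = "A")
                der[!isTi] <- tv[anc[!isTi]]
            } else if (mclass == "WW") {
                der <- ifelse(anc == "A", "T", "A")
                isTi <- rep(FALSE, length(pos))
            } else {
                der <- ifelse(anc == "G", "C", "G")
                isTi <- rep(FALSE, length(pos))
            }
            data.frame(pos = pos, anc = anc, der = der,
                       mclass = mclass, titv = ifelse(isTi, "Ti", "Tv"),
                       stringsAsFactors = FALSE)
        }
        snp <- rbind(mkClass(posWS, "WS"), mkClass(posWW, "WW"),
                     mkClass(posSW, "SW"), mkClass(posSS, "SS"))
        if (is.null(snp) || !nrow(snp)) next
        snp <- snp[order(snp$pos), , drop = FALSE]

        ## per-site B: + for WS derived-S, - for SW derived-W, 0 neutral
        Bti <- if (!is.null(config$BofRho)) {
            stopifnot(!is.null(rhoMap))
            rhoAt <- aggregateRho(rhoMap,
                GRanges(ch, IRanges(snp$pos, width = 1L)))
            config$BofRho(rhoAt)
        } else rep(config$Bti, nrow(snp))
        Bsite <- ifelse(snp$mclass %in% c("WW", "SS"), 0,
                 ifelse(snp$titv == "Ti", Bti, config$Btv))
        Bsite <- ifelse(snp$mclass == "SW", -Bsite,
                 ifelse(snp$mclass == "WS", Bsite, 0))

        ## frequencies then sample counts, rejecting monomorphic draws
        x <- numeric(nrow(snp)); k <- integer(nrow(snp))
        todo <- seq_len(nrow(snp))
        while (length(todo)) {
            for (b in unique(Bsite[todo])) {
                ii <- todo[Bsite[todo] == b]
                x[ii] <- .sampleFrequencies(b, length(ii))
            }
            k[todo] <- stats::rbinom(length(todo), n, x[todo])
            todo <- todo[k[todo] <= 0L | k[todo] >= n]
        }

        ## outgroup: evolve each SNP's ancestral base; background divergence
        pSub <- 1 - exp(-config$outgroupBranch)
        outAllele <- .evolveBase(snp$anc, pSub, config$outgroupKappa)
        bgN <- stats::rbinom(1, L, pSub)
        bgPos <- sample.int(L, bgN)
        bgPos <- setdiff(bgPos, snp$pos)
        outChars <- refChars
        if (length(bgPos))
            outChars[bgPos] <- .evolveBase(refChars[bgPos], 1, config$outgroupKappa)
        outChars[snp$pos] <- outAllele
        outList[[ch]] <- paste(outChars, collapse = "")

        ## coverage mask: 500 bp tiles kept with the configured probability
        tiles <- seq(1L, L, by = 500L)
        keepTile <- stats::runif(length(tiles)) < config$coverageFraction
        if (any(keepTile)) {
            mk <- reduce(GRanges(ch, IRanges(tiles[keepTile],
                pmin(tiles[keepTile] + 499L, L))))
            maskList[[ch]] <- mk
        }
        inMask <- if (!is.null(maskList[[ch]]))
            overlapsAny(GRanges(ch, IRanges(snp$pos, width = 1L)),
                        maskList[[ch]]) else rep(FALSE, nrow(snp))
        depth <- ifelse(inMask, 5L + stats::rpois(nrow(snp), 10),
                        stats::rpois(nrow(snp), 2))

        left <- ifelse(snp$pos > 1L, refChars[pmax(snp$pos - 1L, 1L)],
                       NA_character_)
        right <- ifelse(snp$pos < L, refChars[pmin(snp$pos + 1L, L)],
                        NA_character_)
        ## site table is unpolarized: allele_x = reference (true ancestral),
        ## allele_y = alternate (true derived), count_y = derived copies
        allSites[[ch]] <- data.frame(chrom = ch, pos = snp$pos,
            allele_x = snp$anc, allele_y = snp$der, count_y = k,
            n = n, outgroup_allele = outAllele, outgroup_depth = depth,
            left_base = left, right_base = right, stringsAsFactors = FALSE)
        allTruth[[ch]] <- data.frame(chrom = ch, pos = snp$pos,
            true_ancestral = snp$anc, true_derived = snp$der,
            true_class = snp$mclass, titv = snp$titv, true_x = x,
            k = k, n = n, B_site = Bsite,
            outgroup_changed = outAllele != snp$anc,
            stringsAsFactors = FALSE)
    }
    mask <- if (length(maskList)) {
        m <- do.call(c, unname(maskList))
        GenomeInfoDb::seqlengths(m) <-
            config$chromLengths[GenomeInfoDb::seqlevels(m)]
        m
    } else GRanges()
    list(sites = do.call(rbind, allSites), truth = do.call(rbind, allTruth),
         outgroup = Biostrings::DNAStringSet(unlist(outList)),
         mask = mask, n = n)
}

#' Simulate class spectra directly from the model expectation
#'
#' The fast path for estimator testing: independent Poisson draws around
#' [expectedObservedSpectra()]. Bit-reproducible given `seed`.
#'
#' @param B,theta,e,r,n model parameters (see
#'   [expectedObservedSpectra()]; `r = NULL` means no distortion).
#' @param seed integer seed.
#' @return a [ClassSFS-class].
#' @export
simulateClassSfs <- function(B, theta, e = c(WS = 0, SW = 0, N = 0),
                             r = NULL, n = 60L, seed = 1L) {
    if (is.null(r)) r <- rep(1, n - 1L)
    E <- expectedObservedSpectra(B, theta, e, r, n)
    withSeed(seed, {
        counts <- matrix(stats::rpois(length(E), E), nrow = 3L,
                         dimnames = dimnames(E))
        ClassSFS(counts["WS", ], counts["SW", ], counts["N", ], n = n)
    })
}

## ---- gene tables ---------------------------------------------------------

#' Simulate expression lists and a methylated-CpG site table
#'
#' Genes receive planted expression classes and germline methylation levels
#' correlated with their planted CpG class at the configured association
#' strength (0 = independent). mCpG sites are sampled from the actual CpG
#' positions of each methylated gene's coding sequence; planted UNMET genes
#' emit none.
#'
#' @param config a [simConfig()] object.
#' @param genomeSim [simulateGenome()] output.
#' @return list with `qw` and `dw` expression lists (each QgtW/WgtQ/NS or
#'   DgtW/WgtD/NS character vectors), `mcpg` (`GRanges` of methylated CpG
#'   sites) and `geneTruth` (planted classes per gene).
#' @export
simulateGeneTables <- function(config, genomeSim) {
    stopifnot(inherits(config, "beeSimConfig"))
    withSeed(config$seed + 3L, {
        gt <- genomeSim$geneTruth
        a <- config$assocStrength
        isH <- gt$cpg_class == "HCpG"
        ## expression: HCpG genes lean worker-biased, LCpG drone-biased
        pW <- ifelse(isH, 0.15 + 0.35 * a, 0.15)
        u <- stats::runif(nrow(gt))
        expr_dw <- rep("NS", nrow(gt))
        expr_dw[u < pW] <- "WgtD"
        pD <- ifelse(isH, 0.15, 0.15 + 0.35 * a)
        u2 <- stats::runif(nrow(gt))
        expr_dw[expr_dw == "NS" & u2 < pD] <- "DgtW"
        expr_qw <- sample(c("QgtW", "WgtQ", "NS"), nrow(gt), replace = TRUE,
                          prob = c(0.15, 0.15, 0.7))
        ## methylation: LCpG genes mostly methylated, HCpG mostly not
        pMeth <- ifelse(isH, 0.4 - 0.3 * a, 0.4 + 0.5 * a)
        methylated <- stats::runif(nrow(gt)) < pMeth
        propMeth <- ifelse(methylated,
            stats::rbeta(nrow(gt), ifelse(isH, 1.5, 4), 4), 0)
        mcpg <- GRanges()
        for (j in which(methylated)) {
            gid <- gt$gene_id[j]
            cds <- sort(genomeSim$cdsByGene[[gid]])
            ch <- as.character(seqnames(cds))[1L]
            hits <- unlist(lapply(seq_along(cds), function(i) {
                m <- Biostrings::matchPattern("CG",
                    Biostrings::extractAt(genomeSim$genome[[ch]],
                                          ranges(cds[i]))[[1L]])
                start(m) + start(cds[i]) - 1L
            }))
            if (!length(hits)) next
            nPick <- stats::rbinom(1, length(hits), propMeth[j])
            if (nPick == 0) next
            at <- sample(hits, nPick)
            mcpg <- c(mcpg, GRanges(ch, IRanges(at, width = 2L)))
        }
        gt$expr_qw <- expr_qw
        gt$expr_dw <- expr_dw
        gt$planted_methylated <- methylated
        gt$planted_prop_meth <- propMeth
        list(qw = split(gt$gene_id, expr_qw)[c("QgtW", "WgtQ", "NS")],
             dw = split(gt$gene_id, expr_dw)[
                 intersect(c("DgtW", "WgtD", "NS"), unique(expr_dw))],
             mcpg = sort(mcpg), geneTruth = gt)
    })
}
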