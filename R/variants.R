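## Polarization and classification of biallelic SNPs.
##
## Internally all interval arithmetic is 0-based half-open; site tables carry
## the original 1-based VCF coordinate in `pos` and conversion happens only at
## I/O boundaries.

#' Build a validated site table of biallelic SNPs
#'
#' The site table is the package's exchange format for unpolarized SNPs: one
#' row per biallelic site with the two segregating alleles, the sample count
#' of allele Y among `n` haplotypes, the outgroup consensus allele and its
#' read depth, and the two reference bases flanking the site (used for
#' dinucleotide context).
#'
#' @param chrom chromosome identifiers.
#' @param pos 1-based positions.
#' @param alleleX,alleleY the two segregating alleles (A/C/G/T), distinct.
#' @param countY copies of `alleleY` among the sampled haplotypes,
#'   strictly between 0 and `n`.
#' @param n haploid sample size (default 60, i.e. 30 diploids).
#' @param outgroupAllele outgroup consensus base, `NA` when missing.
#' @param outgroupDepth outgroup read depth at the site.
#' @param leftBase,rightBase reference bases immediately flanking the site
#'   (`NA` at contig ends).
#' @return a `data.frame` with one row per site.
#' @examples
#' siteTable("chr1", 101, "A", "G", 12)
#' @export
siteTable <- function(chrom, pos, alleleX, alleleY, countY, n = 60L,
                      outgroupAllele = NA_character_, outgroupDepth = 0L,
                      leftBase = NA_character_, rightBase = NA_character_) {
    df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
        allele_x = as.character(alleleX), allele_y = as.character(alleleY),
        count_y = as.integer(countY), n = as.integer(n),
        outgroup_allele = as.character(outgroupAllele),
        outgroup_depth = as.integer(outgroupDepth),
        left_base = as.character(leftBase),
        right_base = as.character(rightBase),
        stringsAsFactors = FALSE)
    if (any(df$pos < 1L)) stop("positions must be >= 1")
    if (any(df$allele_x == df$allele_y)) stop("allele_x must differ from allele_y")
    if (!all(df$allele_x %in% BASES) || !all(df$allele_y %in% BASES))
        stop("alleles must be A, C, G or T")
    if (any(df$count_y <= 0L | df$count_y >= df$n))
        stop("count_y must satisfy 0 < count_y < n (sites must be segregating)")
    df
}

#' Classify a mutation by weak/strong membership and transition status
#'
#' Weak (W) alleles are A or T; strong (S) alleles are G or C. The ordered
#' pair (ancestral, derived) yields one of WS, SW, WW, SS, and is a transition
#' (Ti) when both alleles are purines or both pyrimidines.
#'
#' @param ancestral,derived vectors of distinct bases in A/C/G/T.
#' @return a `data.frame` with columns `mclass` and `titv`.
#' @examples
#' classifyMutation(c("A", "C", "G"), c("G", "A", "C"))
#' @export
classifyMutation <- function(ancestral, derived) {
    ancestral <- toupper(as.character(ancestral))
    derived <- toupper(as.character(derived))
    if (!all(ancestral %in% BASES) || !all(derived %in% BASES))
        stop("alleles must be A, C, G or T")
    if (any(ancestral == derived)) stop("ancestral and derived must differ")
    sA <- ancestral %in% STRONG
    sD <- derived %in% STRONG
    mclass <- ifelse(sA, ifelse(sD, "SS", "SW"), ifelse(sD, "WS", "WW"))
    purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
    titv <- ifelse(purine[ancestral] == purine[derived], "Ti", "Tv")
    data.frame(mclass = mclass, titv = unname(titv), stringsAsFactors = FALSE)
}

#' Dinucleotide context flags for a polarized SNP
#'
#' Flags whether the derived allele creates a CpG or GpC dinucleotide that is
#' absent with the ancestral allele, and symmetrically whether the ancestral
#' allele sits in a CpG or GpC that the derived allele destroys. Flanking
#' bases come from the ingroup reference; a missing flank contributes no flag
#' from that side. Flags are independent and may co-occur.
#'
#' @param left,right reference bases flanking the site (`NA` allowed).
#' @param ancestral,derived the polarized alleles.
#' @return a logical matrix with columns `cpg_creating`, `gpc_creating`,
#'   `cpg_destroying`, `gpc_destroying`.
#' @examples
#' dinucleotideContext("C", "A", "A", "G")  # creates CpG
#' @export
dinucleotideContext <- function(left, right, ancestral, derived) {
    left <- toupper(as.character(left)); right <- toupper(as.character(right))
    anc <- toupper(as.character(ancestral)); der <- toupper(as.character(derived))
    eq <- function(x, b) !is.na(x) & x == b
    cbind(
        cpg_creating   = (eq(left, "C") & der == "G") | (eq(right, "G") & der == "C"),
        gpc_creating   = (eq(left, "G") & der == "C") | (eq(right, "C") & der == "G"),
        cpg_destroying = (eq(left, "C") & anc == "G") | (eq(right, "G") & anc == "C"),
        gpc_destroying = (eq(left, "G") & anc == "C") | (eq(right, "C") & anc == "G"))
}

#' Estimate the weighted-parsimony substitution model from summary counts
#'
#' The ingroup mutation weight matrix is estimated from polymorphism counts:
#' \eqn{\mu(X \to Y)} is the number of biallelic polymorphisms with outgroup
#' allele X and segregating alleles X/Y, divided by the number of aligned X
#' bases (the ancestral-base opportunity). The outgroup substitution matrix
#' uses ingroup-fixed sites that differ from the outgroup:
#' \eqn{\sigma(X \to Y)} is the count of fixed X-to-Y differences divided by
#' the aligned X-base count. Both are single-pass moment estimates on a
#' common per-site scale.
#'
#' @param polyCounts 4x4 matrix of polymorphism counts, rows = putative
#'   ancestral (outgroup-matching) base X, columns = the other allele Y.
#' @param fixedCounts 4x4 matrix of ingroup-fixed X vs outgroup-Y difference
#'   counts (rows = ingroup base X, columns = outgroup base Y).
#' @param baseCounts named numeric of aligned base counts for A, C, G, T.
#' @return a [SubstitutionModel-class] object.
#' @examples
#' poly <- matrix(10, 4, 4); diag(poly) <- 0
#' fixed <- matrix(5, 4, 4); diag(fixed) <- 0
#' estimateSubstitutionModel(poly, fixed, c(A = 1000, C = 1000, G = 1000, T = 1000))
#' @export
estimateSubstitutionModel <- function(polyCounts, fixedCounts, baseCounts) {
    polyCounts <- as.matrix(polyCounts); fixedCounts <- as.matrix(fixedCounts)
    baseCounts <- baseCounts[BASES]
    if (any(is.na(baseCounts)))
        stop("baseCounts must be named A, C, G, T")
    if (any(polyCounts < 0) || any(fixedCounts < 0))
        stop("counts must be nonnegative")
    zero <- names(baseCounts)[baseCounts <= 0]
    if (length(zero))
        stop("zero aligned-base opportunity for base(s): ",
             paste(zero, collapse = ", "))
    mu <- sweep(polyCounts, 1L, baseCounts, "/")
    sigma <- sweep(fixedCounts, 1L, baseCounts, "/")
    diag(mu) <- 0; diag(sigma) <- 0
    SubstitutionModel(mu, sigma)
}

## Scenario weights for one orientation: probability weight that `anc` is the
## ancestral allele of the pair (anc -> other) given outgroup allele `out`.
.parsimonyWeight <- function(anc, other, out, mu, sigma) {
    w <- numeric(length(anc))
    idxMut <- cbind(match(anc, BASES), match(other, BASES))
    w <- mu[idxMut]
    matchOut <- !is.na(out) & out == anc
    mismatch <- !is.na(out) & out != anc
    idxSub <- cbind(match(anc, BASES), match(out, BASES))
    w[mismatch] <- w[mismatch] * sigma[idxSub[mismatch, , drop = FALSE]]
    w[is.na(out)] <- NA_real_
    w
}

#' Polarize biallelic SNPs by substitution-aware weighted parsimony
#'
#' For a site with segregating alleles X/Y and outgroup allele O, two
#' evolutionary scenarios are weighed: (i) X ancestral, requiring an ingroup
#' X-to-Y mutation (and an outgroup X-to-O substitution when O differs from
#' X); (ii) Y ancestral, analogously. The probability that the chosen
#' ancestral allele is correct is its scenario weight over the sum of both
#' weights; sites below `pThreshold`, ties, sites with no outgroup allele or
#' insufficient outgroup depth, and sites where both weights vanish are
#' reported as unresolved with a reason code.
#'
#' @param sites a site table from [siteTable()] (or the same columns).
#' @param model a [SubstitutionModel-class].
#' @param pThreshold minimum ancestral-allele probability to accept a
#'   polarization (default 0.9).
#' @param minOutgroupDepth minimum outgroup depth (default 5).
#' @return a list with `snps` (polarized table: ancestral, derived, derived
#'   copy number `k`, `p_ancestral`, `mclass`, `titv`, context flags and
#'   derived allele frequency `f_d`), `unresolved` (sites with a `reason`
#'   column) and `counts` (per-reason tally).
#' @examples
#' mu <- matrix(0.01, 4, 4); diag(mu) <- 0
#' sg <- matrix(0.002, 4, 4); diag(sg) <- 0
#' m <- SubstitutionModel(mu, sg)
#' s <- siteTable("chr1", 500, "A", "G", 10, outgroupAllele = "A",
#'                outgroupDepth = 10, leftBase = "C", rightBase = "T")
#' polarizeSites(s, m)$snps
#' @export
polarizeSites <- function(sites, model, pThreshold = 0.9, minOutgroupDepth = 5L) {
    stopifnot(is(model, "SubstitutionModel"))
    mu <- model@mu; sigma <- model@sigma
    out <- toupper(sites$outgroup_allele)
    out[!is.na(out) & !(out %in% BASES)] <- NA_character_

    wX <- .parsimonyWeight(sites$allele_x, sites$allele_y, out, mu, sigma)
    wY <- .parsimonyWeight(sites$allele_y, sites$allele_x, out, mu, sigma)

    reason <- rep(NA_character_, nrow(sites))
    reason[is.na(out)] <- "no outgroup"
    lowDepth <- is.na(reason) & sites$outgroup_depth < minOutgroupDepth
    reason[lowDepth] <- "low outgroup depth"
    zero <- is.na(reason) & (wX + wY) == 0
    reason[zero] <- "uninformative model"
    tie <- is.na(reason) & wX == wY
    reason[tie] <- "tie"

    pX <- wX / (wX + wY)
    ancIsX <- pX >= 0.5
    pAnc <- ifelse(ancIsX, pX, 1 - pX)
    lowP <- is.na(reason) & pAnc < pThreshold
    reason[lowP] <- "below threshold"

    keep <- is.na(reason)
    snps <- sites[keep, , drop = FALSE]
    if (nrow(snps)) {
        isX <- ancIsX[keep]
        anc <- ifelse(isX, snps$allele_x, snps$allele_y)
        der <- ifelse(isX, snps$allele_y, snps$allele_x)
        k <- ifelse(isX, snps$count_y, snps$n - snps$count_y)
        cls <- classifyMutation(anc, der)
        ctx <- dinucleotideContext(snps$left_base, snps$right_base, anc, der)
        snps <- cbind(snps[c("chrom", "pos", "n")],
            data.frame(ancestral = anc, derived = der, k = as.integer(k),
                p_ancestral = pAnc[keep], mclass = cls$mclass, titv = cls$titv,
                stringsAsFactors = FALSE),
            as.data.frame(ctx))
        snps$f_d <- snps$k / snps$n
    } else {
        snps <- snps[0, , drop = FALSE]
    }
    unresolved <- sites[!keep, , drop = FALSE]
    unresolved$reason <- reason[!keep]
    list(snps = snps, unresolved = unresolved,
         counts = c(table(factor(reason, levels = c("no outgroup",
             "low outgroup depth", "uninformative model", "tie",
             "below threshold")))))
}

#' Filter sites on outgroup coverage and biallelic status
#'
#' @param sites a site table; an optional logical column `biallelic` marks
#'   sites that passed the biallelic check upstream (all `siteTable()` rows
#'   are biallelic by construction).
#' @param minOutgroupDepth minimum outgroup depth (default 5, mirroring a 5x
#'   consensus coverage cutoff).
#' @param biallelicOnly drop sites flagged non-biallelic.
#' @return the retained subset, with a `removed` attribute tallying the
#'   number removed per reason.
#' @export
filterSites <- function(sites, minOutgroupDepth = 5L, biallelicOnly = TRUE) {
    biallelic <- if ("biallelic" %in% names(sites)) sites$biallelic else TRUE
    badAllelic <- biallelicOnly & !biallelic
    lowDepth <- !badAllelic &
        (is.na(sites$outgroup_depth) | sites$outgroup_depth < minOutgroupDepth)
    keep <- !badAllelic & !lowDepth
    res <- sites[keep, , drop = FALSE]
    attr(res, "removed") <- c(not_biallelic = sum(badAllelic),
                              low_outgroup_depth = sum(lowDepth))
    res
}

#' Prune sites by minor allele frequency
#'
#' Removes sites whose minor allele frequency `min(k, n-k)/n` is strictly
#' below `mafThreshold`; a threshold of 0 is the identity.
#'
#' @param sites a site table.
#' @param mafThreshold proportion in `[0, 0.5)`.
#' @return the retained subset.
#' @export
mafPrune <- function(sites, mafThreshold = 0.1) {
    stopifnot(mafThreshold >= 0, mafThreshold < 0.5)
    maf <- pmin(sites$count_y, sites$n - sites$count_y) / sites$n
    sites[maf >= mafThreshold, , drop = FALSE]
}

## Evaluate an expression with a temporary, restorable RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Cap per-element diversity by uniform SNP subsampling
#'
#' For each annotation element whose Watterson diversity exceeds `thetaCap`,
#' uniformly subsamples (without replacement) the largest SNP count whose
#' recomputed theta_w does not exceed the cap. Elements at or below the cap
#' are returned unchanged. Deterministic given `seed`.
#'
#' @param sites a site table with an `element` column (element identifier).
#' @param elementLength named numeric: covered length L per element.
#' @param thetaCap per-base Watterson theta cap (default 0.002).
#' @param seed integer seed for the subsampling RNG.
#' @return the retained subset of `sites`.
#' @export
capElementDiversity <- function(sites, elementLength, thetaCap = 0.002,
                                seed = 1L) {
    if (thetaCap <= 0) stop("thetaCap must be positive")
    stopifnot("element" %in% names(sites))
    withSeed(seed, {
        keepIdx <- unlist(lapply(split(seq_len(nrow(sites)), sites$element),
            function(idx) {
                el <- sites$element[idx[1L]]
                L <- elementLength[[el]]
                n <- sites$n[idx[1L]]
                a <- sum(1 / seq_len(n - 1L))
                S <- length(idx)
                if (S / (a * L) <= thetaCap) return(idx)
                sMax <- floor(thetaCap * a * L)
                sort(sample(idx, sMax))
            }), use.names = FALSE)
        sites[sort(keepIdx), , drop = FALSE]
    })
}
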