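## Glue between the generator/readers and the estimators: tallying the
## substitution-model inputs from data, and the truth-comparison harness.

#' Tally weighted-parsimony model inputs from data
#'
#' Produces the three count sets consumed by [estimateSubstitutionModel()]:
#' polymorphism counts by (outgroup-matching allele, other allele) from
#' biallelic sites where the outgroup carries one of the two alleles;
#' ingroup-fixed vs outgroup difference counts from non-SNP positions where
#' reference and outgroup consensus disagree (within the coverage mask); and
#' the reference base composition as the per-base opportunity.
#'
#' @param sites a site table (with outgroup alleles).
#' @param genome named [Biostrings::DNAStringSet] reference.
#' @param outgroup aligned outgroup `DNAStringSet`.
#' @param mask optional `GRanges` restricting the fixed-difference scan.
#' @return list with `polyCounts`, `fixedCounts` (4x4 matrices) and
#'   `baseCounts` (named vector), ready for [estimateSubstitutionModel()].
#' @export
tallySubstitutionInputs <- function(sites, genome, outgroup, mask = NULL) {
    poly <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    og <- sites$outgroup_allele
    matchX <- !is.na(og) & og == sites$allele_x
    matchY <- !is.na(og) & og == sites$allele_y
    addPairs <- function(m, from, to) {
        if (!length(from)) return(m)
        t2 <- table(factor(from, BASES), factor(to, BASES))
        m + unclass(t2)
    }
    poly <- addPairs(poly, sites$allele_x[matchX], sites$allele_y[matchX])
    poly <- addPairs(poly, sites$allele_y[matchY], sites$allele_x[matchY])

    fixed <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    base <- stats::setNames(numeric(4), BASES)
    snpKey <- paste(sites$chrom, sites$pos)
    for (ch in names(genome)) {
        a <- strsplit(as.character(genome[[ch]]), "")[[1]]
        b <- strsplit(as.character(outgroup[[ch]]), "")[[1]]
        ok <- a %in% BASES & b %in% BASES
        if (!is.null(mask)) {
            inM <- rep(FALSE, length(a))
            mch <- mask[seqnames(mask) == ch]
            for (j in seq_along(mch))
                inM[start(mch)[j]:end(mch)[j]] <- TRUE
            ok <- ok & inM
        }
        isSnp <- paste(ch, seq_along(a)) %in% snpKey
        ok <- ok & !isSnp
        base <- base + vapply(BASES, function(bs) sum(a[ok] == bs), numeric(1))
        diffIdx <- which(ok & a != b)
        fixed <- addPairs(fixed, a[diffIdx], b[diffIdx])
    }
    list(polyCounts = poly, fixedCounts = fixed, baseCounts = base)
}

#' Compare polarized SNPs against generator ground truth
#'
#' Joins the polarized table with the per-SNP truth table on (chrom, pos) and
#' reports mispolarization rates overall and per assigned mutation class,
#' together with the fraction of truly WS/SW sites that ended up in the
#' opposite class. On synthetic data the WS mispolarization rate rises with
#' the simulated outgroup branch length; this harness is how that is
#' measured.
#'
#' @param snps polarized SNP table from [polarizeSites()].
#' @param truth `truth` component of [simulateSnps()].
#' @return list with `overall` mispolarization rate, `by_class` rates per
#'   assigned class, and `n_matched`.
#' @export
compareToTruth <- function(snps, truth) {
    key <- paste(snps$chrom, snps$pos)
    tkey <- paste(truth$chrom, truth$pos)
    idx <- match(key, tkey)
    ok <- !is.na(idx)
    snps <- snps[ok, , drop = FALSE]
    tt <- truth[idx[ok], , drop = FALSE]
    mis <- snps$ancestral != tt$true_ancestral
    byClass <- vapply(c("WS", "SW", "WW", "SS"), function(cl) {
        sel <- snps$mclass == cl
        if (!any(sel)) return(NA_real_)
        mean(mis[sel])
    }, numeric(1))
    list(overall = mean(mis), by_class = byClass, n_matched = nrow(snps))
}
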