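## Gene-level CpG, expression and germline-methylation classes, and the
## class-comparison analyses around crossover rates.

## Concatenate a gene's CDS parts in transcription orientation.
.cdsSequence <- function(cds, genome) {
    ch <- as.character(seqnames(cds))[1L]
    cds <- sort(cds)
    seqs <- Biostrings::extractAt(genome[[ch]], ranges(cds))
    s <- Biostrings::DNAString(paste(as.character(seqs), collapse = ""))
    if (as.character(strand(cds))[1L] == "-")
        s <- Biostrings::reverseComplement(s)
    s
}

#' Gene-body CpG observed/expected and CpG class
#'
#' Computes CpG O/E over the concatenated coding sequence of each gene (in
#' transcription orientation) and classifies genes as HCpG when strictly
#' above the threshold, LCpG otherwise. Gene-body CpG depletion marks a
#' history of germline methylation, so LCpG genes are the putatively
#' methylated class.
#'
#' @param cdsByGene a named `GRangesList` (or list of `GRanges`), one element
#'   of CDS intervals per gene.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param threshold HCpG cutoff (default 1.19, the genome-wide gene mean;
#'   use 1.04 for the 1 kb-window variant).
#' @param minLength minimum summed CDS length to classify (default 200).
#' @return `data.frame` with `gene_id`, `cds_cpg_oe`, `cpg_class`.
#' @export
geneCpGClass <- function(cdsByGene, genome, threshold = 1.19,
                         minLength = 200L) {
    ids <- names(cdsByGene)
    oe <- vapply(ids, function(g) {
        cds <- cdsByGene[[g]]
        if (sum(width(cds)) < minLength) return(NA_real_)
        cpgOE(.cdsSequence(cds, genome))
    }, numeric(1))
    cls <- ifelse(is.na(oe), NA_character_,
                  ifelse(oe > threshold, "HCpG", "LCpG"))
    data.frame(gene_id = ids, cds_cpg_oe = unname(oe),
               cpg_class = unname(cls), stringsAsFactors = FALSE)
}

#' Tag genes with caste-biased expression classes
#'
#' Annotates genes under the two expression schemes (queen vs worker, drone
#' vs worker) from membership lists. Genes absent from all lists of a scheme
#' get `NA`; genes claimed by two conflicting lists of one scheme are
#' excluded from that scheme with a diagnostic; list IDs not present in the
#' gene table are warned about, counted and skipped.
#'
#' @param genes `data.frame` with a `gene_id` column.
#' @param qw named list of character vectors `QgtW`, `WgtQ`, `NS` (any may
#'   be missing).
#' @param dw named list of character vectors `DgtW`, `WgtD`, `NS`.
#' @return `genes` with added `expr_qw` and `expr_dw` columns; attributes
#'   `unknown_ids` and `conflicts` carry the diagnostics.
#' @export
assignExpressionClass <- function(genes, qw = list(), dw = list()) {
    assign1 <- function(lists, levels) {
        lab <- rep(NA_character_, nrow(genes))
        conflicts <- character(0)
        unknown <- character(0)
        for (lv in levels) {
            ids <- lists[[lv]]
            if (is.null(ids)) next
            unknown <- c(unknown, setdiff(ids, genes$gene_id))
            hit <- genes$gene_id %in% ids
            clash <- hit & !is.na(lab) & lab != lv
            conflicts <- c(conflicts, genes$gene_id[clash])
            lab[hit & is.na(lab)] <- lv
        }
        lab[genes$gene_id %in% conflicts] <- NA_character_
        list(lab = lab, conflicts = unique(conflicts),
             unknown = unique(unknown))
    }
    aqw <- assign1(qw, c("QgtW", "WgtQ", "NS"))
    adw <- assign1(dw, c("DgtW", "WgtD", "NS"))
    unknown <- unique(c(aqw$unknown, adw$unknown))
    if (length(unknown))
        warning(length(unknown), " expression-list gene ID(s) not in gene table; skipped")
    conflicts <- unique(c(aqw$conflicts, adw$conflicts))
    if (length(conflicts))
        warning(length(conflicts),
                " gene(s) in conflicting expression lists; excluded from that scheme")
    genes$expr_qw <- aqw$lab
    genes$expr_dw <- adw$lab
    attr(genes, "unknown_ids") <- unknown
    attr(genes, "conflicts") <- conflicts
    genes
}

#' Germline methylation metrics and class per gene
#'
#' Counts significantly methylated CpGs (mCpGs) overlapping each gene's
#' coding sequence and derives the per-kb rate and the proportion of
#' available CpG sites methylated. Genes with no mCpG are UNMET; methylated
#' genes are split at the median of the methylated-proportion metric into
#' LMET (below) and HMET (at or above), so the two classes differ in size by
#' at most one gene.
#'
#' @param cdsByGene named `GRangesList` of CDS intervals per gene.
#' @param genome named [Biostrings::DNAStringSet] (to count available CpG
#'   sites in the coding sequence).
#' @param mcpg `GRanges` of methylated-CpG site coordinates (same assembly).
#' @return `data.frame` with `gene_id`, `cds_kb`, `n_cpg`, `n_mcpg`,
#'   `mcpg_per_kb`, `prop_cpg_methylated`, `meth_class`.
#' @export
methylationMetrics <- function(cdsByGene, genome, mcpg) {
    ids <- names(cdsByGene)
    res <- do.call(rbind, lapply(ids, function(g) {
        cds <- cdsByGene[[g]]
        kb <- sum(width(cds)) / 1000
        nCpG <- sum(Biostrings::vcountPattern("CG",
            Biostrings::extractAt(genome[[as.character(seqnames(cds))[1L]]],
                                  ranges(sort(cds)))))
        nM <- sum(countOverlaps(mcpg, cds) > 0)
        data.frame(gene_id = g, cds_kb = kb, n_cpg = nCpG, n_mcpg = nM,
                   stringsAsFactors = FALSE)
    }))
    res$mcpg_per_kb <- ifelse(res$n_cpg > 0, res$n_mcpg / res$cds_kb, NA_real_)
    res$prop_cpg_methylated <- ifelse(res$n_cpg > 0, res$n_mcpg / res$n_cpg,
                                      NA_real_)
    res$meth_class <- NA_character_
    ok <- res$n_cpg > 0
    res$meth_class[ok & res$n_mcpg == 0] <- "UNMET"
    methylated <- ok & res$n_mcpg > 0
    if (any(methylated)) {
        med <- stats::median(res$prop_cpg_methylated[methylated])
        res$meth_class[methylated] <-
            ifelse(res$prop_cpg_methylated[methylated] >= med, "HMET", "LMET")
    }
    res
}

#' Recombination rate in coding sequence and gene flanks
#'
#' Length-weighted mean population recombination rate over each gene's CDS,
#' and over two flanking spans pooled from both sides of the gene: a near
#' flank (default 50 kb starting 10 kb from each gene end) and a far flank
#' (default 100 kb starting 50 kb away). Flanks are truncated at chromosome
#' ends; with `noncodingOnly = TRUE` (default) annotated CDS bases of any
#' gene are excluded from flanks. Flanks are defined geometrically, so the
#' result is strand-invariant.
#'
#' @param geneSpans `GRanges` of gene spans with a `gene_id` column.
#' @param cdsByGene named `GRangesList` of CDS intervals per gene.
#' @param rateMap `GRanges` with `rho_per_kb`.
#' @param nearOffset,nearWidth,farOffset,farWidth flank geometry in bp.
#' @param noncodingOnly exclude all annotated CDS from flanks.
#' @return `data.frame` with `gene_id`, `rho_cds`, `rho_flank_near`,
#'   `rho_flank_far`.
#' @export
geneRegionRho <- function(geneSpans, cdsByGene, rateMap,
                          nearOffset = 1e4, nearWidth = 5e4,
                          farOffset = 5e4, farWidth = 1e5,
                          noncodingOnly = TRUE) {
    seqlens <- GenomeInfoDb::seqlengths(geneSpans)
    allCds <- reduce(unlist(GRangesList(as.list(cdsByGene))),
                     ignore.strand = TRUE)
    meanRho <- function(gr) {
        gr <- gr[width(gr) > 0]
        if (!length(gr)) return(NA_real_)
        v <- aggregateRho(rateMap, gr)
        if (all(is.na(v))) return(NA_real_)
        sum(v * width(gr), na.rm = TRUE) / sum(width(gr)[!is.na(v)])
    }
    flank2 <- function(g, offset, wdt) {
        ch <- as.character(seqnames(g))
        maxEnd <- seqlens[ch]
        if (is.na(maxEnd)) maxEnd <- .Machine$integer.max
        lft <- IRanges(max(1L, start(g) - offset - wdt),
                       max(0L, start(g) - offset - 1L))
        rgt <- IRanges(min(end(g) + offset + 1L, maxEnd + 1L),
                       min(end(g) + offset + wdt, maxEnd))
        r <- c(lft, rgt)
        r <- r[width(r) > 0]
        gr <- GRanges(ch, r)
        if (noncodingOnly) gr <- setdiff(gr, allCds, ignore.strand = TRUE)
        gr
    }
    res <- do.call(rbind, lapply(seq_along(geneSpans), function(j) {
        g <- geneSpans[j]
        id <- mcols(g)$gene_id
        cds <- cdsByGene[[id]]
        data.frame(gene_id = id,
            rho_cds = if (!is.null(cds)) meanRho(granges(cds)) else NA_real_,
            rho_flank_near = meanRho(flank2(g, nearOffset, nearWidth)),
            rho_flank_far = meanRho(flank2(g, farOffset, farWidth)),
            stringsAsFactors = FALSE)
    }))
    res
}

#' Bootstrap comparison of a statistic across gene classes
#'
#' Gene-weighted class means of a chosen statistic with 200-replicate
#' percentile bootstrap CIs, relative difference of each class mean from the
#' overall mean, and pairwise bootstrap p-values. Supports cross-tabulated
#' groupings by passing an interaction of two class columns.
#'
#' @param genes gene `data.frame`.
#' @param classCol name of the class column (or a vector of labels).
#' @param statCol name of the statistic column (or a numeric vector).
#' @param nBoot bootstrap replicates (default 200).
#' @param seed integer seed.
#' @return list with `classes` (class, n, mean, ci_lo, ci_hi, rel_diff) and
#'   `pairs` as in [bootstrapCompare()].
#' @export
compareGeneClasses <- function(genes, classCol, statCol, nBoot = 200L,
                               seed = 1L) {
    cls <- if (length(classCol) == 1L) genes[[classCol]] else classCol
    val <- if (length(statCol) == 1L && is.character(statCol))
        genes[[statCol]] else statCol
    ok <- !is.na(cls) & is.finite(val)
    bc <- bootstrapCompare(val[ok], cls[ok], nBoot = nBoot, seed = seed)
    overall <- mean(val[ok])
    bc$classes$rel_diff <- bc$classes$mean / overall - 1
    bc
}

#' Recombination rate at given diversity, by element class
#'
#' High-resolution control for the confounding of inferred recombination
#' with local diversity: the genome is cut into small windows (default 1 kb),
#' windows spanning more than `minElementBp` of coding or intergenic
#' sequence are classified accordingly (coding windows optionally split into
#' LCpG/HCpG by the majority gene class), and the mean recombination rate is
#' reported per diversity (theta_w) bin and class with bootstrap CIs.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param elements `GRangesList` from [resolveElements()].
#' @param sites site table for theta_w.
#' @param rateMap `GRanges` with `rho_per_kb`.
#' @param cdsByGene optional named `GRangesList`; with `geneCpG` enables the
#'   LCpG/HCpG split.
#' @param geneCpG optional `data.frame` from [geneCpGClass()] (use
#'   `threshold = 1.04` for this analysis).
#' @param windowSize window width (default 1 kb).
#' @param minElementBp minimum element bases to classify a window
#'   (default 500, strict).
#' @param thetaBreaks bin edges for theta_w (default deciles).
#' @param nBoot,seed bootstrap settings.
#' @return `data.frame`: class, theta bin, n windows, mean rho, CI bounds.
#' @export
rhoGivenThetaProfile <- function(genome, elements, sites, rateMap,
                                 cdsByGene = NULL, geneCpG = NULL,
                                 windowSize = 1e3, minElementBp = 500L,
                                 thetaBreaks = NULL, nBoot = 200L, seed = 1L) {
    seqlengths <- stats::setNames(Biostrings::width(genome), names(genome))
    wins <- genomeWindows(seqlengths, windowSize, minLastFrac = 1)
    n <- sites$n[1L]
    siteGr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
    S <- countOverlaps(wins, siteGr)
    theta <- wattersonTheta(S, n, width(wins))
    rho <- aggregateRho(rateMap, wins)
    ovWidth <- function(gr) {
        hits <- findOverlaps(wins, gr)
        w <- width(pintersect(wins[queryHits(hits)], gr[subjectHits(hits)]))
        out <- numeric(length(wins))
        agg <- tapply(w, queryHits(hits), sum)
        out[as.integer(names(agg))] <- agg
        out
    }
    codingBp <- ovWidth(elements$CDS)
    intergenicBp <- ovWidth(elements$intergenic)
    cls <- rep(NA_character_, length(wins))
    cls[intergenicBp > minElementBp] <- "intergenic"
    cls[codingBp > minElementBp] <- "coding"
    if (!is.null(cdsByGene) && !is.null(geneCpG)) {
        for (sub in c("LCpG", "HCpG")) {
            ids <- geneCpG$gene_id[!is.na(geneCpG$cpg_class) &
                                   geneCpG$cpg_class == sub]
            if (!length(ids)) next
            gr <- reduce(unlist(GRangesList(as.list(cdsByGene[ids]))),
                         ignore.strand = TRUE)
            bp <- ovWidth(gr)
            cls[cls %in% "coding" & bp > minElementBp] <- sub
        }
    }
    ok <- !is.na(cls) & !is.na(rho) & is.finite(theta)
    if (is.null(thetaBreaks))
        thetaBreaks <- unique(stats::quantile(theta[ok], seq(0, 1, 0.2)))
    bin <- cut(theta, thetaBreaks, include.lowest = TRUE)
    withSeed(seed, {
        cells <- expand.grid(class = unique(cls[ok]), bin = levels(bin),
                             stringsAsFactors = FALSE)
        do.call(rbind, lapply(seq_len(nrow(cells)), function(j) {
            sel <- ok & cls == cells$class[j] & !is.na(bin) &
                   as.character(bin) == cells$bin[j]
            v <- rho[sel]
            if (!length(v))
                return(data.frame(class = cells$class[j], bin = cells$bin[j],
                    n = 0L, mean_rho = NA_real_, ci_lo = NA_real_,
                    ci_hi = NA_real_, stringsAsFactors = FALSE))
            b <- vapply(seq_len(nBoot),
                        function(i) mean(sample(v, replace = TRUE)), numeric(1))
            data.frame(class = cells$class[j], bin = cells$bin[j],
                n = length(v), mean_rho = mean(v),
                ci_lo = unname(stats::quantile(b, 0.025)),
                ci_hi = unname(stats::quantile(b, 0.975)),
                stringsAsFactors = FALSE)
        }))
    })
}
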