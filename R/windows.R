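## Windowed genome statistics over annotation elements.
##
## Annotation overlap precedence: CDS > 5' UTR > 3' UTR > intron >
## intergenic; bases covered by no gene feature are intergenic. Windows are
## fixed and non-sliding, anchored at position 0 of each chromosome.

ELEMENT_TYPES <- c("CDS", "five_prime_UTR", "three_prime_UTR", "intron",
                   "intergenic")

#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

#' Resolve annotation into disjoint element ranges
#'
#' Builds a disjoint partition of the genome into CDS, 5' UTR, 3' UTR,
#' intron and intergenic ranges from a GFF3-style annotation, applying the
#' precedence CDS > UTR > intron > intergenic. Introns are gene bases not
#' covered by CDS or UTR; intergenic is everything outside genes.
#'
#' @param annotation a `GRanges` with a `type` metadata column containing at
#'   least `gene` and `CDS` entries (UTR types optional), e.g. from
#'   [rtracklayer::import()] of a GFF3 file.
#' @param seqlengths named vector of chromosome lengths (defaults to the
#'   seqlengths of `annotation`, which must then be set).
#' @return a named `GRangesList` with one element per element type; the
#'   union tiles the genome disjointly.
#' @export
resolveElements <- function(annotation, seqlengths = NULL) {
    if (is.null(seqlengths)) {
        seqlengths <- GenomeInfoDb::seqlengths(annotation)
        if (any(is.na(seqlengths)))
            stop("seqlengths must be provided or set on the annotation")
    }
    genome <- GRanges(names(seqlengths),
                      IRanges(1L, unname(seqlengths)))
    byType <- function(t) {
        g <- annotation[mcols(annotation)$type %in% t]
        reduce(g, ignore.strand = TRUE)
    }
    cds <- byType("CDS")
    utr5 <- setdiff(byType("five_prime_UTR"), cds, ignore.strand = TRUE)
    utr3 <- setdiff(byType("three_prime_UTR"),
                    union(cds, utr5, ignore.strand = TRUE),
                    ignore.strand = TRUE)
    genes <- byType(c("gene", "mRNA"))
    genic <- Reduce(function(a, b) union(a, b, ignore.strand = TRUE),
                    list(cds, utr5, utr3))
    intron <- setdiff(union(genes, genic, ignore.strand = TRUE), genic,
                      ignore.strand = TRUE)
    intergenic <- setdiff(genome,
                          union(genes, genic, ignore.strand = TRUE),
                          ignore.strand = TRUE)
    grl <- GRangesList(CDS = cds, five_prime_UTR = utr5,
                       three_prime_UTR = utr3, intron = intron,
                       intergenic = intergenic)
    grl
}

#' Fixed non-sliding genome windows
#'
#' @param seqlengths named chromosome lengths.
#' @param windowSize window width in bp (default 100 kb).
#' @param minLastFrac keep the final partial window of a chromosome only if
#'   it spans at least this fraction of `windowSize` (default 0.5).
#' @return a `GRanges` of windows.
#' @export
genomeWindows <- function(seqlengths, windowSize = 1e5, minLastFrac = 0.5) {
    w <- tileGenome(seqlengths, tilewidth = windowSize,
                    cut.last.tile.in.chrom = TRUE)
    w[width(w) >= windowSize * minLastFrac | width(w) == windowSize]
}

#' Length-weighted mean recombination rate over windows
#'
#' Aggregates a piecewise-constant population recombination map (intervals
#' carrying `rho_per_kb`) over query windows by overlap-length weighting.
#' Windows not covered by any interval yield `NA`.
#'
#' @param rateMap a `GRanges` with numeric metadata column `rho_per_kb`.
#' @param windows a `GRanges` of query windows.
#' @return numeric vector, one mean rho/kb per window.
#' @examples
#' rm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 301), c(300, 1000)),
#'                              rho_per_kb = c(100, 300))
#' w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
#' aggregateRho(rm, w)  # 0.3*100 + 0.7*300 = 240
#' @export
aggregateRho <- function(rateMap, windows) {
    stopifnot("rho_per_kb" %in% names(mcols(rateMap)))
    ## queries on chromosomes absent from the map are simply uncovered (NA)
    hits <- suppressWarnings(findOverlaps(windows, rateMap))
    ov <- suppressWarnings(pintersect(windows[queryHits(hits)],
                                      rateMap[subjectHits(hits)]))
    w <- width(ov)
    rho <- mcols(rateMap)$rho_per_kb[subjectHits(hits)]
    num <- tapply(w * rho, queryHits(hits), sum)
    den <- tapply(w, queryHits(hits), sum)
    res <- rep(NA_real_, length(windows))
    idx <- as.integer(names(num))
    res[idx] <- as.numeric(num / den)
    res
}

## Composition over a set of sequence fragments: dinucleotides are counted
## within fragments only (fragment junctions are not adjacent in the genome).
.fragmentComposition <- function(seqs) {
    if (!length(seqs))
        return(c(L = 0, C = 0, G = 0, GC = 0, CG = 0, GpC = 0))
    lf <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
    as.numeric(c(L = sum(lf), C = sum(lf[, "C"]), G = sum(lf[, "G"]),
      GC = sum(lf[, "C"] + lf[, "G"]),
      CG = sum(Biostrings::vcountPattern("CG", seqs)),
      GpC = sum(Biostrings::vcountPattern("GC", seqs)))) |>
        stats::setNames(c("L", "C", "G", "GC", "CG", "GpC"))
}

.oeFromComposition <- function(comp, which = "CG") {
    if (comp["C"] == 0 || comp["G"] == 0 || comp["L"] < 2) return(NA_real_)
    unname(comp[which] * comp["L"] / (comp["C"] * comp["G"]))
}

#' Windowed population-genetic statistics per annotation element
#'
#' For each fixed window and each annotation element type (plus the pooled
#' "all" row), computes Watterson's theta, pi and Tajima's D from the SNPs
#' falling on element bases, GC content and CpG O/E of the element sequence,
#' per-base divergence to an aligned outgroup consensus (over masked-in
#' bases) and the length-weighted mean recombination rate. Statistics are
#' reported absent (`NA`) when fewer than `minCovered` element bases fall in
#' the window.
#'
#' @param genome a named [Biostrings::DNAStringSet] (the reference).
#' @param elements a `GRangesList` from [resolveElements()].
#' @param sites a site table (or polarized SNP table) with columns `chrom`,
#'   `pos`, `n` and `count_y` or `k`.
#' @param rateMap optional `GRanges` with `rho_per_kb`.
#' @param outgroup optional aligned outgroup `DNAStringSet` (same
#'   coordinates as `genome`).
#' @param mask optional `GRanges` of outgroup-covered regions; divergence is
#'   computed over masked-in bases only.
#' @param windowSize window width (default 100 kb).
#' @param minCovered minimum element bases per window to report statistics
#'   (default 200).
#' @param minLastFrac passed to [genomeWindows()].
#' @return a `data.frame`, one row per window x element (element "all" =
#'   whole window).
#' @export
windowStats <- function(genome, elements, sites, rateMap = NULL,
                        outgroup = NULL, mask = NULL, windowSize = 1e5,
                        minCovered = 200L, minLastFrac = 0.5) {
    seqlengths <- stats::setNames(Biostrings::width(genome), names(genome))
    wins <- genomeWindows(seqlengths, windowSize, minLastFrac)
    kcol <- if ("k" %in% names(sites)) sites$k else sites$count_y
    n <- if (nrow(sites)) sites$n[1L] else 2L
    siteGr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
    allGrl <- c(elements, GRangesList(
        all = GRanges(names(seqlengths), IRanges(1L, unname(seqlengths)))))

    ## pre-assign sites to element types
    siteElt <- rep(NA_character_, length(siteGr))
    for (t in names(elements)) {
        hit <- overlapsAny(siteGr, elements[[t]])
        siteElt[hit & is.na(siteElt)] <- t
    }

    maskGr <- mask
    rows <- list()
    for (wi in seq_along(wins)) {
        win <- wins[wi]
        rhoWin <- if (!is.null(rateMap)) aggregateRho(rateMap, win) else NA_real_
        for (t in names(allGrl)) {
            segs <- intersect(allGrl[[t]], win, ignore.strand = TRUE)
            covered <- sum(width(segs))
            inWin <- overlapsAny(siteGr, win) &
                (if (t == "all") TRUE else siteElt == t & !is.na(siteElt))
            S <- sum(inWin, na.rm = TRUE)
            if (covered < minCovered) {
                rows[[length(rows) + 1L]] <- data.frame(
                    chrom = as.character(seqnames(win)),
                    start = start(win) - 1L, end = end(win), element = t,
                    covered_bases = covered, S = S, theta_w = NA_real_,
                    pi = NA_real_, tajimas_d = NA_real_, gc = NA_real_,
                    cpg_oe = NA_real_, divergence = NA_real_,
                    diversity_over_divergence = NA_real_,
                    rho_mean = NA_real_, stringsAsFactors = FALSE)
                next
            }
            kk <- kcol[which(inWin)]
            theta <- wattersonTheta(S, n, covered)
            pb <- nucleotideDiversity(kk, n, covered)
            D <- tajimasD(S, pb * covered, n)
            seqs <- Biostrings::extractAt(
                genome[[as.character(seqnames(win))]], ranges(segs))
            comp <- .fragmentComposition(seqs)
            gc <- if (comp["L"] > 0) unname(comp["GC"] / comp["L"]) else NA_real_
            oe <- .oeFromComposition(comp)
            div <- NA_real_
            if (!is.null(outgroup)) {
                dsegs <- segs
                if (!is.null(maskGr))
                    dsegs <- intersect(dsegs, maskGr, ignore.strand = TRUE)
                if (sum(width(dsegs)) > 0) {
                    ch <- as.character(seqnames(win))
                    aa <- paste(as.character(Biostrings::extractAt(
                        genome[[ch]], ranges(dsegs))), collapse = "")
                    bb <- paste(as.character(Biostrings::extractAt(
                        outgroup[[ch]], ranges(dsegs))), collapse = "")
                    div <- divergenceRate(aa, bb)$divergence
                }
            }
            rhoElt <- if (!is.null(rateMap) && length(segs))
                sum(aggregateRho(rateMap, segs) * width(segs), na.rm = TRUE) /
                    sum(width(segs)) else rhoWin
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = as.character(seqnames(win)),
                start = start(win) - 1L, end = end(win), element = t,
                covered_bases = covered, S = S, theta_w = theta, pi = pb,
                tajimas_d = D, gc = gc, cpg_oe = oe, divergence = div,
                diversity_over_divergence =
                    if (is.na(div) || div == 0) NA_real_ else theta / div,
                rho_mean = if (t == "all") rhoWin else rhoElt,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}
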