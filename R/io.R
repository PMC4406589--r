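## I/O boundaries: VCF + FASTA + BED + GFF3 in, TSV out. Coordinates in all
## emitted files are 1-based (VCF/GFF) or 0-based half-open (BED), matching
## the formats' conventions.

#' Write a simulated dataset to standard files
#'
#' Emits the generator's products as reference FASTA, outgroup FASTA, GFF3
#' annotation, VCF (diploid genotypes reconstituted from the haploid derived
#' counts), outgroup coverage BED, truth TSVs and a manifest.
#'
#' @param genomeSim [simulateGenome()] output.
#' @param snpSim [simulateSnps()] output.
#' @param dir output directory (created if needed).
#' @param geneTables optional [simulateGeneTables()] output: adds expression
#'   list TSVs and an mCpG BED.
#' @param seed seed for the haplotype assignment of derived alleles to
#'   diploid genotypes.
#' @return invisibly, a named character vector of the files written.
#' @export
writeSimOutputs <- function(genomeSim, snpSim, dir, geneTables = NULL,
                            seed = 1L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    f <- function(x) file.path(dir, x)
    files <- c(reference = f("reference.fa"), outgroup = f("outgroup.fa"),
               annotation = f("annotation.gff3"), vcf = f("snps.vcf"),
               mask = f("outgroup_mask.bed"), truth = f("snp_truth.tsv"),
               gene_truth = f("gene_truth.tsv"))
    Biostrings::writeXStringSet(genomeSim$genome, files["reference"])
    Biostrings::writeXStringSet(snpSim$outgroup, files["outgroup"])
    rtracklayer::export(genomeSim$annotation, files["annotation"],
                        format = "gff3")
    rtracklayer::export(snpSim$mask, files["mask"], format = "bed")
    .writeVcf(snpSim$sites, genomeSim$genome, files["vcf"], seed = seed)
    utils::write.table(snpSim$truth, files["truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(genomeSim$geneTruth, files["gene_truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(geneTables)) {
        for (nm in names(geneTables$qw)) {
            p <- f(sprintf("expr_qw_%s.txt", nm))
            writeLines(geneTables$qw[[nm]], p)
            files[paste0("qw_", nm)] <- p
        }
        for (nm in names(geneTables$dw)) {
            p <- f(sprintf("expr_dw_%s.txt", nm))
            writeLines(geneTables$dw[[nm]], p)
            files[paste0("dw_", nm)] <- p
        }
        rtracklayer::export(geneTables$mcpg, f("mcpg.bed"), format = "bed")
        files["mcpg"] <- f("mcpg.bed")
    }
    manifest <- f("MANIFEST.txt")
    writeLines(sprintf("%s\t%s", names(files), basename(files)), manifest)
    files["manifest"] <- manifest
    invisible(files)
}

## Fixed-format VCF emission for the simulator: REF is the (ancestral)
## reference base, ALT the derived allele, and the k derived copies are
## scattered over n haplotypes paired into n/2 diploid genotypes.
.writeVcf <- function(sites, genome, path, seed = 1L) {
    n <- sites$n[1L]
    nSamples <- n %/% 2L
    samples <- sprintf("BEE%02d", seq_len(nSamples))
    withSeed(seed, {
        gtRows <- vapply(seq_len(nrow(sites)), function(j) {
            hap <- integer(n)
            hap[sample.int(n, sites$count_y[j])] <- 1L
            paste(paste0(hap[seq(1L, n, 2L)], "|", hap[seq(2L, n, 2L)]),
                  collapse = "\t")
        }, character(1))
    })
    hdr <- c("##fileformat=VCFv4.2",
        "##source=beeGBGC-simulator",
        sprintf("##contig=<ID=%s,length=%d>", names(genome),
                Biostrings::width(genome)),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t"))
    body <- paste(sites$chrom, sites$pos, ".", sites$allele_x,
                  sites$allele_y, ".", "PASS", ".", "GT", gtRows,
                  sep = "\t")
    writeLines(c(hdr, body), path)
}

#' Read a site table from VCF, reference, outgroup and coverage mask
#'
#' Imports biallelic SNVs from a VCF (multi-allelic and indel records are
#' skipped and counted, not errors), sums derived copies over the diploid
#' genotypes, looks up the outgroup consensus allele and flanking reference
#' bases, and assigns the outgroup depth from the coverage mask (masked-in
#' sites carry the mask's depth floor, masked-out sites 0).
#'
#' @param vcfPath path to a VCF file.
#' @param referencePath path to the reference FASTA (or a `DNAStringSet`).
#' @param outgroupPath path to the outgroup consensus FASTA (or a
#'   `DNAStringSet`); `NULL` leaves the outgroup columns missing.
#' @param maskPath path to the outgroup coverage BED (or a `GRanges`);
#'   `NULL` marks all outgroup calls as covered.
#' @param maskDepth depth recorded for masked-in sites (default 5, the
#'   consensus coverage floor used to build such masks).
#' @return a [siteTable()] `data.frame`; attribute `skipped` counts records
#'   dropped per reason.
#' @export
readSiteAlleles <- function(vcfPath, referencePath, outgroupPath = NULL,
                            maskPath = NULL, maskDepth = 5L) {
    vcf <- VariantAnnotation::readVcf(vcfPath)
    ref <- if (is(referencePath, "DNAStringSet")) referencePath
           else Biostrings::readDNAStringSet(referencePath)
    names(ref) <- sub("\\s.*", "", names(ref))
    og <- if (is.null(outgroupPath)) NULL
          else if (is(outgroupPath, "DNAStringSet")) outgroupPath
          else Biostrings::readDNAStringSet(outgroupPath)
    if (!is.null(og)) names(og) <- sub("\\s.*", "", names(og))
    mask <- if (is.null(maskPath)) NULL
            else if (is(maskPath, "GRanges")) maskPath
            else rtracklayer::import(maskPath)

    rr <- SummarizedExperiment::rowRanges(vcf)
    refAl <- as.character(rr$REF)
    altList <- rr$ALT
    nAlt <- S4Vectors::elementNROWS(altList)
    altFirst <- rep(NA_character_, length(rr))
    altFirst[nAlt >= 1L] <- as.character(unlist(altList))[
        cumsum(nAlt)[nAlt >= 1L] - nAlt[nAlt >= 1L] + 1L]
    isSnv <- nAlt == 1L & nchar(refAl) == 1L & !is.na(altFirst) &
        nchar(altFirst) == 1L & refAl %in% BASES & altFirst %in% BASES
    skipped <- c(multiallelic = sum(nAlt > 1L),
                 indel_or_other = sum(nAlt <= 1L & !isSnv[nAlt <= 1L]))

    gt <- VariantAnnotation::geno(vcf)$GT[isSnv, , drop = FALSE]
    countAlt <- function(g) {
        a <- substr(g, 1L, 1L); b <- substr(g, 3L, 3L)
        (a == "1") + (b == "1")
    }
    cy <- rowSums(apply(gt, 2L, countAlt))
    n <- 2L * ncol(gt)
    gr <- rr[isSnv]
    chrom <- as.character(seqnames(gr)); pos <- start(gr)
    seg <- cy > 0 & cy < n
    skipped["not_segregating"] <- sum(!seg)
    chrom <- chrom[seg]; pos <- pos[seg]; cy <- cy[seg]
    refAl <- refAl[isSnv][seg]; altAl <- altFirst[isSnv][seg]

    atBase <- function(seqs, ch, p) {
        out <- rep(NA_character_, length(p))
        for (c2 in unique(ch)) {
            sel <- which(ch == c2 & !is.na(p) & p >= 1L &
                         p <= length(seqs[[c2]]))
            if (length(sel))
                out[sel] <- as.character(Biostrings::extractAt(
                    seqs[[c2]], IRanges(p[sel], width = 1L)))
        }
        out
    }
    leftB <- atBase(ref, chrom, pos - 1L)
    rightB <- atBase(ref, chrom, pos + 1L)
    ogAl <- if (!is.null(og)) atBase(og, chrom, pos) else NA_character_
    ogAl[!is.na(ogAl) & !(ogAl %in% BASES)] <- NA_character_
    depth <- if (is.null(mask)) rep(maskDepth, length(pos)) else {
        inM <- overlapsAny(GRanges(chrom, IRanges(pos, width = 1L)), mask)
        ifelse(inM, maskDepth, 0L)
    }
    st <- siteTable(chrom, pos, refAl, altAl, cy, n = n,
                    outgroupAllele = ogAl, outgroupDepth = depth,
                    leftBase = leftB, rightBase = rightB)
    attr(st, "skipped") <- skipped
    st
}

#' Write polarized SNPs (and unresolved sites) as TSV
#'
#' @param polarized the list returned by [polarizeSites()].
#' @param path output TSV for the polarized table; unresolved sites go to
#'   `<path>.unresolved.tsv` with their reason codes.
#' @return invisibly, the paths written.
#' @export
writePolarizedTable <- function(polarized, path) {
    utils::write.table(polarized$snps, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    up <- paste0(path, ".unresolved.tsv")
    utils::write.table(polarized$unresolved, up, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(path, up))
}
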