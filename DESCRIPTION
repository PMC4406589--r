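Package: beeGBGC
Title: GC-Biased Gene Conversion and Recombination Landscape Analysis for
    Honeybee Population Genomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying GC-biased gene conversion (gBGC) and the
    recombination landscape from population resequencing data, developed
    around the haplodiploid honeybee system. Implements outgroup-based SNP
    polarization by substitution-aware weighted parsimony, mutation-class
    (weak/strong) and dinucleotide-context classification, windowed
    population-genetic statistics (Watterson's theta, pi, Tajima's D, GC,
    CpG observed/expected, divergence, mean population recombination rate),
    maximum-likelihood estimation of the population-scaled conversion
    coefficient B and the AT mutational bias lambda from class-specific
    derived allele frequency spectra (with nuisance spectrum-distortion and
    polarization-error parameters), gene-level CpG/expression/methylation
    class comparisons, and a fully seeded synthetic-data generator emitting
    FASTA, GFF3, VCF, BED and truth tables so that every stage of the
    pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: PopulationGenetics, Genetics, SNP, Sequencing, Software
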