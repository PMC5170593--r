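Package: variome
Title: Resequencing Variome Construction: Read QC, Variant Filtering,
    Effect Annotation and Marker Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a population variome from paired-end resequencing
    data the way crop diversity studies do: paired-end FASTQ quality
    filtering (N-fraction, mean-quality, 3' quality trimming with a
    length floor, duplicate removal), allele-depth based variant
    filtering (alternative-read candidacy, confident-allele depth,
    depth-ratio zygosity classification, homozygous-line retention,
    population minor-allele-frequency filtering), gene-model-aware
    functional annotation of SNPs and InDels (synonymous and
    non-synonymous, frameshift and non-frameshift, splice-window,
    intron, UTR, intergenic), per-morphotype polymorphism summaries,
    windowed genome tracks and InDel length distributions, and in
    silico screening of SNP sites for KASP assay design. Ships a
    synthetic-data generator that emits a toy multi-chromosome genome,
    gene models, a structured accession population, reads and
    allele-depth tables together with a ground-truth manifest, so the
    whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
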