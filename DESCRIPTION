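Package: macdiv
Title: Comparative Genome-Wide SNV Characterization Across Related Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative characterization of single nucleotide
    variants (SNVs) called against one shared reference genome across a panel
    of related individuals or species. Implements multi-sample site merging
    and conservative site filtering (missing genotypes, triallelic sites,
    duplication masks, CpG context, variant proximity), exact carrier-set
    sharing counts and species/population-specific SNV identification with
    outgroup exclusion, per-sample diversity summaries (heterozygosity,
    Ti/Tv, mutation and codon spectra), codon-level functional effect
    annotation from gene models, non-overlapping sliding-window scans of
    nonsynonymous SNV density with a Cook's-distance influence rule for
    outlier window detection, and hypergeometric gene-set over-representation
    with Benjamini-Hochberg correction. A tree-based synthetic-data generator
    produces complete toy datasets (FASTA, GFF3, VCF, BED, truth tables) with
    clade-structured allele sharing for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), methods
Imports:
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, VariantAnnotation, Sequencing, Annotation
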