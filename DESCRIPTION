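Package: ssrmine
Title: Genome-Wide Microsatellite Mining, Regional Distribution Statistics
    and Marker Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects perfect mono- to hexanucleotide microsatellites (SSRs)
    in genome sequences, groups repeat motifs into canonical classes by
    circular permutation and reverse complement, partitions a genome into
    5'UTR/CDS/intron/3'UTR/intergenic regions (with a transposable-element
    overlay) from GFF3 and BED annotation, and computes the survey
    statistics used in genome-wide SSR characterization studies: counts,
    relative abundance (loci per Mb), GC content, repeat-copy-number
    distributions and their coefficient of variation. Also screens
    tetranucleotide loci for marker development (flank extraction and
    filtering), computes per-locus population-genetic diversity statistics
    (observed and expected heterozygosity, polymorphism information
    content, rarefaction-based allelic richness, Hardy-Weinberg exact
    tests) from co-dominant genotype tables, and ships simulators for
    genomes with planted repeats and for genotypes drawn under
    Hardy-Weinberg equilibrium so every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
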