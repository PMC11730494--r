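Package: famcascade
Title: Family-Based Rare-Variant Co-Segregation Filtering, IBD Intersection,
    and Single-Point Parametric Linkage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for prioritising candidate disease variants in a single
    extended family: co-segregation filtering of a multi-sample VCF under
    dominant (heterozygous-shared) and recessive (homozygous-shared) patterns,
    a five-step rare-damaging-variant cascade (FILTER status and protein
    consequence, gnomAD and cohort allele frequency, CADD phred score,
    identity-by-descent overlap) with a per-step survivor ledger, reading and
    multi-way intersection of Beagle-style IBD segments, single-point
    parametric linkage LOD scores via exact Elston-Stewart peeling of
    two-locus pedigree likelihoods under a configurable penetrance model,
    coding-position codon arithmetic with APOE epsilon-haplotype calling, and
    a gene-dropping simulator that generates fully cross-consistent synthetic
    pedigrees, genotypes, annotations and truth IBD tracts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
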