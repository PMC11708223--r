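Package: kaspforge
Title: Degenerate-Base KASP Marker Design, Selection and Validation Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs Kompetitive Allele-Specific PCR (KASP) genotyping assays
    from a panel of resequenced genomes compared against a reference assembly.
    Candidate SNP and InDel target variants are passed through a sequential
    filter cascade (rare-allele and polymorphism rules, fractional read-depth
    coverage at the target and across both 50 bp flanks, flanking-variation
    admissibility), flanking polymorphism is encoded with IUPAC degenerate
    bases and N-runs, and designs are screened for short tandem repeats,
    unique placement in one or more reference assemblies, and GC content.
    Target variants are annotated for predicted functional effect against
    GFF3 gene models, trait-targeted marker panels are selected under
    per-locus and global quotas, and genotyping runs are analysed for call
    rate, concordance with design-time predictions, population structure via
    hierarchical clustering, and design-property associations with assay
    success. A fully seeded synthetic-data generator with analytic ground
    truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
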