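Package: bsamap
Title: Bulked Segregant Analysis and Recombinant Mapping of Plant Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes causal plant mutations from pooled whole-genome
    sequencing and individual-plant marker genotypes. Implements per-site
    marker-index and delta-index statistics with read-support filtering, the
    G statistic for pooled allele counts, sliding-window genome scans with
    threshold-based candidate region calls, screening of gel-resolvable
    InDel markers, recombinant-based interval narrowing for both homozygous
    (F2) and heterozygous (backcross F1) mapping designs, candidate-variant
    extraction with exon annotation and coverage-gap scanning for large
    deletions, Mendelian segregation tests, and a forward simulator of
    crossing schemes with phenotype selection and pooled read sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
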