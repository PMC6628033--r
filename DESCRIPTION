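Package: bsascan
Title: Bulked Segregant Analysis with SNP-Index Scans and Simulated Null Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping recessive mutations from bulked segregant
    whole-genome resequencing of F2 populations. Computes per-site SNP-indices
    from pooled allele depths, applies a dual-pool extremeness filter, averages
    indices in sliding genomic windows to form delta SNP-index profiles, and
    calls candidate regions against Monte-Carlo confidence thresholds simulated
    under the null hypothesis of no segregating locus. Includes a seeded F2
    bulk-sequencing simulator (Poisson crossovers, phenotype-selected bulks,
    binomial read sampling), codon-level annotation of candidate SNPs
    (synonymous, missense, nonsense, stop-loss), Mendelian segregation tests,
    and spectrophotometric pigment quantification with derived carotenoid and
    chlorophyll summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    Biostrings,
    rtracklayer,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
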