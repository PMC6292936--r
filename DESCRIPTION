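Package: skimeval
Title: Design and Evaluation of Skim Whole-Genome Resequencing Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to plan and audit genotyping by low-coverage ("skim")
    whole-genome resequencing. Simulates genotype truth and read sampling for
    diversity panels, four-parent crosses and doubled haploids under a Poisson
    coverage / binomial allele-sampling model; thins read depths or FASTQ
    files to target coverages; calls genotypes from allele counts in
    list-based or de novo mode; applies depth, missing-data, minor-allele
    frequency, heterozygosity and triallelic filters; and summarises genotype
    concordance against a deeply sequenced reference, cumulative
    missing-data accuracy, per-chromosome marker density, per-individual
    genotype yields and the sequencing cost trade-off between coverage and
    sample number.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    Biostrings,
    S4Vectors
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
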