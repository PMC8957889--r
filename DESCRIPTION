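Package: rohscape
Title: Runs-of-Homozygosity Landscapes, Inbreeding and Selection Signatures from SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of runs of homozygosity (ROH) in
    diploid SNP-array genotypes, and the population-genetic statistics built on
    them. Provides readers and writers for PED/MAP, VCF and BED interval files;
    quality-control filters (call rate, exact Hardy-Weinberg test, MAF); a
    sliding-window ROH caller with a false-positive-controlled minimum-SNP
    threshold; genomic inbreeding coefficients (F_ROH by length class and the
    excess-homozygosity F_HOM); ROH hotspot and coldspot landscape calling with
    interval flanking and overlap reporting; windowed nucleotide diversity,
    Tajima's D and Weir-Cockerham FST; linkage-disequilibrium-based effective
    population size; derived-allele frequencies and a single-SNP additive
    linear association model with covariates. A seeded synthetic-data generator
    plants ground-truth autozygous tracts, population divergence and phenotype
    effects so that every stage of the pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
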