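Package: CNPed
Title: Partitioning of Copy-Number Genotypes in Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts integrated copy-number genotype calls of the form
    [a,b] (copies of SNP allele A and allele B summed over both
    chromosomes) into chromosome-partitioned copy-number genotypes
    [T1m,T2n] using Mendelian transmission within families. Homozygous
    calls are resolved from heterozygous first-degree relatives and,
    failing that, from a sequential set of nuclear-family rules applied
    to a fixpoint. The package also provides linkage-format pedigree and
    genotype-matrix readers and writers, multi-allelic recoding of
    partitioned genotypes for linkage software, a nuclear-family
    Mendelian consistency checker, and a gene-dropping simulator with
    masking and error injection used to validate the partitioning engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
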