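Package: ssrpop
Title: SSR Population Genetics and Core Collection Construction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of codominant microsatellite (SSR) genotype data:
    per-locus and per-population diversity statistics (Na, Ne, Shannon I,
    Ho, He, PIC), Wright's F-statistics and gene flow, three-level analysis
    of molecular variance (AMOVA), Nei (1972) genetic distances with UPGMA
    dendrograms and principal coordinate analysis, admixture-model
    population structure via Gibbs sampling with the Evanno delta-K model
    choice, and stepwise expected-heterozygosity core collection
    construction. Includes a Balding-Nichols simulator of structured
    diploid populations, readers and writers for GenAlEx-dialect CSV and
    STRUCTURE two-row genotype files, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
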