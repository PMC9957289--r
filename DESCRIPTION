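Package: photocline
Title: Photoperiod-Temperature Clines in Candidate-Gene Allele Frequencies
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether allele frequencies at a sequenced
    gene fragment follow geographic clines in seasonality. Derives a
    predicted critical photoperiod (pCPP) per sampling locality from the
    annual photoperiod-temperature trajectory (civil-twilight day length
    crossed with interpolated monthly temperatures at a fixed threshold),
    calls SNPs from a multi-specimen consensus alignment with IUPAC
    heterozygote codes using a minimum-carrier rule, classifies variants
    by region and coding effect, and summarises population structure via
    multilocus Nei G_ST, composite linkage disequilibrium, and
    neighbor-joining trees. Gene-environment association uses pairwise
    Pearson correlation of allele-frequency differences against
    differences in geographic distance, latitude, longitude, altitude and
    pCPP, with Benjamini-Hochberg adjustment. Includes a seeded synthetic
    data generator with planted pCPP clines for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    ape,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
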