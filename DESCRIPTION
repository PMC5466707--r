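Package: binmapper
Title: Recombination Bin Maps, Assembly Correction and QTL Scans for
    Biparental RIL Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of low-coverage resequencing data from a
    two-parent recombinant inbred line (RIL) population: sliding-window
    genotype calling from noisy per-SNP parental-origin observations,
    recombination breakpoint detection, construction of a recombination bin
    map and a Kosambi genetic linkage map, genetic-map-guided scaffold
    anchoring and assembly error correction, gap filling from a donor
    assembly by dual-flank matching, and per-bin likelihood-ratio mapping
    of qualitative and quantitative traits. Includes a seeded simulator of
    RIL populations (selfing with per-meiosis crossovers), low-coverage
    observations, phenotypes, and fragmented assemblies so every stage is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
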