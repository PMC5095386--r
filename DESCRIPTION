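Package: coscape
Title: Crossover Landscape Analysis for Selfed F2 Sequencing Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects meiotic crossovers in selfed F2 progeny of a
    heterozygous F1 from multi-sample variant calls, and characterises the
    resulting recombination landscape. Provides allele-balance genotype
    classification and confident-marker filtering with structural-variant
    masking, seed-and-extend genotype-block segmentation with parent-free
    phasing of intraspecific crosses, crossover localisation, Monte-Carlo
    hotspot and coldspot detection in fixed windows, crossover-mutation
    coupling tests, windowed population pairwise diversity, and a synthetic
    selfed-F2 cross simulator that supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    jsonlite,
    vcfR,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
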