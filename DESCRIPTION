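Package: ploidyscope
Title: Nuclear Ploidy Typing, Inheritance Inference and Variant
    Filtering for Cardiomyocyte Polyploidy Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Intensity-based nuclear ploidy classification for
    single-cell suspension micrographs, normalised to a CD31-positive
    endothelial diploid standard; nucleation-by-nuclear-ploidy
    composition calculus for cardiomyocytes, hepatocytes and marrow
    cells; Mendelian mode-of-inheritance inference from reciprocal F1
    crosses with exhaustive single-locus model enumeration;
    marker-selected backcross genome simulation under a Haldane
    crossover model; and a substrain-private X-linked coding variant
    filter for multi-strain exome call sets. Ships a synthetic-data
    generator (cell populations, rendered multi-channel frames, VCF
    panels with planted ground truth) so the whole pipeline is testable
    without animal-derived data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    tiff,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
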