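Package: phosmark
Title: Multi-Omic Discovery of Acquired-Resistance Phosphosite Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for identifying phosphosite markers of acquired drug
    resistance from SILAC (stable isotope labeling by amino acids in cell
    culture) phosphoproteomics time courses with label-swapped channel
    assignments, and for integrating them with treatment-independent
    differentially expressed genes. Implements class-1 localization
    filtering, channel-orientation resolution, signed fold-change
    transformation, set-algebra classification of resistance-associated
    regulation across four biological contrasts, temporal-overlap
    aggregation, two-group differential expression with
    Benjamini-Hochberg false discovery rate control, hypergeometric
    gene-set enrichment, and export of an annotated multi-omic network.
    Ships a synthetic-data generator with ground-truth labels so the
    whole pipeline is testable without access to deposited raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
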