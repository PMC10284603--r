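Package: ailqtl
Title: QTL Interval Mapping and Variant Prioritisation for Advanced Intercross Lines
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trait locus (QTL) analysis in advanced
    intercross lines (AILs) bred from two inbred strains. Implements maximum
    likelihood interval mapping for quantitative traits (EM on the three
    component Gaussian mixture) and liability-type binary traits (logistic
    likelihood-ratio scans) with AIL-expanded recombination fractions, 1-LOD
    support intervals, fixed-term resolution of linked peaks and additive /
    dominance effect estimation. Adds the surrounding pipeline of an AIL
    study design: a gamete-level breeding-scheme simulator for testing,
    strain-difference variant filtering, variant-density genome segmentation
    and QTL narrowing, permutation tests for gene-network statistics, and
    interval-shuffle nulls for variant enrichment in genomic features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'sim-pedigree.R'
    'sim-genotypes.R'
    'sim-phenotypes.R'
    'sim-fixtures.R'
    'linkage-probs.R'
    'linkage-scan.R'
    'linkage-peaks.R'
    'variants.R'
    'network.R'
    'features.R'
    'io.R'
    'pipeline.R'
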