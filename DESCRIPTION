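Package: coalscan
Title: Introgression Inference from Genome-Window Topologies and Site Patterns
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing introgression from incomplete lineage
    sorting in clades of closely related species. Implements Patterson's D
    (ABBA-BABA) over all species-tree-compatible triads with block-jackknife
    significance, ancestry-informative-marker discovery and F1/backcross
    hybrid classification, rooted four-taxon gene-tree frequency scanning
    with megabase and telomere-scaled chromosome binning, window sampling
    with alignment-completeness filtering, and window/site concordance
    factors. A built-in multispecies-coalescent simulator with directional
    introgression pulses and a telomere-weighted retention landscape
    generates test data end-to-end, so the whole pipeline runs without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
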