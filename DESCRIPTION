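Package: spliceith
Title: Spliceomic Intratumor Heterogeneity from Splice-Junction Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies spliceomic intratumor heterogeneity (sITH) from
    splice-junction read counts. Junctions are grouped into intronic
    splicing units (connected sets of junctions sharing a donor or
    acceptor coordinate), per-unit splice-site usage distributions are
    compared between a tumor sample and one or more normal references
    with the base-2 Jensen-Shannon divergence, and the mean divergence
    over units is reported as the sITH score. Includes Shannon-entropy
    heterogeneity measures over isoform fractions and junction usage,
    readers for STAR SJ.out.tab and a generic junction TSV, a synthetic
    junction-profile generator with single-cell-into-normal mixture
    synthesis, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
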