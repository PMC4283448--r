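Package: oligoscope
Title: Sub-OTU Oligotyping and Microdiversity Ecology for Amplicon Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes per-OTU 16S rRNA amplicon alignments into oligotypes by
    recursive selection of maximum Shannon-entropy alignment positions, screens
    oligotype occurrence matrices for checkerboard and togetherness (aggregation)
    patterns, relates oligotype abundances to environmental and spatial gradients
    with redundancy analysis under forward selection, and builds permutation-tested
    co-occurrence networks from Whittaker's index of association partitioned with
    Markov clustering. Includes a synthetic community generator that emulates a
    two-transect deep-sea sediment sampling design with planted sub-populations
    and per-base sequencing error, providing ground truth for parameter-recovery
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    igraph,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
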