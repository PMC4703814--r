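Package: masdiv
Title: Marker-Gene Diversity Analysis for Anaerobic Alkane Degraders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of MasD (alkylsuccinate synthase alpha
    subunit) functional-gene amplicon surveys: simulation of barcoded
    pyrosequencing-style amplicon reads with known ground truth, read-level
    quality control with a simplified de novo chimera screen, translation and
    motif-based ORF screening against a reference panel, calibration of
    protein OTU identity thresholds from paired 16S rRNA / marker-protein
    strain sequences, distance-based OTU clustering, per-site diversity
    statistics (singleton taxonomy, Good's coverage, inverse Simpson,
    rarefaction, subsampling, occupancy classes), and between-site community
    structure (Bray-Curtis, NMDS, Ward clustering, co-occurrence,
    force-directed presence-absence network).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vegan,
    igraph,
    ape,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite
Config/testthat/edition: 3
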