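Package: elytramorph
Title: Quantification of Sexually Dimorphic Elytral Spot Patterns and
    Dsx-Motif Content of Open Chromatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for sexually dimorphic black spot patterns
    on ladybird beetle (Harmonia axyridis) elytra. Segments black spots from
    RGB elytron images (median smoothing, Otsu thresholding, morphological
    contour smoothing), aligns wings by centroid and principal axes, builds an
    average ten-spot template, splits fused spots with a template-constrained
    marker-based watershed, and measures per-spot areas normalized to total
    elytral area. Sex and RNAi-treatment differences are tested with the
    Brunner-Munzel rank test with Holm correction, and categorical scores with
    Fisher's exact test. A regulatory-genomics stage scans Doublesex-binding
    motifs (position-specific scoring matrix, log-likelihood ratio scores) in
    open-chromatin peak intervals and tabulates the with- versus without-motif
    peak ratio across color-pattern alleles, fraction of reads in peaks,
    conservation classes, and sex-sharing of peaks. Includes a ground-truthed
    synthetic data generator for elytron images and motif-planted genomes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
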