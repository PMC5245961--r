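Package: oriseq
Title: Replication-Origin Mapping from Nascent-Strand Sequencing and DNA
    Combing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping and characterising human DNA replication
    origins. Implements a fixed-window origin caller for
    BrdU-immunoprecipitated nascent-strand sequencing (BrIP-seq) against a
    genomic control, with a two-fold enrichment filter and a
    mean-plus-3-SD read threshold; 3' poly-T read trimming;
    origin-landscape statistics (inter-origin distances, peak-set overlap,
    distance to transcription start sites, Wilcoxon rank-sum comparisons);
    dual-pulse (CldU/IdU) molecular-combing analytics for fork progression
    rate and single-molecule inter-origin distance; quantitative-western
    licensing arithmetic (molecules per cell, detection-limit bounds,
    genome-wide origin numbers); and a seeded synthetic-data generator
    with planted ground truth so the whole pipeline can be exercised end
    to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
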