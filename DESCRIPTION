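Package: morphoscreen
Title: Single-Cell Morphological Profiling and Screen Statistics for
    High-Content Imaging of Cell Shape and YAP/TAZ Translocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, synthetic-testable implementation of a
    multiplexed high-content screening analysis linking RhoGEF/GAP
    perturbations to cell-shape signatures and YAP/TAZ nuclear
    translocation. Provides nuclear/cytoplasm segmentation and subcellular
    region measurement, a five-class linear shape classifier with a
    PCA-based "normal cell" penetrance filter, per-plate normalisation and
    mock-referenced Z-scoring into quantitative morphological signatures
    (QMS), hierarchical phenoclustering by uncentered Pearson correlation,
    a 3D collagen invasion index, focal-adhesion tracking with
    assembly/disassembly rate fitting and estimation statistics (Hedges' g
    with BCa bootstrap intervals), wound-heal Golgi polarity angles, and
    SAM-style permutation-FDR differential proteomics. A synthetic-data
    module generates plates, movies, z-stacks and abundance tables with
    known ground truth so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    nnet,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
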