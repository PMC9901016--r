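Package: ssctrace
Title: Clonal Lineage Tracing and Spatial Mapping of Skeletal Stem Cell Hierarchies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing differentiation hierarchies of sorted
    skeletal stem cell (SSC) populations from somatic mitochondrial DNA
    heteroplasmy, and for mapping the spatial organisation of marker-defined
    cell types in multiplexed tissue images. Includes a synthetic-data
    generator that emulates mutator-mouse mtDNA clonal drift along a
    differentiation tree with bulk mitochondrial capture sequencing,
    log-normal flow-cytometry marker mixtures, and spatially structured
    multi-channel images with ground truth; variant filtering and
    unsupervised clustering of allele-frequency profiles; a transmission
    consistency score for candidate hierarchies with a permutation null;
    nuclear-seeded watershed segmentation, marker gating and nearest-neighbour
    enrichment statistics for imaging data; and hierarchical gating of
    flow-cytometry event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
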