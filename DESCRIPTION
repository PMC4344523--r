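Package: halofish
Title: Simulation and Quantitative Analysis of Halo-FISH Images of
    Extrachromosomal Telomere-Repeat DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify extrachromosomal telomere-repeat (ECTR) DNA
    in single deproteinized nuclei imaged by Halo-FISH, a FISH-based agarose
    gel assay in which extrachromosomal DNA diffuses out of the intensely
    DAPI-stained nuclear core into a surrounding Halo. The package provides
    a forward simulator of 4-channel widefield z-stacks (DAPI, centromere,
    C-strand and G-strand telomere probes) with full ground truth,
    Richardson-Lucy deconvolution, DAPI-based core/Halo segmentation, 3D
    spot detection with watershed intensity integration, plasmid-standard
    quantitative-FISH calibration of integrated intensity to base pairs,
    object-based G/C colocalization, per-nucleus ECTR metrics (counts,
    lengths, strand biases, chromosomal versus extrachromosomal
    partitioning), centromere-based cell-cycle binning, and a command-line
    pipeline with CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
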