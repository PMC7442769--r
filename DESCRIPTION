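Package: HCPprofiler
Title: Host Cell Protein Discovery and Profiling for Biotherapeutic Drug Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Optimized data evaluation for host cell protein (HCP) discovery
    in bottom-up LC-MS/MS analyses of biotherapeutic drug products.
    Implements shared-peptide protein inference under a two-dimensional
    target-decoy false discovery rate, rescue of peptides on the full-scan
    MS level ("in silico peptides") via retention-time windows, mass
    deviation percentile filters and averagine isotope-envelope correlation,
    credibility-tiered HCP profiles, top-3 relative quantification, and
    Jaccard-index based profile comparison and hierarchical clustering.
    Ships a ground-truth synthetic data generator emulating replicate
    bottom-up proteomics measurements for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    data.table,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'HCPprofiler-package.R'
    'averagine.R'
    'formats.R'
    'digest.R'
    'profiling.R'
    'compare.R'
    'inference.R'
    'rescue.R'
    'pipeline.R'
    'synthetic.R'
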