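Package: granulekit
Title: Quantification of Cytoplasmic Protein Granules in Fluorescence
    Microscopy, FRAP, and Densitometry
Version: 0.1.0
Authors@R:
    person("Granulekit", "Developers", email = "granulekit@example.org",
           role = c("aut", "cre"))
Description: A reusable, tested pipeline for quantifying membraneless
    cytoplasmic protein granules (biomolecular condensates) formed by
    receptor tyrosine kinase fusion oncoproteins. Provides illumination
    and autofluorescence correction, Otsu-threshold granule detection
    with a physical size gate, object-based two-channel colocalization
    by centroid distance, per-granule fold-enrichment scoring, cell-level
    phenotype statistics, FRAP recovery normalization and mobile-fraction
    estimation, western-blot densitometry normalizations, and the
    associated inferential statistics (t tests, one-way ANOVA with Tukey
    HSD, SEM).  A synthetic-data module generates field images, FRAP
    traces, and densitometry tables with exact ground truth so that every
    stage is verifiable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
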