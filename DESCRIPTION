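Package: poolgwas
Title: Design and Variance Decomposition for DNA-Pooling Genome-Wide
    Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for planning and analysing pool-based genome-wide
    association studies. Estimates SNP allele frequencies from bead-level
    two-channel array intensities (allelotyping), normalizes arrays
    strip-by-strip, and decomposes the variance of pooled allele-frequency
    estimates into array and pool-construction components using paired-array
    comparisons of replicate arrays, replicate pools, and independent pools.
    Variance estimates are translated into relative and effective sample
    sizes as a function of replicate arrays, planning tables, optimal array
    allocation between pools, cost summaries, and approximate case-control
    power and minimum detectable odds ratios. A synthetic-data generator
    with known ground truth supports validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
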