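Package: petqc
Title: Quality Assessment of Long-Range Chromatin Interaction Assays by
    Random Sub-Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes local and global quality descriptors for long-range
    chromatin interaction assays (Hi-C, in situ Hi-C, ChIA-PET) from mapped
    paired-end tags (PETs). Unique intra-chromosomal PETs spanning more than a
    configurable genomic distance are repeatedly sub-sampled at fixed densities
    (90/70/50 percent by default); per-window recovery and dispersion of binned
    PET counts yield density quality indicators (denQC), similarity indicators
    (simQC) and a single global QCscore. Includes readers for BEDPE and 4DN
    .pairs text formats, a seeded synthetic PET generator with TAD-block
    structure for calibration experiments, dispersion-map export, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
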