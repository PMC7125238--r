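Package: herbqc
Title: Quality-Control Audit Trail for Herbarium Specimen Digitisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch quality control for digitised herbarium sheet images,
    implementing the staged audit trail used in mass digitisation of
    botanical collections: filename and barcode verification (with a
    built-in Code 128 and UPC-A scan-line decoder), file size and
    resolution heuristics, MD5 fixity spot checks, duplicate detection,
    lightweight TIFF 6.0 and JPEG 2000 structure validation, colour-chart
    exposure classification and Delta E colour accuracy, the visual
    inspection sampling schedule, derivative generation, storage and
    archive verification, and a dual-rendering provenance ledger driven by
    an explicit state machine. Includes a synthetic herbarium-sheet
    generator with defect injection and machine-readable ground truth so
    the whole pipeline can be exercised without real collection data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    png,
    jsonlite,
    yaml,
    tools,
    utils,
    stats,
    grDevices
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with Pillow, on the PATH as 'python',
    for JPEG 2000 and JPEG derivative encoding.
Config/testthat/edition: 3
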