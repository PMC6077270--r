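Package: eduquant
Title: Quantitative Target-Efficacy Analysis of EdU/Immunofluorescence Tumor Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for quantifying in-vivo drug target efficacy
    from two-channel fluorescence images of tumor sections. The EdU (red) channel
    is segmented into proliferating and non-proliferating compartments, positive
    cells are detected as blob centroids in both channels, random circular regions
    of interest are sampled inside the relevant compartment, and cells-per-square-
    millimetre densities are aggregated into percent-change comparisons between
    drug-treated and control groups. A ground-truthed synthetic section simulator
    (Poisson point processes per compartment, Gaussian spot rendering) supports
    validation of every stage against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
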