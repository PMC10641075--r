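Package: mprakit
Title: Design and Analysis of Barcoded 3'UTR Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for massively parallel reporter assays (MPRAs) that tile
    3'UTR elements with short barcodes. Covers design of barcoded oligo
    libraries (variant-centered sequence windows, composition-preserving
    shuffled controls, Hamming-separated barcode whitelists), simulation of
    DNA/Input-RNA/TRAP-RNA barcode count tables with known ground truth
    including transduction-bottleneck "jackpotting", per-barcode activity
    quantification with a random-intercept mixed model, likelihood-ratio
    allelic and element differential tests with FDR control, power simulation
    of barcode-driven false allelic effects, k-mer support-vector
    classification of high- versus low-activity elements, and library QC
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    methods,
    pROC,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    lme4,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
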