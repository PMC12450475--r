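Package: txstress
Title: Modeling Transcription Loss from Accumulating Transcription-Blocking DNA Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative framework linking randomly accumulating
    transcription-blocking DNA lesions (TBLs) to genome-wide transcription
    loss. Provides the closed-form expectation model over a weighted gene
    catalog, a Monte-Carlo lesion-placement simulator on the diploid
    double-stranded genome, UV-dose/lesion-density/lesion-count conversions,
    calibration of daily lesion accumulation rates against longitudinal
    nascent-transcription measurements with validation error tables,
    repair-capacity arithmetic, dose-response regression on EU-incorporation
    data, a gene-body coverage "tilt" statistic, and microscopy
    quantification of nucleoplasmic EU intensity with the size, circularity
    and intensity filters used for hepatocyte imaging. A synthetic-data
    module generates every input class so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    EBImage,
    rtracklayer
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
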