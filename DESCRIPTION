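Package: thermocol
Title: Thermal Signatures of Microbial Activity in Instrumented Sediment Columns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting microbial thermogenesis in
    instrumented Winogradsky columns from multi-channel temperature logs.
    Provides heat-balance theory predictions for sediment heating rates,
    readers and writers for semicolon-delimited logger output, diel
    phase segmentation of the day-night illumination cycle, vertical-gradient
    and living-versus-control difference statistics, insulation-event
    temperature-retention metrics, a binned-frequency Mann-Whitney
    comparison, and a lumped-capacitance thermal simulator that generates
    realistic synthetic column logs with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    jsonlite
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
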