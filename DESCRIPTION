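Package: lipidquery
Title: Cross-Platform Interpretation of Shotgun Lipidomics Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns shotgun (direct-infusion) MS and MS/MS spectra from
    multiple samples into a MasterScan database, identifies lipid species
    with a molecular-fragmentation query language evaluated over
    sum-composition constraints, transposes precursor-ion and neutral-loss
    scans into virtual MS/MS spectra so one set of queries serves all
    acquisition modes, and quantifies species by isotope-corrected,
    class-normalized intensities. Includes a synthetic lipidome and
    spectra simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    yaml
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
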