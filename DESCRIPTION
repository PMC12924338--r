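Package: orgloc
Title: Consensus Organellar Localization Calling and Transit-Peptide Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for conservative in silico reconstruction of organellar
    energy metabolism in non-model algae: benchmarking of subcellular
    localization predictors against a gold standard (confusion matrices,
    MCC), a conservative unanimity consensus caller with a
    multiclass-tool-only rule for membrane and peroxisomal classes,
    transit-peptide validation features (positional charge profiles,
    FGLK-site scanning, position-specific residue enrichment), assembly of
    species-by-enzyme pathway presence/localization matrices with
    contaminant downgrading and pathway-completeness calls, relative
    abundance filtering of 16S community tables, and the Raman
    I(1656)/I(1440) lipid-unsaturation band ratio. A synthetic-data
    generator emulates the statistical structure of targeting presequences,
    predictor error, community tables and spectra so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
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
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
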