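Package: psoscreen
Title: Ex Vivo Cytokine Prescreening of Biologic Response in Psoriasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ex vivo PBMC prescreening of biologic
    therapy in psoriasis. Peripheral blood mononuclear cells stimulated with
    heat-inactivated Streptococcus pyogenes, with or without a biologic at its
    trough serum concentration, yield multiplex cytokine panels; the package
    computes Th1/Th17/Th2 biomarker indices (single analytes and analyte
    ratios such as IFN-gamma/IL-13), their reduction rate and difference
    against the induced-only baseline, tie-aware Spearman associations with
    clinical PASI change (including per-biologic and PsO/PsA subgroup
    analyses), and a direction-of-change composite for ranking candidate
    biologics per patient. Ships a transcription of the published 20-patient
    cohort and a seeded synthetic-cohort generator with Gaussian-copula
    calibration of the index-to-PASI rank correlation and below-LLOQ
    censoring, so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
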