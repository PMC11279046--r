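Package: methmark
Title: Prognostic DNA-Methylation Biomarker Discovery from Matched
    Tumor-Normal Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-step pipeline for discovering prognostic CpG
    methylation biomarkers from matched tumor and adjacent-normal tissue
    pairs. Step one screens probes with paired t-tests under
    Benjamini-Hochberg false-discovery-rate control and a
    complete-separation effect-size filter; step two validates candidates
    on an independent cohort with univariate Cox regression, maps probes
    to genes, and ranks genes by their frequency across enriched Gene
    Ontology biological-process terms; step three fixes each final
    marker's prognostic methylation threshold by a constrained
    minimal-p-value log-rank cutpoint scan with Kaplan-Meier summaries.
    Includes a synthetic-cohort generator with a planted-marker truth
    ledger so the whole pipeline can be exercised and calibrated without
    external data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
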