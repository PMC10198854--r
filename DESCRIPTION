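Package: tlstme
Title: Tertiary Lymphoid Structure Signature Scoring and Tumor
    Microenvironment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tertiary lymphoid structures (TLS) in bulk tumor
    transcriptomes with a 13-chemokine signature score, stratifies cohorts by
    score quartiles, and relates TLS status to outcome with survival machinery
    implemented from first principles (Kaplan-Meier, log-rank, Cox
    proportional-hazards with Efron ties). Includes a per-gene Cox interaction
    screen for genes that modulate the TLS-survival association, single-sample
    gene-set enrichment (ssGSEA) and marker-mean scoring, two-group
    differential expression with fold-change filters, hypergeometric
    over-representation analysis, tumor mutational burden and per-group
    mutation-frequency comparison from MAF-like tables, and complete-linkage
    classification of the tumor microenvironment into five classes. A
    synthetic cohort generator with a latent TLS factor, a linear hazard
    model, group-dependent mutation frequencies and ordinal immunotherapy
    response labels makes every stage testable without external data.
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
    rlang,
    stats,
    tools,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    survival,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
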