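Package: hgborrow
Title: Bayesian Dynamic Borrowing and Pharmacodynamic Analysis for
    Perioperative 2-HG Suppression Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for perioperative (window-of-opportunity)
    trials of mutant-IDH1 inhibitors in low-grade glioma, where the primary
    pharmacodynamic endpoint is suppression of the oncometabolite
    d-2-hydroxyglutarate (2-HG) in resected tumor tissue.  Implements a
    Bayesian hierarchical normal model on log10 tumor 2-HG with dynamic
    borrowing between concurrent and external untreated controls, fitted by
    a conjugate Gibbs sampler; operating-characteristics simulation for
    design evaluation; RANO-LGG best-overall-response classification with
    exact binomial (Clopper-Pearson) confidence intervals for the objective
    response rate; pharmacodynamic association statistics including
    per-gene linear association, signed -log10(p) gene ranking, preranked
    permutation gene-set enrichment, and Benjamini-Hochberg adjustment; and
    a synthetic-cohort generator so the whole pipeline runs without any
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    coda,
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
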