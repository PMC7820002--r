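Package: momint
Title: Multi-Omic Module Integration for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking blood gene expression to serum
    metabolite and cytokine modules in small case-control cohorts, motivated by
    studies of minimal hepatic encephalopathy (MHE) in cirrhotic patients.
    Provides per-omic differential testing (empirical-Bayes moderated t for
    genes and metabolites, exact Wilcoxon for cytokine panels, with
    Benjamini-Hochberg FDR), generalized-log variance stabilization,
    correlation-module discovery via PAM clustering on the distance
    sqrt(2(1-r^2)) with silhouette-guided model selection, per-module PLS2
    regression (NIPALS) scored by R-squared and leave-one-out Q-squared,
    loading-ranked gene-set enrichment, and pathway/term-module network
    construction. Includes a synthetic multi-omic cohort generator with
    planted group effects, latent correlation modules and gene-module
    coupling, plus ground-truth records for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    fgsea,
    mixOmics
Config/testthat/edition: 3
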