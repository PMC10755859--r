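Package: strainflow
Title: Strain-Level Probiotic Colonization Tracking and Fecal Community
    Typing for Infant Metagenomic Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for strain-resolved analysis of infant gut
    metagenomes from probiotic intervention trials. Implements SNV-based
    consensus strain typing of Bifidobacterium longum subsp. infantis over
    a signature-gene catalog (allele-frequency consensus calling,
    read/gene quality filters, concatenated profiles, neighbor-joining
    strain trees, and probiotic/autochthonous/untyped categorization),
    longitudinal colonization tracking (detection, persistence,
    replacement), Dirichlet-multinomial-mixture fecal community typing
    with Laplace/AIC/BIC model selection, ecology statistics (diversity,
    Bray-Curtis, PERMANOVA, PCoA, Procrustes, Kendall taxon-biomarker
    associations, pathogen prevalence), and the trial statistics layer
    (ANCOVA-adjusted means with Tukey intervals, non-inferiority
    decisions, sample size, relative risk, Freeman-Halton exact tests,
    censoring rules). A synthetic cohort generator with machine-readable
    ground truth makes every stage testable without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    data.table,
    emmeans,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
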