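Package: iltx
Title: Transcriptome and Phenotype Analysis of Transgene Effects Across
    Genetic Backgrounds in C. elegans Introgression Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how a transgene's effects on the
    transcriptome and on life-history phenotypes depend on genetic
    background, built around introgression-line (IL) panels in
    Caenorhabditis elegans. Implements per-gene factorial linear models
    (expression ~ age + transgene * genotype) with Type II F tests, a
    permutation-derived significance threshold chosen by the false
    positive / true positive ratio, transcriptome-based developmental age
    estimation from age-responsive marker genes, introgression interval
    mapping from expression markers and PCR panels, hypergeometric GO-term
    enrichment, two-way ANOVA with Tukey HSD contrasts for phenotypes, and
    Kaplan-Meier / log-rank survival analysis with bagging and crawl-off
    censoring. Includes a synthetic-data generator with recorded ground
    truth that emulates a five-background, two-transgene-state, three
    replicate microarray design for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
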