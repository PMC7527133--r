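Package: cohortnet
Title: Consensus Co-Occurrence Networks and Primary Cohorts for Microbial
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers consensus co-occurrence networks from OTU count tables
    and extracts the first-neighbor ("primary") cohorts of target taxa.
    Implements the full pipeline used for abundant freshwater
    bacterioplankton: rarefaction and a prevalence-by-abundance filter
    sweep, four association estimators (Pearson with
    Benjamini-Hochberg adjustment, SparCC basis correlations with
    bootstrap pseudo-p values, Dice-Sorensen on presence/absence, and
    sparse neighborhood selection with StARS stability selection), edge
    voting across methods, taxonomic assortativity and modularity,
    cohort overlap analysis, and the supporting environmental and
    seasonal statistical screens.  A seeded synthetic-community
    generator (including a dilution mixed-culture simulator) provides
    ground-truth interaction networks for validating recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    glmnet,
    igraph,
    stats,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
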