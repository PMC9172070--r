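Package: lnescore
Title: Local Network Entropy Scoring for Critical Transition Detection
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects pre-disease (critical transition) states from a single
    case sample scored against a reference cohort on a protein-protein
    interaction network. For every gene, a Shannon-type local network entropy
    is computed from the normalized absolute Pearson correlations between the
    gene and its first-order network neighbors, before and after mixing one
    case sample into the reference cohort; the mean per-gene product of the
    entropy change and the standard-deviation change is the sample's global
    LNE score. The package aggregates scores by clinical stage to call the
    tipping point, extracts dynamic network biomarker (DNB) gene modules from
    the top-ranked LNE genes of critical-state samples, classifies optimistic
    and pessimistic prognostic biomarkers via Kaplan-Meier/log-rank
    stratification, flags dark genes (non-differential expression but
    differential entropy), and ships a synthetic tipping-point simulator so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
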