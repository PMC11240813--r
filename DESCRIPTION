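Package: herdrank
Title: Dominance Hierarchy, Feeding Behaviour and Faecal Microbiota Analysis for Group-Housed Pigs
Version: 0.1.0
Authors@R: person("Herdrank", "Maintainers", email = "maintainers@herdrank.org", role = c("aut", "cre"))
Description: A reproducible pipeline linking social dominance hierarchy in
    group-housed growing pigs to feeding behaviour, growth and faecal
    microbiota. Provides round-robin tournament scheduling and ranking-score
    computation for pairwise dominance tests, electronic-feeder event-log
    feature extraction with pen-relative normalization, hierarchy-change
    accounting, linear and random-intercept models for growth and behaviour
    contrasts, and module-based differential-network (NetMoss-style)
    microbial biomarker identification from genus-level abundance tables,
    including SparCC compositional correlation inference, WGCNA-style module
    detection, FDR-corrected differential abundance calls and cross-validated
    panel AUC. A synthetic-cohort generator with planted effects makes every
    stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
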