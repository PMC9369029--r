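Package: planttata
Title: TATA-Box Affinity Scoring and Mutation Effect Assessment for Plant
    Proximal Promoters
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates TATA-binding protein (TBP) affinity for 90-bp plant
    proximal promoter fragments with a three-step slide/stop/bend model, maps
    human-TBP dissociation constants onto the plant scale through a pair of
    calibrated linear rescaling equations, and compares wildtype against
    mutant promoter variants with a Z test that predicts expression excess,
    deficiency, or no significant change.  Verification tooling computes
    Pearson, Spearman, Kendall tau-b and Goodman-Kruskal gamma correlations
    with significance, ordinary least-squares fits with confidence bands, a
    tab-separated knowledge-base reader/writer for promoter-variant datasets,
    and a seeded synthetic promoter-family generator so that the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
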