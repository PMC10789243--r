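Package: combopredict
Title: Drug Combination Prediction by Transcriptional Reversal and Target
    Optimisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate two-drug combinations for drug repurposing by
    two complementary engines: Combination Gene Expression Matching (CGEM),
    which scores the combined gene-expression signature of a drug pair for
    maximal Kolmogorov-Smirnov reversal of a disease up/down signature, and
    Target Optimisation (TargOpt), which scores pairs by coverage of
    disease-relevant targets in the desired direction against off-target
    burden. The two rankings are merged by rank aggregation and annotated
    with drug-drug interaction and shared-mechanism flags for expert triage.
    Also provides behavioural endpoint utilities for preclinical phenotyping
    (discrimination index, latency censoring, exploration-time inclusion
    rules) and seeded synthetic-data generators with planted ground truth so
    the whole pipeline is testable without external downloads. Reads and
    writes GCT 1.2 signature matrices, GMT gene sets and plain TSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
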