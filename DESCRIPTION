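Package: promethee2
Title: PROMETHEE-II Outranking Analysis for Drug-Candidate Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complete PROMETHEE-II multi-criteria outranking pipeline: min-max
    normalization of a crisp decision matrix, pairwise preference evaluation
    under the standard preference-function family, weighted preference
    aggregation, positive/negative/net outranking flows and a complete
    competition ranking. Includes linguistic-scale elicitation (five-level
    verbal scale to crisp scores, multi-expert panel aggregation), weight
    sensitivity analysis (sweeps, criterion knockout, Kendall tau-b rank
    agreement), synthetic expert-panel generators with known ground truth for
    validation, delimited-text and DOT exports, a command-line interface, and
    a bundled case study ranking nine anti-angiogenic receptor tyrosine kinase
    inhibitors against three angiogenic growth-factor criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
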