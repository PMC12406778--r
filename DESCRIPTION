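Package: survcat
Title: LLM-Assisted Categorization of Open-Ended Survey Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Categorizes open-ended survey free-text responses (such as
    caregiver-reported reasons for child non-vaccination in household
    coverage surveys) into a closed, researcher-defined category scheme
    using several LLM-assisted strategies: embedding-cluster-then-label,
    zero-shot, few-shot, chain-of-thought prompting, and fine-tune dataset
    export. Includes unique-string deduplication with multiplicity
    weighting, a benchmark evaluation protocol (accuracy, adjudicated
    accuracy ceiling, margin-of-error and sample-size calculations), a
    token-based API cost model, deterministic mock completion and
    embedding backends for fully offline testing, and a seeded synthetic
    corpus generator with known category ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    stats,
    stringi,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
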