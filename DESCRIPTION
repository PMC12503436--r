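Package: drkex
Title: Schema-Constrained Knowledge Extraction, Verifiable Rewards, and
    Strict-Match Evaluation for Drug Repositioning Text Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for literature-based drug-repositioning knowledge
    extraction at desk scale: an 11-entity/18-relation annotation schema
    with validation lints, a parser for chain-of-thought model outputs
    (think/step tag integrity plus a two-root-key JSON payload), a
    dual-reward scorer combining accuracy and structural-format
    components for reinforcement-learning fine-tuning with verifiable
    rewards, the group-relative policy optimisation (GRPO) objective
    mathematics, a strict exact-match precision/recall/F1 evaluation
    harness with an error taxonomy and confusion matrix, and a synthetic
    corpus generator with controlled error injection so every component
    is testable without trained models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
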