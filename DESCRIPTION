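Package: coopsignal
Title: Zero-Determinant Strategies, Emotion Signals and Cooperation in the
    Iterated Prisoner's Dilemma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how memory-one counterpart strategies and
    outcome-contingent emotion displays shape human cooperation in the
    iterated prisoner's dilemma. Implements the zero-determinant (ZD)
    strategy algebra of Press and Dyson (construction, certification,
    completion, stationary outcome distributions and enforced payoff
    relations), a reproducible match engine for memory-one players, the
    cooperative/competitive emotion display policies, a synthetic
    participant-cohort generator with a logistic round-level choice model,
    and the full between-subjects statistical pipeline: Type III factorial
    ANOVA with partial eta-squared, planned synergistic contrasts, pooled
    t tests, mixed ANOVA with Huynh-Feldt sphericity correction, bootstrap
    multiple mediation, and noncentral-F power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
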