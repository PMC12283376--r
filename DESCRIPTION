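Package: games2x2
Title: Finitely Repeated 2x2 Games Between Scripted and Text-Backed Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and benchmarking harness for finitely repeated two-player,
    two-action games. Represents pay-off matrices, enumerates the topology of
    strict ordinal 2x2 games and classifies them into six structural families,
    renders games as textual prompts with controlled framing variants, plays
    matches between pluggable decision policies (scripted human-like strategies
    and text-completion-backed agents, including a social chain-of-thought
    wrapper and prediction modes), and aggregates tournament reports with
    normalized scores. Includes the comparison statistics used for benchmarking:
    two-sided t-tests, Cohen's d with confidence intervals, and the
    Jeffreys-Zellner-Siow default Bayes factor.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
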