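Package: assocnet
Title: Free-Association Norms, Semantic Memory Networks, and
    Spreading-Activation Priming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with free-association norms of the
    "World of Words" family: reading and cleaning cue-response tables
    (spelling correction, compound restoration, article stripping,
    noun lemmatization, repetition balancing), building filtered
    weighted semantic memory networks, simulating spreading activation
    to model semantic priming, and quantifying priming and implicit
    bias effects with paired Wilcoxon tests, matched-pairs rank-biserial
    effect sizes, and Spearman correlations against lexical decision
    reaction times. Includes a synthetic norms generator with planted
    community structure and a corruption ledger, so the whole pipeline
    can be validated end-to-end without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
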