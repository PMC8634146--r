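Package: discrimlex
Title: Linear Discriminative Learning for Inflectional Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An engine for modeling inflectional morphology with linear
    discriminative learning: binary sublexical cue matrices (phone, letter
    and syllable n-grams), simulated or embedding-derived semantic matrices,
    linear form-to-meaning and meaning-to-form mappings estimated either as
    the regression end-state or incrementally with the Widrow-Hoff rule,
    correlation-based comprehension evaluation under strict and lenient
    criteria, word-form synthesis by analysis over n-gram overlap graphs,
    nonce-word (wug) plural simulation, semantic-role expansion with
    simulated token frequencies, weight pruning, and a seeded generator of
    German-like noun paradigm lexicons for fully self-contained experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Matrix, MASS, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
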