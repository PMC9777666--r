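Package: umamipanel
Title: Taste-Compound Scoring and Consumer Emotion Analytics for
    Crustacean Flavor Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links the taste chemistry of Chinese mitten crab (Eriocheir
    sinensis) edible parts to consumer response. Scores free amino acids,
    5'-nucleotides and metal ions by taste activity value (TAV) and
    equivalent umami concentration (EUC) with nucleotide synergy; analyses
    check-all-that-apply (CATA) emoji selections with Cochran's Q,
    pairwise McNemar tests with Bonferroni correction and chi-square
    correspondence analysis; relates variable groups through multiple
    factor analysis and Escoufier's RV coefficient with network export;
    and predicts hedonic preference from six flavor compounds with a
    single-hidden-layer feed-forward neural network. A synthetic-panel
    generator emulates the study design (9 samples, 93 consumers, 23
    emojis) so every stage is testable from packaged summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
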