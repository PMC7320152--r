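Package: usvsis
Title: Suffix-Tree Markov Models and Syntax Information Scoring for Vocal Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for evaluating and improving syllable-labeling algorithms for
    animal vocal sequences, developed around mouse ultrasonic vocalizations (USVs).
    Labeled syllable sequences are modeled as depth-D suffix-tree Markov chains,
    from which the entropy rate and the Syntax Information Score (SIS; the mutual
    information between a syllable label and its suffix) are estimated. Includes
    synthetic Markov ground-truth models with analytic entropy rate and SIS for
    estimator validation, two reference labelers (a pitch-jump/duration scheme and
    a cosine-distance centroid scheme over filterbank features), the Syntax
    Information Maximization (SIM) algorithm that refines cluster centroids by
    multiplicative perturbation to maximize SIS, a simplified spectrogram-based
    syllable parser, and statistically matched synthetic fixture generators
    (Markov label corpora, clustered feature corpora, chirp audio).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
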