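Package: formamentis
Title: Forma Mentis Networks from Free-Association and Valence Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds forma mentis networks: undirected word-association
    networks whose nodes carry population-derived valence attributes
    (positive, neutral, negative) estimated from free-association and
    1-5 Likert rating surveys. Implements the survey cleaning rules
    (blank-fraction rejection, warm-up associate removal, token
    normalization), an against-the-rest Kruskal-Wallis valence
    classifier, valence auras of network neighborhoods, Kendall tau
    emotional-homophily statistics with attribute-preserving
    configuration-model null ensembles, cross-validation against
    external affective norms, and a seeded synthetic survey generator
    with known ground truth for end-to-end parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
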