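Package: divrank
Title: Diversity-Biased Learning-to-Rank for Biomedical Passage Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A combined learning-to-rank framework for promoting diversity in
    biomedical passage retrieval. A general linear ranking model is trained by
    coordinate ascent that directly maximizes a retrieval metric over eight
    classical content-based features (TF-IDF, Okapi BM25, three
    divergence-from-randomness models, Dirichlet and Hiemstra language models,
    and query-term proximity). A diversity-biased model adds seven features
    derived from the aspect annotations of an initial ranking (novelty and
    coverage of query aspects), and the two models are combined with an
    alpha-weighted linear mixture. Includes TREC-Genomics-style evaluation at
    the document, passage, character and aspect levels, run/qrels/LETOR file
    I/O, and a seeded synthetic-collection generator with controllable aspect
    redundancy for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
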