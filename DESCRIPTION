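Package: screenloop
Title: Seed-Driven Relevance Ranking for Systematic Review Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated title and abstract screening for systematic
    reviews. Articles retrieved by a search strategy are embedded as
    numeric vectors (deterministic tf-idf or paragraph vectors trained
    per collection), ranked by cosine similarity to known-relevant seed
    articles, and presented in rounds of 50; reviewer flags feed back
    into the ranking between rounds. Includes exact-match reference
    de-duplication for RIS and CSV collections, multi-reviewer conflict
    detection, evaluation metrics (work saved over sampling at a recall
    level, percent not reviewed, screening-rate and time/cost savings),
    simulation replay of labelled corpora with threshold and
    seed-sensitivity analyses, and a synthetic labelled-corpus generator
    so the whole pipeline is testable without copyrighted review data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    stringi,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
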