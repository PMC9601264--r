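Package: ccevector
Title: Entropy-Based Consensus Encoding of Likert Surveys for Clinical
    Event Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Encodes qualitative expert opinion into machine-learning-ready
    feature vectors for clinical decision support. Implements the
    entropy-based consensus, dissension and strength-of-consensus statistics
    for multi-rater ordinal (Likert) rating samples, Gompertz sigmoid
    weighting for respondent sample size, assembly of mixed
    quantitative/qualitative critical clinical event (CCE) vectors with
    cohort min-max normalization, reference-based similarity scoring
    (Euclidean, cosine, Canberra and Mahalanobis distances), desk-scale
    k-nearest-neighbour classification and k-means clustering over CCE
    vectors, and seed-deterministic synthetic survey and encounter-cohort
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
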