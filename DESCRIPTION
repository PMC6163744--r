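Package: postmine
Title: Content-Based and Temporal Mining of Patient-Community Social Media Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing social-media activity of patient
    communities (rare-disease Facebook groups and similar): engagement
    scoring and tertile stratification, tf-idf selection of
    group-distinctive vocabulary, contingency-table log-likelihood
    (keyness) comparison of a post corpus against a reference priority
    document, lexicon-based polarity and subjectivity scoring, Spearman
    correlation screens, and hour/weekday/daypart temporal aggregation.
    Includes a seeded synthetic-corpus generator that emulates the
    statistical structure of a Netvizz-style post export (post-type mix,
    overdispersed interaction counts, bimodal diurnal rhythm, planted
    corpus-enriched keywords, hour-dependent polarity drift) so the whole
    pipeline can be exercised without access to the original data, and a
    calibration routine that recovers the unprinted corpus-size ratio of
    a published keyness table from its printed rows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
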