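Package: forumvigil
Title: Patient-Forum Infodemiology and Pharmacovigilance Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for infodemiology studies of drug-related discussions on
    patient forums: keyword-filtered corpus ingestion with an auditable
    retention ledger, semisupervised topic classification by prototype-centroid
    cosine similarity with keyword overrides, lexicon-and-rules sentiment
    scoring on the compound -1..+1 scale, monthly/seasonal/change-point
    analysis of discussion volume, human-validation metrics (accuracy,
    weighted F1, Cohen's kappa with bootstrap intervals), and a synthetic
    corpus generator with ground truth for end-to-end parameter-recovery
    testing. Defaults emulate a three-year vitiligo-forum extract discussing
    topical ruxolitinib.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
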