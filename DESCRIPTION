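Package: workuprec
Title: Item-Association Recommender for Specialty Referral Workup Orders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates an item co-occurrence recommender that, given
    the clinical items on a patient's chart at the time of a specialty referral,
    ranks the diagnostic workup orders (labs and imaging) a specialist is likely
    to place at the first visit. Implements positive-predictive-value ranking
    from a sparse item association matrix, query-item weighting schemes (inverse
    frequency, relative risk, and their combination) selected by cross-validation,
    prevalence-based cold-start fallback, and evaluation machinery (precision and
    recall at k, pooled ROC AUC, bootstrap confidence intervals, baseline rankers,
    paired ranker comparison). Ships a synthetic EHR cohort generator with planted
    conditional order probabilities so the full pipeline is buildable and testable
    without real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
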