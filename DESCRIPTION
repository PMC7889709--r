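Package: picusirs
Title: Rule-Based SIRS Detection and Clustered Diagnostic Accuracy for
    Pediatric Intensive Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects systemic inflammatory response syndrome (SIRS) in
    pediatric intensive-care time series using the age-specific IPSCC
    consensus criteria (at least two of four criteria, one of which must
    be an abnormal body temperature or leukocyte count), with context
    rules for active cooling, pacemakers and mechanical ventilation.
    Turns the continuous rule state into episodes (24-hour closing rule)
    and SIRS-positive patient-days (one-full-hour rule), and scores a
    detector or bedside rater against a reference standard: stay-level
    six-case classification with a +/- 4 hour episode-start matching
    window, day-level contingency tables, sensitivity and specificity
    from intercept-only logistic generalized estimating equations with
    exchangeable working correlation and robust (sandwich) Wald
    confidence intervals, best/worst-case missing-data bounds, and
    one-proportion sample-size planning. A seeded synthetic-cohort
    generator with injected episodes, context intervals, imperfect
    raters and day-level missingness lets the whole pipeline run end to
    end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
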