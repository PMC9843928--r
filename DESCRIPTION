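Package: abilitysim
Title: Simulated Clinical Trials Comparing Ability and Norm-Referenced
    Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte-Carlo machinery for parallel-arm clinical trials in
    neurodevelopmental disability whose endpoint is a standardized test
    score.  Simulates correlated baseline/endpoint person-ability (growth
    scale value, GSV) scores, converts them through raw-score lookup
    tables into age-normed V-scale scores, analyzes each simulated trial
    by ANCOVA with the baseline score as covariate, and estimates power
    and type I error over a grid of age-range and impairment scenarios.
    Because the publisher's score-conversion tables are copyrighted, a
    generator for structurally faithful synthetic table sets is included,
    along with readers and validators for user-supplied tables.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
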