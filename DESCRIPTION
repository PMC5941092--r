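Package: surveyguard
Title: Deduplication and Cross-Validation of Web Survey Submissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based toolkit for screening fraudulent ("spam")
    submissions to small web-based health surveys. Implements a
    configurable registry of suspicion indicators (speeding, duplicate
    and mismatched IP addresses, email-handle conventions, chained start
    times, odd-hour completion, implausible clinical profiles,
    straight-lining, item nonresponse, gibberish text, failed
    verification items), a k-strikes adjudication rule with a manual
    review queue, protocol versioning across recruitment waves with a
    uniform retrospective pass, a rolling-window drift monitor for
    evolving spam, and a seeded synthetic-cohort simulator that emits
    valid respondents and labelled spam waves (naive and evolved,
    including a dual-link diversion scenario) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
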