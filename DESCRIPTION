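Package: tripcoord
Title: Coordination of Dual-Foraging Seabird Pairs from Colony Attendance Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse coordinated chick provisioning in seabirds with a
    dual foraging strategy, from binned colony presence/absence observations of
    individually marked pairs. Extracts foraging trips on a 10-minute grid,
    classifies them into short and long trips by a variance-minimising cut-off
    on log duration, runs Monte Carlo randomization tests for pair coordination
    (short-trip/long-trip overlap) and for evenness of chick feeding
    (coefficient of variation of inter-feeding intervals), combines per-session
    p-values across observation sessions (Stouffer Z, Fisher, logit), derives
    chick growth parameters with their principal-component reduction, fits the
    downstream linear mixed models, and generates study-shaped synthetic colony
    attendance data for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
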