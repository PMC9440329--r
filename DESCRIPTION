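Package: cropsieve
Title: Exhaustive Weather-Feature Selection for District-Level Crop Yield
    Regression
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Weather-based crop yield prediction by exhaustive, strictly
    out-of-sample selection of time-aggregated weather features for
    per-district multiple linear regressions.  Monthly weather variables are
    aggregated over all contiguous 2-6 month windows of the pre-harvest
    season; an exhaustive best-subset search per district and target year
    feeds a binomial occurrence-frequency screen; screened feature
    combinations are ranked by leave-one-out prediction skill, merged into a
    pool of globally and locally well-performing models, and the per-district
    winners drive hindcasts and forecasts that are aggregated to regional
    yield series with uncertainty bands.  Includes a synthetic district-panel
    generator with planted feature effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
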