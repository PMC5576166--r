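Package: hequity
Title: Geographic Equity Analysis of Health Care Resource Distributions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how equitably health care resources
    (physicians, nurses, hospital beds) are distributed across the
    administrative regions of a country, on two complementary bases:
    per 10 000 population and per 1 000 square kilometres of land area.
    Implements Lorenz curves and Gini concentration coefficients for
    grouped regional data (trapezoidal and grouped-formula estimators with
    a brute-force verification oracle), population-density based
    urban/suburban/rural classification with rank-based (Mann-Whitney U)
    group comparison, Fisher-Jenks natural-breaks supply categories for
    choropleth-style reporting, WHO workforce-threshold checks, and a
    synthetic region-table generator with controllable inequality for
    validation against the closed-form log-normal Gini. Ships the 2014
    Mongolian province-level table as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
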