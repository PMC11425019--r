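Package: dhengage
Title: Engagement and Retention Analytics for Digital Health App Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engagement-analytics pipeline for remote-monitoring smartphone
    studies: reads participant registries and test-completion event logs,
    computes registration-to-activation conversion funnels, sessionizes
    day-level activity into test-series completions (the daily-activity
    series, its reduced variant, and the two-minute walk test), derives the
    four canonical UX metrics (continuous-usage streaks, inactivity gaps,
    test completion rate and day-n user retention) as complementary
    cumulative distributions, fits power-law tails to inactivity times, and
    compares calendar-window cohorts (for example before and after reminders
    and push notifications were introduced). A stochastic user-behavior
    simulator with an activation funnel, geometric streaks, heavy-tailed
    gaps and a notification-policy engine generates synthetic datasets with
    the same schema so every stage is testable without the study's data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
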