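---
title: "Engagement analytics for smartphone-study event logs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engagement analytics for smartphone-study event logs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhengage)
```

## The problem

A remote-monitoring smartphone study produces two tables: a *registry*
(one row per registrant, with registration, e-consent and app-activation
dates, self-declared MS status and platform) and an *event log* (one row
per completed test, with a participant id, a test code from the
eight-test battery, and a timestamp). Engagement analysis asks four
questions of these tables: who converts from registration to an activated
app; for how many consecutive days people use the app; for how long they
pause; and how many are still active *n* days after activation. This
vignette documents how `dhengage` defines and computes those quantities,
the design decisions that were genuinely open, and what the bundled
simulator does and does not emulate.

## Sessionization: from events to series completions

All metrics are day-granular. Timestamps are converted to calendar days
under a configurable timezone policy; the default is UTC because public
exports rarely state their locale and a fixed zone is the only
reproducible choice (`timezone_policy = "source_local"` is available for
logs known to carry local time). Within-day event order is never used:
the app enforces the fixed test sequence, logs may not preserve it, and a
day-level completion is a set property.

Three test series are tracked:

* **DA** — the full daily-activities sequence: DMQ, IPS, IPS Digit–Digit,
  PT, DaS, SBT, UTT;
* **DAx** — DA without the two tests that require standing and space
  (SBT, UTT);
* **TwoMWT** — the two-minute walk test alone.

A series is completed on a day when all its strictly daily tests appear
in that day's event set. The IPS is special: the app offers it at most
weekly while the rest of the sequence is daily, so requiring IPS daily
would make week-long DA streaks structurally impossible — contradicting
the multi-week streaks such studies report. `dhengage` therefore treats
IPS as *weekly credit*: a DA/DAx completion requires an IPS on the same
day or within the trailing `ips_weekly_window_days` window (default 7
days including the day itself, i.e. the day or the 6 days before).
Setting `ips_weekly_window_days = 0` recovers the strict reading, in
which IPS becomes a daily requirement. Whether the original study's own
counter used the weekly-credit or the strict rule is not documented; the
window default is this package's reconstruction, and the strict mode is
kept precisely so the sensitivity is one configuration flag away.

Because DAx's requirement set is a subset of DA's, every DA completion
day is a DAx completion day. This subset property is asserted as a
property-style test on randomized inputs and is also enforced *by
construction* in the simulator (below), so it holds at both ends of the
pipeline.

Validation quarantines — never silently drops — events with unknown
participant ids or timestamps before the participant's activation, and
deduplicates identical (participant, test, timestamp) rows; app telemetry
retries make such duplicates common, and at day granularity they carry no
signal.

## The four metrics

Let \(D_i \subseteq \{0, 1, 2, \dots\}\) be participant *i*'s set of
completion days for a series, with day 0 the activation day.

**Continuous usage time.** Runs are maximal blocks of consecutive days in
\(D_i\). Two units are reported, because the published figures leave the
unit ambiguous: the per-participant *longest* run (the unit behind
"proportion of participants with ≥ 3 consecutive days of usage", with
the cohort size as denominator) and the pooled multiset of all run
episodes. Both are exposed as first-class outputs of `usage_ccdf()`.

**Inactivity time.** Gaps are the inactive stretches *strictly between*
two runs. A trailing inactive stretch after the last active day is
censored, not a gap: a gap is by definition bounded by use on both sides,
and counting the open-ended tail would conflate pausing with churn.
Participants who never pause contribute nothing to the gap multiset.

**Truncation.** Usage and inactivity metrics only consider the first
`truncation_days` (default 343) days of each participant's data, so
cohorts whose calendar windows differ in length stay comparable; activity
beyond the horizon is discarded and flagged (`truncated_at`). The
truncation deliberately does *not* apply to completion-rate and retention
curves, which are defined over the full observation window.

**Test completion rate.** \(P(\text{participant completed} \ge n
\text{ series})\), denominator the cohort size, computed over the whole
window. Day-level deduplication means a participant contributes at most
one completion per series per day.

**User retention rate.** The phrase "fraction of participants who
returned *n* days after activation" admits two readings: active exactly
on day *n*, or still active at-or-after day *n*. `dhengage` defaults to
the latter — \(R(n) = \#\{i : \max D_i \ge n\}/N\), the CCDF of the last
active day — for two structural reasons: the study frames all four
metrics as complementary cumulative distributions, and its published
retention rows show identical day-14 and day-30 values (a plateau),
which exact-day retention essentially never produces but a last-active-day
CCDF does naturally. The exact-day definition remains available
(`retention_definition = "active_exactly_day_n"`). Under the default the
curve is non-increasing by construction, and day-1 retention can never
exceed the ≥ 1-series completion rate (day-0-only users count in the
latter only) — both are asserted as tests.

## Power-law tail of the inactivity times

The inactivity CCDF is summarized by the magnitude α of its log-log
slope, \(\log P(X \ge n) \approx -\alpha \log n\). Two estimators are
implemented:

* `loglog_ls` (the reporting convention): weighted least squares of
  \(\log \hat p(n)\) on \(\log n\) over support points ≥ `xmin` with
  positive probability. The weights are the delta-method inverse
  variances of a log proportion, \(w_n = \text{num}_n / (1 - \hat p_n)\):
  an empirical CCDF's tail consists of many support points each carried
  by a handful of observations, and unweighted LS lets that noise
  dominate the slope. On an exact power-law curve the fit is exact to
  machine precision regardless of weights (zero residuals), which the
  tests assert at α = 0.96 and α = 2.
* `discrete_mle`: the zeta-distribution maximum-likelihood exponent
  \(\hat s\) (Hurwitz-zeta normalization, direct series summation with an
  Euler–Maclaurin tail), reported as \(\hat s - 1\) so both methods share
  the CCDF-slope scale. The conversion is the usual density/CCDF exponent
  relation for discrete power laws. The Kolmogorov–Smirnov distance
  between empirical and fitted CCDFs is reported as goodness.

The two estimators answer slightly different questions: `loglog_ls`
summarizes the curve actually plotted; the MLE assumes the zeta form and
will differ when the data follow a different discrete power law (the
simulator's generator, for instance, is an exact-CCDF power law, not a
zeta, and its small-\(n\) mass differs). Both are reported; neither is
silently substituted for the other. No power-law-versus-lognormal model
comparison is attempted — the claim being summarized is "approximate
power law", not a model selection.

A fit needs at least 3 usable support points; fewer is an error, not a
silent NA.

## Cohorts and comparison

Cohort windows are data, not code: the four study windows ship as a named
preset (`cohort_preset()`) and anything can be overridden. Journey
cohorts assign by *registration date* (the journey variant is determined
at registration) and include participants regardless of MS status, since
MS status was only collected post-activation; reminders cohorts assign by
*activity inside the window* and are MS-only. A participant active in
both observation periods belongs to both cohorts with disjoint clipped
event sets — clipping never increases any metric, which is asserted
end-to-end. One documented discrepancy: the without-reminders window's
end date is printed in two places as October 20 and October 21, 2019; the
preset uses **October 20 inclusive** and this paragraph is the record of
that choice.

Within a reminders cohort, retention is still anchored at each
participant's activation date even when that date precedes the window
(their early events are clipped away). On real multi-period data this
can make a long-activated participant trivially "retained" at small
*n*; in the simulated datasets participants activate inside their
cohort's window, so the effect is not exercised. Analysts applying the
preset windows to external data should be aware of it.

Percentages are formatted half-up at one decimal (`round_half_up()`,
since base R rounds half to even). The published table itself mixes
conventions (e.g. 39/172 printed as 22.6, a truncation; 113/350 printed
at two decimals), which is why reproduction tests compare at ±0.1
percentage point rather than exact string equality.

## The simulator

The generator's purpose is structural: produce datasets with the same
schema and the same statistical signatures the analysis assumes, so every
stage is testable without the study's data.

* **Funnel.** Registrants consent with `p_consent` (default 1 — in the
  study every registrant completed the in-flow e-consent), then activate
  with probability `p_activate_base` = 0.539, the published
  original-journey conversion rate. The seamless journey multiplies the
  activation *odds* by `deep_link_effect` = 2.5124, the odds ratio
  implied by the published 53.9% → 74.6% contrast. Activation delays are
  uniform within the 48-hour activation-code validity; non-activators
  stall and keep no activation date.
* **Behavior.** From activation day, an alternating renewal process:
  streak lengths are geometric with continuation probability
  `streak_continue_p` (0.5 — consistent with the fast early falloff of
  usage CCDFs); at each streak end the participant abandons permanently
  with probability `1 − p_return` (p_return = 0.55), otherwise draws a
  gap from the discrete power law with CCDF slope `gap_exponent` = 0.96
  — the exponent reported for the inactivity distributions — and survives
  it with \((1-h)^{gap}\), `dropout_hazard` h = 0.01/day. The gap
  sampler is the inverse transform \(X = \lfloor U^{-1/\alpha}\rfloor\),
  whose CCDF is *exactly* \(n^{-\alpha}\) on the integers, so the
  generator and the slope estimator are a clean round trip (recovery
  within ±0.05 at 20,000 draws is an acceptance property).
* **Series draws.** Each active day is a DAx day with
  `p_dax_given_active` (0.85) and, conditional on that, a DA day with
  `p_da/p_dax` — the coupling that enforces DA ⊆ DAx by construction;
  the 2MWT is independent (`p_2mwt_given_active`, 0.40). Active days
  with no series draw emit only the mood question (an
  opened-but-abandoned session), which keeps the participant in
  activity-based cohorts without creating completions. IPS is emitted at
  most weekly, which always satisfies the weekly-credit window.
* **Reminder effect.** Applied as parameter modifiers when notifications
  are enabled: streak continuation × 1.6, dropout hazard × 0.5, +0.10 on
  the 2MWT probability. These defaults were set once as a plausible
  mHealth-adherence calibration that reproduces the broad published
  magnitudes (day-1 retention in the 60–85% range, a several-fold day-30
  retention lift with reminders, heavy-tailed gaps); they are conditions
  of the simulated study, not fitted estimates. With all multipliers at
  their null values the with/without cohorts are exchangeable — asserted
  as an identity test at a fixed seed.
* **Notifications.** The policy engine reproduces the trigger rules:
  reengagement notifications 4 hours after the day's last completed test,
  capped at 7 PM (a session already past 7 PM gets nothing); streak
  encouragement at 10 AM after 3 consecutive active days, at most twice a
  week; lapse encouragement after 3 inactive days; acknowledgment every
  14 days at 6 PM; globally at most 2 notifications per participant-day.
  The published rule text says "at 7 PM, at the latest" and "never after
  7 PM", which this implementation reads as *send time ≤ 19:00 exactly*.
  Notifications are descriptive output only — they do not feed back into
  behavior, because the study measures cohort-level contrasts, not
  notification-level causal effects; the uplift parameters are the
  stand-in for that unobserved mechanism. One trigger in the published
  rules — abandoning mid-walk-test — is unobservable from a
  completed-tests log and is represented in the type vocabulary but never
  emitted by the generator.

What the simulator does **not** emulate: demographic covariate effects,
platform differences, passive GPS/life-space data, calendar seasonality,
per-participant heterogeneity in the behavior parameters, and any real
notification→behavior feedback. Passing tests on simulated data
therefore demonstrate that the *pipeline* computes its definitions
correctly under the assumed renewal-process structure — not that real
cohorts follow that structure.

## Verification strategy and problem sizes

Every metric is checked against an independent brute-force oracle on
randomized inputs: a day-by-day scan for runs/gaps (200 random activity
patterns), per-participant milestone counting for funnels, key-wise
grouping for daily profiles, last-active-day counting for retention. The
behavior process has an exact day-level recursion for
\(P(\text{some active day} \ge m)\) implemented independently in the test
helpers; simulated day-30 retention must match it within 3 percentage
points (2,500 participants). Funnel calibration is checked at 5,000
registrants per arm (±2 points). Published headline rates are reproduced
from fixtures that realize the printed numerator/denominator pairs
exactly — the retention fixture assigns rank-ordered last-active days so
that any pointwise-dominant profile (DAx over DA) dominates
participant-wise too. The analysis scripts simulate 600 registrants per
arm; all sizes were chosen as the smallest that leave the stochastic
assertions comfortable margins.

## Known limitations

* The weekly-credit IPS rule is a reconstruction (see above); strict mode
  changes DA/DAx counts.
* Retention anchored at activation interacts with window clipping for
  participants activated before a cohort window opens (see above).
* The discrete MLE assumes the zeta form; on non-zeta power laws it is a
  cross-check, not an unbiased estimator of the CCDF slope.
* `usage_unit` and the CCDF-vs-density slope convention are documented
  choices where the published material is ambiguous; the density-exponent
  reading would differ by +1 and is deliberately not the default.
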