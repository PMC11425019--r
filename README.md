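# dhengage

Engagement and retention analytics for digital-health smartphone studies.

Remote-monitoring studies in multiple sclerosis (and other chronic
conditions) ask participants to self-administer a battery of smartphone
tests — a daily-activities sequence (mood question, information-processing
speed test and its digit–digit control, pinching, shape drawing, static
balance, U-turn) plus a separately administered two-minute walk test
(2MWT). The scientific questions such studies keep running into are not
about the tests but about *engagement*: how many registrants ever activate
the app, how long they keep using it, how long they pause, and whether UX
changes (a deep-linked activation journey, configurable reminders and push
notifications) move those numbers.

`dhengage` is a pipeline for exactly that analysis, from raw
test-completion event logs and a participant registry to:

* **conversion funnels** — registration → e-consent → app activation, per
  calendar cohort;
* **sessionization** — day-level activity profiles and test-series
  completions for three series: `DA` (the full fixed sequence), `DAx`
  (the sequence minus the balance and U-turn tests) and `TwoMWT`, with a
  weekly-credit rule for the at-most-weekly IPS test;
* **the four canonical UX metrics**, each as a complementary cumulative
  distribution (CCDF):
  * continuous usage time — maximal runs of consecutive active days,
    P(run ≥ n);
  * inactivity time — gaps strictly between runs, P(gap ≥ n), with a
    power-law tail fit (log-log slope and a discrete-MLE cross-check);
  * test completion rate — P(participant completes ≥ n series);
  * user retention rate — P(participant still active on or after day n
    post-activation), i.e. the CCDF of the last active day;
* **cohort comparison** — calendar-window cohorts (e.g. before/after the
  reminders rollout), MS-only filters, per-cohort event clipping, and a
  retention table at days 1/3/7/14/30 in `pct (num/denom)` format;
* **a behavior simulator** — an activation funnel with a configurable
  deep-link odds effect, an alternating renewal process per participant
  (geometric streaks, discrete power-law gaps with CCDF slope
  `gap_exponent`, permanent-dropout hazard), coupled series draws that
  enforce DA ⊆ DAx by construction, and a push-notification policy engine
  (4-hour reengagement triggers capped at 7 PM, encouragement after
  3-day streaks and 3-day lapses, acknowledgments every 2 weeks, at most
  2 notifications per day).

The model behind the usage metrics: for participant *i* with active-day
set *D\_i* (days since activation), runs are maximal blocks of consecutive
days in *D\_i* and gaps the inactive stretches strictly between them.
Usage and inactivity metrics are truncated to the first 343 days per
participant so cohorts observed for different spans stay comparable.
The retention rate at day *n* is
`R(n) = #{i : max(D_i) ≥ n} / N`, and the inactivity CCDF is fit as
`log P(gap ≥ n) ≈ −α log n` (variance-stabilized least squares; the
discrete zeta MLE is reported on the same CCDF-slope scale as α\_MLE − 1).

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(simulate → funnel → metrics → comparison), writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_funnel.R
Rscript analysis/03_engagement_metrics.R
Rscript analysis/04_cohort_compare.R
```

`02_funnel.R` prints, for the simulated arms and for the published counts
run through the same code path:

```
simulated conversion: original 56.0%, seamless 74.3%
published counts reproduce: 53.9 (328/608) and 74.6 (359/481)
```

i.e. the simulated original-journey arm converts near its configured 53.9%
base rate and the deep-linked arm near 74.6%; the `53.9 (328/608)` cell is
`conversion_rate()` applied to a fixture realizing the published
registered/activated counts. `03_engagement_metrics.R` reports, per
cohort, the headline usage statistic and the inactivity tail, e.g.

```
reminders_without (n=194): P(max DA run >= 3) = 0.24, max run 6 d, max gap 49 d, max series 15
reminders_without inactivity slope: 0.971 (loglog_ls, r^2=0.968); 0.738 (discrete MLE)
```

— the fitted slope sits near the configured gap exponent of 0.96. And
`04_cohort_compare.R` prints the retention table (rows cohort × series,
cells `pct (num/denom)`) and the day-30 contrast, on simulated data:

```
day-30 DA retention: with 14.0% vs without 3.1%
```

showing the reminder effect the simulator encodes: longer streaks and a
halved dropout hazard lift day-30 retention several-fold, while the
inactivity-gap distribution stays comparable between cohorts.

Programmatic use mirrors the scripts:

```r
library(dhengage)
sim <- simulate_study(simulation_config(seed = 1, n_registrants = 500))
log <- validate_log(sim$registry, sim$events)
report <- compare_cohorts(log, analysis_config())
render_retention_table(report)
```

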