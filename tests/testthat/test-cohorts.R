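two_period_log <- function() {
  reg <- participant_registry(
    participant_id = c("both", "gap_only", "early", "late", "non_ms"),
    registration_date = as.Date("2019-01-01"),
    consent_date = as.Date("2019-01-01"),
    activation_date = as.Date("2019-01-02"),
    ms_status = c("MS", "MS", "MS", "MS", "non_MS")
  )
  ev <- event_log(
    participant_id = c("both", "both", "gap_only", "early", "late", "non_ms"),
    test = "TwoMWT",
    timestamp = as.Date(c("2019-03-01", "2020-06-01", "2019-12-15",
                          "2019-05-01", "2021-01-01", "2019-05-01"))
  )
  validate_log(reg, ev)
}

test_that("activity-window assignment handles dual membership and the gap", {
  log <- two_period_log()
  asg <- assign_cohorts(log, cohort_preset("reminders"))
  without <- asg$participant_id[asg$cohort == "reminders_without"]
  with_ <- asg$participant_id[asg$cohort == "reminders_with"]
  expect_setequal(without, c("both", "early"))
  expect_setequal(with_, c("both", "late"))
  # active only between the windows: member of neither
  expect_false("gap_only" %in% asg$participant_id)
  # reminder cohorts are restricted to MS participants
  expect_false("non_ms" %in% without)
})

test_that("cohort clipping equals a brute-force date filter", {
  cfg <- simulation_config(n_registrants = 120, seed = 23)
  sim <- simulate_study(cfg)
  log <- validate_log(sim$registry, sim$events)
  w <- cohort_preset("reminders")$reminders_without
  asg <- assign_cohorts(log, list(w))
  sub <- dhengage:::clip_cohort_log(log, asg, w$label, analysis_config())
  ev <- tibble::as_tibble(log$events)
  d <- as.Date(ev$timestamp, tz = "UTC")
  manual <- ev[ev$participant_id %in% asg$participant_id &
                 d >= w$start_date & d <= w$end_date, ]
  expect_equal(tibble::as_tibble(sub$events), manual, ignore_attr = TRUE)
})

test_that("duplicate cohort labels are rejected", {
  log <- two_period_log()
  w <- cohort_window("same", "2019-01-01", "2019-06-30")
  expect_error(assign_cohorts(log, list(w, w)), class = "dhengage_config_error")
})

test_that("identical windows produce identical curves (null comparison)", {
  cfg <- simulation_config(n_registrants = 80, seed = 24)
  sim <- simulate_study(cfg)
  log <- validate_log(sim$registry, sim$events)
  ac <- analysis_config(cohort_windows = list(
    cohort_window("one", "2018-11-12", "2019-10-20", ms_only = TRUE),
    cohort_window("two", "2018-11-12", "2019-10-20", ms_only = TRUE)
  ))
  rep <- compare_cohorts(log, ac)
  for (s in c("DA", "DAx", "TwoMWT")) {
    m1 <- rep$cohorts$one$metrics[[s]]
    m2 <- rep$cohorts$two$metrics[[s]]
    expect_equal(tibble::as_tibble(m1$retention), tibble::as_tibble(m2$retention))
    expect_equal(tibble::as_tibble(m1$inactivity), tibble::as_tibble(m2$inactivity))
  }
})

test_that("every DA metric curve is dominated by its DAx counterpart", {
  cfg <- simulation_config(n_registrants = 200, seed = 25)
  sim <- simulate_study(cfg)
  log <- validate_log(sim$registry, sim$events)
  rep <- compare_cohorts(log, analysis_config())
  for (label in names(rep$cohorts)) {
    co <- rep$cohorts[[label]]
    if (isTRUE(co$empty)) next
    da <- co$metrics$DA; dax <- co$metrics$DAx
    ns <- unique(c(da$completion$n, dax$completion$n))
    expect_true(all(ccdf_prob(da$completion, ns) <= ccdf_prob(dax$completion, ns)))
    expect_true(all(da$retention$fraction <=
                      dax$retention$fraction[seq_len(nrow(da$retention))] + 1e-12))
  }
})

test_that("the report bundle is byte-identical across reruns", {
  cfg <- simulation_config(n_registrants = 60, seed = 26)
  sim <- simulate_study(cfg)
  log <- validate_log(sim$registry, sim$events)
  rep <- compare_cohorts(log, analysis_config())
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep, d1)
  write_report(rep, d2)
  for (f in c("curves.csv", "retention_curves.csv", "retention_table.csv",
              "funnel.json", "config.yml", "report.log")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_true(file.exists(file.path(d1, "manifest.json")))
})

test_that("the rendered retention table reproduces the published cells", {
  fw <- fixture_without_cohort()
  fn <- fixture_with_cohort()
  reg <- participant_registry(
    participant_id = c(fw$registry$participant_id, fn$registry$participant_id),
    registration_date = c(fw$registry$registration_date, fn$registry$registration_date),
    consent_date = c(fw$registry$consent_date, fn$registry$consent_date),
    activation_date = c(fw$registry$activation_date, fn$registry$activation_date),
    ms_status = "MS"
  )
  ev <- event_log(
    c(fw$events$participant_id, fn$events$participant_id),
    c(fw$events$test, fn$events$test),
    c(fw$events$timestamp, fn$events$timestamp)
  )
  log <- validate_log(reg, ev)
  rep <- compare_cohorts(log, analysis_config(cohort_windows = cohort_preset("reminders")))
  tab <- render_retention_table(rep)
  cell <- function(cohort, series, day) {
    tab[[paste0("day_", day)]][tab$cohort == cohort & tab$series == series]
  }
  expect_equal(cell("reminders_without", "DA", 30), "9.7 (34/350)")
  expect_equal(cell("reminders_without", "DAx", 30), "17.1 (60/350)")
  expect_equal(cell("reminders_without", "TwoMWT", 30), "6.3 (22/350)")
  expect_equal(cell("reminders_with", "DA", 30), "30.8 (53/172)")
  expect_equal(cell("reminders_with", "DAx", 30), "30.8 (53/172)")
  expect_equal(cell("reminders_with", "TwoMWT", 30), "22.7 (39/172)")
  expect_equal(cell("reminders_without", "DA", 1), "61.7 (216/350)")
  expect_equal(cell("reminders_with", "DA", 1), "65.7 (113/172)")
})

test_that("empty cohorts and out-of-span days are marked censored", {
  log <- two_period_log()
  ac <- analysis_config(cohort_windows = list(
    cohort_window("nobody", "2030-01-01", "2030-02-01"),
    cohort_window("short", "2019-01-01", "2019-01-10")
  ))
  rep <- compare_cohorts(log, ac)
  tab <- render_retention_table(rep, days = c(1, 30))
  expect_true(all(tab$day_1[tab$cohort == "nobody"] == "censored"))
  # the short window ends 8 days after activation: day 30 is unobservable
  expect_true(all(tab$day_30[tab$cohort == "short"] == "censored"))
})

test_that("funnel sections appear for registration-assigned cohorts", {
  cfg <- simulation_config(n_registrants = 60, seed = 27)
  sim <- simulate_study(cfg)
  log <- validate_log(sim$registry, sim$events)
  rep <- compare_cohorts(log, analysis_config())
  expect_setequal(names(rep$funnels), c("journey_original", "journey_seamless"))
  d <- withr::local_tempdir()
  write_report(rep, d)
  fj <- jsonlite::read_json(file.path(d, "funnel.json"))
  expect_setequal(names(fj), c("journey_original", "journey_seamless"))
  expect_true(all(c("registered", "consented", "activated") %in%
                    names(fj$journey_original)))
})
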