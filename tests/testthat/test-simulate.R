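test_that("simulation is fully reproducible under a fixed seed", {
  cfg <- simulation_config(n_registrants = 80, seed = 31)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(tibble::as_tibble(a$registry), tibble::as_tibble(b$registry))
  expect_identical(tibble::as_tibble(a$events), tibble::as_tibble(b$events))
  expect_identical(a$notifications, b$notifications)

  c2 <- simulate_study(simulation_config(n_registrants = 80, seed = 32))
  expect_false(identical(tibble::as_tibble(a$events), tibble::as_tibble(c2$events)))
})

test_that("zero registrants yield an empty but valid dataset", {
  cfg <- simulation_config(n_registrants = 0, seed = 1)
  sim <- simulate_study(cfg)
  expect_equal(nrow(sim$registry), 0)
  expect_equal(nrow(sim$events), 0)
  log <- validate_log(sim$registry, sim$events)
  expect_equal(nrow(log$quarantine), 0)
})

test_that("a unit deep-link effect makes the journeys draw identically", {
  cfg <- simulation_config(n_registrants = 500, deep_link_effect = 1)
  a <- simulate_funnel(cfg, "original", seed = 4)
  b <- simulate_funnel(cfg, "seamless", seed = 4)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("funnel arms converge to the configured conversion rates", {
  cfg <- simulation_config(n_registrants = 5000)
  orig <- simulate_funnel(cfg, "original", seed = 101)
  seam <- simulate_funnel(cfg, "seamless", seed = 102)
  rate <- function(reg) mean(!is.na(reg$activation_date))
  expect_lt(abs(100 * rate(orig) - 53.9), 2)
  expect_lt(abs(100 * rate(seam) - 74.6), 2)
})

test_that("degenerate streak parameter gives only single-day runs", {
  cfg <- simulation_config(streak_continue_p = 0, p_dax_given_active = 1,
                           p_da_given_active = 1)
  reg <- fixture_funnel_registry(60, 60, start_date = as.Date("2019-01-01"))
  ev <- simulate_behavior(reg, cfg, horizon_date = as.Date("2019-12-01"),
                          seed = 12)
  log <- validate_log(reg, ev)
  comp <- sessionize(log)
  s <- run_gap_summaries(comp, reg, "DAx")
  expect_true(all(unlist(s$run_lengths) == 1))
})

test_that("the generated gap multiset carries the configured CCDF slope", {
  set.seed(44)
  g <- rdiscrete_powerlaw(20000, 0.96)
  cur <- inactivity_ccdf(summaries_from_gaps(g))
  fit <- fit_powerlaw(cur, xmin = 1, method = "loglog_ls")
  expect_lt(abs(fit$alpha - 0.96), 0.05)
})

test_that("with certain series draws, sessionization recovers the active days", {
  cfg <- simulation_config(p_da_given_active = 1, p_dax_given_active = 1)
  reg <- fixture_funnel_registry(40, 40, start_date = as.Date("2019-01-01"),
                                 ms_status = "MS")
  ev <- simulate_behavior(reg, cfg, horizon_date = as.Date("2019-10-01"),
                          seed = 13)
  log <- validate_log(reg, ev)
  prof <- build_daily_profiles(log)
  comp <- sessionize(log)
  for (s in c("DA", "DAx")) {
    got <- comp[comp$series == s, c("participant_id", "date")]
    got <- got[order(got$participant_id, got$date), ]
    expect_equal(got, prof[, c("participant_id", "date")], ignore_attr = TRUE)
  }
})

test_that("day-30 retention matches the exact renewal-process recursion", {
  cfg <- simulation_config(p_dax_given_active = 1, p_da_given_active = 1,
                           streak_continue_p = 0.5, p_return = 0.55,
                           dropout_hazard = 0.01, gap_exponent = 0.96)
  n <- 2500
  reg <- fixture_funnel_registry(n, n, start_date = as.Date("2019-01-01"),
                                 ms_status = "MS")
  ev <- simulate_behavior(reg, cfg, horizon_date = as.Date("2026-01-01"),
                          seed = 14)
  comp <- sessionize(validate_log(reg, ev))
  ret <- retention_curve(comp, reg, "DAx")
  observed <- ret$fraction[ret$day == 30]
  expected <- oracle_retention_phi(30, s = 0.5, p_return = 0.55,
                                   a = 0.96, h = 0.01)
  expect_lt(abs(100 * observed - 100 * expected), 3)
})

test_that("a null reminder effect leaves behavior unchanged at a fixed seed", {
  cfg_off <- simulation_config(
    reminder_effect = list(streak_continue_multiplier = 1,
                           dropout_hazard_multiplier = 1, p_2mwt_uplift = 0),
    notifications_enabled = FALSE
  )
  cfg_on <- cfg_off
  cfg_on$notifications_enabled <- TRUE
  reg <- fixture_funnel_registry(50, 50, start_date = as.Date("2019-01-01"))
  a <- simulate_behavior(reg, cfg_off, horizon_date = as.Date("2019-06-01"),
                         seed = 15)
  b <- simulate_behavior(reg, cfg_on, horizon_date = as.Date("2019-06-01"),
                         seed = 15)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("the reminder effect lifts day-30 retention in the full study", {
  cfg <- simulation_config(n_registrants = 400, seed = 16)
  sim <- simulate_study(cfg)
  log <- validate_log(sim$registry, sim$events)
  rep <- compare_cohorts(log, analysis_config())
  ret_with <- rep$cohorts$reminders_with$metrics$DA$retention
  ret_without <- rep$cohorts$reminders_without$metrics$DA$retention
  expect_gt(ret_with$fraction[ret_with$day == 30],
            ret_without$fraction[ret_without$day == 30])
})

test_that("notification policy respects the daily cap and the 7 PM rule", {
  cfg <- simulation_config(n_registrants = 150, seed = 17,
                           notifications_enabled = TRUE)
  sim <- simulate_study(cfg)
  notes <- sim$notifications
  expect_gt(nrow(notes), 0)
  per_day <- table(paste(notes$participant_id, as.Date(notes$timestamp, tz = "UTC")))
  expect_lte(max(per_day), 2)
  tod <- as.numeric(format(notes$timestamp, "%H", tz = "UTC")) * 60 +
    as.numeric(format(notes$timestamp, "%M", tz = "UTC"))
  expect_true(all(tod <= 19 * 60))
})

test_that("an evening abandonment is notified at the 7 PM cap, not later", {
  cfg <- simulation_config(notifications_enabled = TRUE)
  ev <- event_log("p", c("DMQ", "IPSDD"),
                  as.POSIXct(c("2020-03-02 17:50:00", "2020-03-02 18:00:00"),
                             tz = "UTC"))
  notes <- simulate_notifications(ev, cfg)
  incomplete <- notes[notes$kind == "incomplete_daily", ]
  expect_equal(nrow(incomplete), 1)
  expect_equal(format(incomplete$timestamp, "%H:%M", tz = "UTC"), "19:00")
})

test_that("fully adherent days trigger no reengagement notifications", {
  cfg <- simulation_config(notifications_enabled = TRUE)
  all8 <- c("DMQ", "IPS", "IPSDD", "PT", "DaS", "SBT", "UTT", "TwoMWT")
  days <- as.Date("2020-03-01") + 0:6
  ev <- event_log(
    participant_id = rep("p", length(days) * 8),
    test = rep(all8, length(days)),
    timestamp = as.POSIXct(rep(paste(days, "09:00:00"), each = 8), tz = "UTC") +
      rep(120 * (0:7), length(days))
  )
  notes <- simulate_notifications(ev, cfg)
  expect_true(all(notes$kind %in% c("encouragement_streak", "acknowledgment")))
  expect_gt(sum(notes$kind == "encouragement_streak"), 0)
})

test_that("simulated datasets round-trip through disk unchanged", {
  cfg <- simulation_config(n_registrants = 25, seed = 18,
                           notifications_enabled = TRUE)
  sim <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_simulated_dataset(sim, dir)
  expect_setequal(list.files(dir),
                  c("registry.csv", "events.csv", "notifications.csv",
                    "scenario.yml"))
  reg2 <- read_registry(file.path(dir, "registry.csv"))
  ev2 <- read_event_log(file.path(dir, "events.csv"))
  expect_equal(tibble::as_tibble(reg2), tibble::as_tibble(sim$registry),
               ignore_attr = TRUE)
  expect_equal(nrow(ev2), nrow(sim$events))
  scen <- yaml::read_yaml(file.path(dir, "scenario.yml"))
  expect_equal(scen$seed, 18)
})
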