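test_that("runs and gaps match hand-traced cases", {
  comp <- completions_from_days(list(p = c(1, 2, 3, 7)))
  rg <- runs_and_gaps(comp, registry_for("p"), "p", "DA")
  expect_equal(rg$runs$length, c(3L, 1L))
  expect_equal(rg$runs$start_day, c(1L, 7L))
  expect_equal(rg$gaps, 3L)

  single <- runs_and_gaps(completions_from_days(list(p = 5)),
                          registry_for("p"), "p", "DA")
  expect_equal(single$runs$length, 1L)
  expect_length(single$gaps, 0)

  none <- runs_and_gaps(completions_from_days(list(q = 1)),
                        registry_for(c("p", "q")), "p", "DA")
  expect_equal(nrow(none$runs), 0)
})

test_that("runs and gaps equal the brute-force scan on 200 random patterns", {
  set.seed(77)
  for (i in 1:200) {
    days <- random_day_pattern(max_day = sample(c(10, 60, 300), 1))
    comp <- completions_from_days(list(p = days))
    rg <- runs_and_gaps(comp, registry_for("p"), "p", "DA")
    o <- oracle_runs_gaps(days)
    expect_equal(rg$runs$length, o$run_lengths)
    expect_equal(rg$gaps, o$gaps)
    # conservation: active days + gap days span the observation exactly
    expect_equal(sum(rg$runs$length) + sum(rg$gaps),
                 max(days) - min(days) + 1L)
  }
})

test_that("activity beyond the truncation horizon is discarded and flagged", {
  cfg <- analysis_config(truncation_days = 343)
  comp <- completions_from_days(list(p = c(0, 1, 342, 343, 400)))
  s <- run_gap_summaries(comp, registry_for("p"), "DA", cfg)
  expect_equal(s$n_active, 3L)
  expect_equal(s$truncated_at, 343L)
  s2 <- run_gap_summaries(completions_from_days(list(p = c(0, 1))),
                          registry_for("p"), "DA", cfg)
  expect_true(is.na(s2$truncated_at))
})

test_that("usage CCDF over participant max runs gives the headline fraction", {
  # 10 participants, 3 with a longest run of >= 3 consecutive days
  day_sets <- c(
    lapply(1:3, function(i) 0:(2 + i)),
    lapply(4:10, function(i) c(0, 2, 4))
  )
  names(day_sets) <- paste0("p", 1:10)
  comp <- completions_from_days(day_sets)
  s <- run_gap_summaries(comp, registry_for(paste0("p", 1:10)), "DA")
  cur <- usage_ccdf(s, unit = "participant_max_run")
  expect_equal(ccdf_prob(cur, 3), 0.30)
  expect_equal(ccdf_prob(cur, 1), 1)

  # all runs of length one
  s1 <- run_gap_summaries(completions_from_days(list(a = c(0, 2), b = 4)),
                          registry_for(c("a", "b")), "DA")
  cur1 <- usage_ccdf(s1, unit = "participant_max_run")
  expect_equal(ccdf_prob(cur1, 1), 1)
  expect_equal(ccdf_prob(cur1, 2), 0)
})

test_that("pooled-episode usage CCDF equals direct counting", {
  set.seed(5)
  day_sets <- lapply(1:30, function(i) random_day_pattern(50))
  names(day_sets) <- paste0("p", 1:30)
  comp <- completions_from_days(day_sets)
  s <- run_gap_summaries(comp, registry_for(names(day_sets)), "DA")
  cur <- usage_ccdf(s, unit = "pooled_episodes")
  all_runs <- unlist(lapply(day_sets, function(d) oracle_runs_gaps(d)$run_lengths))
  for (n in sort(unique(all_runs))) {
    expect_equal(ccdf_prob(cur, n), mean(all_runs >= n))
  }
})

test_that("inactivity CCDF pools gaps across participants", {
  cur <- inactivity_ccdf(summaries_from_gaps(c(1, 1, 2)))
  expect_equal(ccdf_prob(cur, 1), 1)
  expect_equal(ccdf_prob(cur, 2), 1 / 3)

  # nobody ever pauses: degenerate empty curve
  cur0 <- inactivity_ccdf(summaries_from_gaps(integer()))
  expect_equal(nrow(cur0), 0)
  expect_equal(ccdf_prob(cur0, 1), 0)

  set.seed(6)
  day_sets <- lapply(1:25, function(i) random_day_pattern(80))
  names(day_sets) <- paste0("p", 1:25)
  comp <- completions_from_days(day_sets)
  s <- run_gap_summaries(comp, registry_for(names(day_sets)), "DA")
  cur2 <- inactivity_ccdf(s)
  pooled <- unlist(lapply(day_sets, function(d) oracle_runs_gaps(d)$gaps))
  for (n in sort(unique(pooled))) {
    expect_equal(ccdf_prob(cur2, n), mean(pooled >= n))
  }
})

test_that("log-log fit is exact on pure power-law curves", {
  n <- 1:50
  f96 <- fit_powerlaw(ccdf_curve(n, n^(-0.96)), xmin = 1, method = "loglog_ls")
  expect_equal(f96$alpha, 0.96, tolerance = 1e-9)
  expect_equal(f96$goodness, 1, tolerance = 1e-9)

  f2 <- fit_powerlaw(ccdf_curve(n, n^(-2)), xmin = 1, method = "loglog_ls")
  expect_equal(f2$alpha, 2, tolerance = 1e-9)

  expect_error(fit_powerlaw(ccdf_curve(1:2, c(1, 0.5))),
               class = "dhengage_fit_error")
})

test_that("discrete MLE recovers the exponent of true zeta draws", {
  set.seed(19)
  x <- oracle_rzeta(20000, s = 2.5)
  cur <- inactivity_ccdf(summaries_from_gaps(x))
  fit <- fit_powerlaw(cur, xmin = 1, method = "discrete_mle")
  # reported on the CCDF-slope scale: density exponent minus one
  expect_equal(fit$alpha, 1.5, tolerance = 0.05)
  expect_lt(fit$goodness, 0.02)
})

test_that("completion-rate curve counts participants with at least n series", {
  fix <- fixture_without_cohort()
  comp <- sessionize(validate_log(fix$registry, fix$events))
  cur <- completion_rate_curve(comp, fix$registry, "DA")
  expect_equal(ccdf_prob(cur, 1), 234 / 350)
  expect_equal(round_half_up(100 * ccdf_prob(cur, 1), 1), 66.9)

  # nobody completes anything
  no_comp <- tibble::tibble(participant_id = character(),
                            date = as.Date(character()), series = character())
  empty <- completion_rate_curve(no_comp, registry_for(c("a", "b")), "DA")
  expect_equal(ccdf_prob(empty, 1), 0)

  # random fixture vs sort-and-count oracle
  set.seed(8)
  day_sets <- lapply(1:40, function(i) random_day_pattern(40))
  names(day_sets) <- paste0("p", 1:40)
  compr <- completions_from_days(day_sets)
  curr <- completion_rate_curve(compr, registry_for(names(day_sets)), "DA")
  counts <- sort(vapply(day_sets, length, integer(1)), decreasing = TRUE)
  for (n in 1:max(counts)) {
    expect_equal(ccdf_prob(curr, n), sum(counts >= n) / 40)
  }
})

test_that("retention curve is the CCDF of the last active day", {
  # participant active only on the activation day
  comp <- completions_from_days(list(p = 0))
  ret <- retention_curve(comp, registry_for("p"), "DA", days = 0:1)
  expect_equal(ret$fraction[ret$day == 0], 1)
  expect_equal(ret$fraction[ret$day == 1], 0)

  set.seed(9)
  day_sets <- lapply(1:50, function(i) random_day_pattern(45))
  names(day_sets) <- paste0("p", 1:50)
  compr <- completions_from_days(day_sets)
  reg <- registry_for(names(day_sets))
  ret2 <- retention_curve(compr, reg, "DA")
  expect_true(all(diff(ret2$fraction) <= 0))
  tab <- series_day_table(compr, reg, "DA")
  for (n in c(0, 1, 5, 20, 45)) {
    expect_equal(ret2$retained[ret2$day == n],
                 oracle_retention(tab, names(day_sets), n))
  }
})

test_that("day-1 retention never exceeds the >=1-series completion rate", {
  set.seed(10)
  for (i in 1:10) {
    day_sets <- lapply(1:30, function(j) random_day_pattern(30, p_active = 0.15))
    names(day_sets) <- paste0("p", 1:30)
    compr <- completions_from_days(day_sets)
    reg <- registry_for(names(day_sets))
    ret <- retention_curve(compr, reg, "DA")
    cur <- completion_rate_curve(compr, reg, "DA")
    r1 <- ret$fraction[ret$day == 1]
    if (length(r1) == 0) r1 <- 0
    expect_lte(r1, ccdf_prob(cur, 1))
  }
})

test_that("retention fixtures reproduce the published day-1 rates", {
  fix <- fixture_without_cohort()
  comp <- sessionize(validate_log(fix$registry, fix$events))
  ret <- retention_curve(comp, fix$registry, "DA")
  expect_equal(round_half_up(100 * ret$fraction[ret$day == 1], 1), 61.7)
  retx <- retention_curve(comp, fix$registry, "DAx")
  expect_equal(retx$retained[retx$day == 1], 290)
})

test_that("the alternative exact-day retention definition is available", {
  comp <- completions_from_days(list(p = c(0, 5), q = c(0, 1)))
  cfg <- analysis_config(retention_definition = "active_exactly_day_n")
  ret <- retention_curve(comp, registry_for(c("p", "q")), "DA", cfg,
                         days = c(0, 1, 5))
  expect_equal(ret$retained, c(2L, 1L, 1L))
})
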