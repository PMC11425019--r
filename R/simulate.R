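# Stochastic user-behavior simulator: activation funnel, alternating
# streak/gap renewal process with heavy-tailed gaps, coupled series draws,
# and the notification-policy engine. Generates datasets with the same
# schema the analysis consumes, so every stage is testable without the
# study's data.

#' Simulation configuration
#'
#' Full parameterization of the synthetic funnel and behavior generator.
#' Defaults encode the study conditions: the original-journey conversion
#' rate as the base activation probability, a deep-link odds ratio chosen so
#' the seamless journey converts at the reported rate, a 48-hour activation
#' code, geometric streaks, discrete power-law gaps with CCDF slope 0.96,
#' and a reminder effect that lengthens streaks, halves abandonment and
#' uplifts walk-test uptake.
#'
#' @param seed integer seed; fixed seed gives fully reproducible output
#' @param n_registrants registrants per simulated arm
#' @param p_consent probability a registrant completes e-consent (the
#'   consent step is part of the registration flow, so default 1)
#' @param p_activate_base activation probability under the original journey
#' @param deep_link_effect multiplicative odds factor on activation under
#'   the seamless (deep-linked) journey
#' @param activation_code_expiry_h activation-code validity in hours;
#'   activation delays are drawn inside this window
#' @param start_date first registration date of the simulated study
#' @param study_span_days calendar span of the simulated study
#' @param registration_span_days span over which registrations are drawn
#'   (default: the whole study span)
#' @param streak_continue_p per-day probability an active streak continues
#'   (streak lengths are geometric)
#' @param gap_exponent CCDF slope of the discrete power-law gap lengths
#' @param p_return probability a participant returns after a streak ends
#'   (otherwise they abandon permanently)
#' @param dropout_hazard per-day probability of permanent abandonment while
#'   waiting out a gap
#' @param p_da_given_active per-active-day probability of a full DA series
#' @param p_dax_given_active per-active-day probability of a DAx series
#'   (must be >= `p_da_given_active`; DA days are drawn as sub-events of DAx
#'   days so the DA-subset invariant holds by construction)
#' @param p_2mwt_given_active per-active-day probability of a 2MWT
#' @param p_ms probability an activated participant self-declares MS
#' @param p_ios probability of the iOS platform
#' @param reminder_effect list with `streak_continue_multiplier`,
#'   `dropout_hazard_multiplier`, `p_2mwt_uplift`; applied when
#'   notifications are enabled
#' @param notifications_enabled whether the reminder effect and notification
#'   engine are active
#' @return a `simulation_config` list
#' @export
simulation_config <- function(seed = 20181112L,
                              n_registrants = 600L,
                              p_consent = 1,
                              p_activate_base = 0.539,
                              deep_link_effect = 2.5124,
                              activation_code_expiry_h = 48,
                              start_date = as.Date("2018-11-12"),
                              study_span_days = 1086L,
                              registration_span_days = NULL,
                              streak_continue_p = 0.5,
                              gap_exponent = 0.96,
                              p_return = 0.55,
                              dropout_hazard = 0.01,
                              p_da_given_active = 0.70,
                              p_dax_given_active = 0.85,
                              p_2mwt_given_active = 0.40,
                              p_ms = 0.6,
                              p_ios = 0.8,
                              reminder_effect = list(
                                streak_continue_multiplier = 1.6,
                                dropout_hazard_multiplier = 0.5,
                                p_2mwt_uplift = 0.10
                              ),
                              notifications_enabled = FALSE) {
  probs <- c(p_consent = p_consent, p_activate_base = p_activate_base,
             p_return = p_return, dropout_hazard = dropout_hazard,
             streak_continue_p = streak_continue_p,
             p_da_given_active = p_da_given_active,
             p_dax_given_active = p_dax_given_active,
             p_2mwt_given_active = p_2mwt_given_active,
             p_ms = p_ms, p_ios = p_ios)
  if (any(probs < 0 | probs > 1)) {
    stop_dhengage(
      sprintf("probabilities out of [0,1]: %s",
              paste(names(probs)[probs < 0 | probs > 1], collapse = ", ")),
      "dhengage_config_error"
    )
  }
  if (p_da_given_active > p_dax_given_active) {
    stop_dhengage("p_da_given_active must be <= p_dax_given_active",
                  "dhengage_config_error")
  }
  if (gap_exponent <= 0) {
    stop_dhengage("gap_exponent must be positive", "dhengage_config_error")
  }
  if (deep_link_effect <= 0) {
    stop_dhengage("deep_link_effect must be positive", "dhengage_config_error")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_registrants = as.integer(n_registrants),
      p_consent = p_consent,
      p_activate_base = p_activate_base,
      deep_link_effect = deep_link_effect,
      activation_code_expiry_h = activation_code_expiry_h,
      start_date = as.Date(start_date),
      study_span_days = as.integer(study_span_days),
      registration_span_days = as.integer(registration_span_days %||% study_span_days),
      streak_continue_p = streak_continue_p,
      gap_exponent = gap_exponent,
      p_return = p_return,
      dropout_hazard = dropout_hazard,
      p_da_given_active = p_da_given_active,
      p_dax_given_active = p_dax_given_active,
      p_2mwt_given_active = p_2mwt_given_active,
      p_ms = p_ms,
      p_ios = p_ios,
      reminder_effect = reminder_effect,
      notifications_enabled = notifications_enabled
    ),
    class = "simulation_config"
  )
}

#' Simulate the registration -> consent -> activation funnel
#'
#' Registrants consent with `p_consent` (e-consent is part of the
#' registration flow); consenters activate with `p_activate_base`, with the
#' odds multiplied by `deep_link_effect` under the seamless journey.
#' Activation delays are drawn uniformly within the activation-code validity
#' window; non-activators stall at code expiry and leave no activation date.
#'
#' @param config a [simulation_config()]
#' @param journey `"original"` or `"seamless"`
#' @param n number of registrants (default `config$n_registrants`)
#' @param id_prefix prefix for generated participant ids
#' @param seed optional seed; `NULL` uses the current RNG state
#' @return a `participant_registry`
#' @export
simulate_funnel <- function(config, journey = c("original", "seamless"),
                            n = config$n_registrants, id_prefix = "P",
                            seed = NULL) {
  journey <- match.arg(journey)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    return(participant_registry(character(), as.Date(character())))
  }
  p_act <- config$p_activate_base
  if (journey == "seamless") {
    odds <- p_act / (1 - p_act) * config$deep_link_effect
    p_act <- odds / (1 + odds)
  }
  reg_date <- config$start_date +
    floor(runif(n) * config$registration_span_days)
  consented <- runif(n) < config$p_consent
  consent_date <- as.Date(ifelse(consented, reg_date, NA), origin = "1970-01-01")
  activated <- consented & runif(n) < p_act
  delay_days <- floor(runif(n) * config$activation_code_expiry_h / 24)
  activation_date <- as.Date(ifelse(activated, consent_date + delay_days, NA),
                             origin = "1970-01-01")
  ms <- ifelse(activated, ifelse(runif(n) < config$p_ms, "MS", "non_MS"), "unknown")
  participant_registry(
    participant_id = sprintf("%s%05d", id_prefix, seq_len(n)),
    registration_date = reg_date,
    consent_date = consent_date,
    activation_date = activation_date,
    ms_status = ms,
    platform = ifelse(runif(n) < config$p_ios, "ios", "android")
  )
}

# effective behavior parameters once the reminder effect is applied
effective_behavior_params <- function(config) {
  s <- config$streak_continue_p
  h <- config$dropout_hazard
  p2 <- config$p_2mwt_given_active
  if (isTRUE(config$notifications_enabled)) {
    re <- config$reminder_effect
    s <- min(s * re$streak_continue_multiplier, 0.99)
    h <- min(h * re$dropout_hazard_multiplier, 1)
    p2 <- min(p2 + re$p_2mwt_uplift, 1)
  }
  list(streak_continue_p = s, dropout_hazard = h, p_2mwt = p2)
}

#' Simulate test-completion behavior for activated participants
#'
#' Each activated participant follows an alternating renewal process from
#' activation day (day 0): active streaks whose lengths are geometric with
#' continuation probability `streak_continue_p`; at every streak end the
#' participant abandons permanently with probability `1 - p_return`,
#' otherwise draws a gap from the discrete power law with CCDF slope
#' `gap_exponent` and survives it with probability
#' `(1 - dropout_hazard)^gap`. On each active day, a DAx series is completed
#' with `p_dax_given_active` and, conditional on that, a full DA series with
#' `p_da_given_active / p_dax_given_active` (so DA days are a subset of DAx
#' days by construction); the 2MWT is drawn independently. Active days with
#' no series draw still emit the mood question (an opened-but-abandoned
#' session). IPS is emitted at most weekly, which always keeps it inside the
#' trailing weekly-credit window of the series detector.
#'
#' @param registry `participant_registry`; only rows with an activation date
#'   generate events
#' @param config a [simulation_config()]; the reminder effect applies iff
#'   `notifications_enabled`
#' @param horizon_date last calendar day that can generate events (default
#'   end of the simulated study)
#' @param seed optional seed; `NULL` uses the current RNG state
#' @return an `event_log`
#' @export
simulate_behavior <- function(registry, config, horizon_date = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  horizon_date <- as.Date(horizon_date %||%
                            (config$start_date + config$study_span_days - 1L))
  par <- effective_behavior_params(config)
  reg <- tibble::as_tibble(registry)
  reg <- reg[!is.na(reg$activation_date), , drop = FALSE]
  out_pid <- character(); out_test <- character(); out_ts <- numeric()
  for (i in seq_len(nrow(reg))) {
    pid <- reg$participant_id[i]
    act <- reg$activation_date[i]
    horizon <- as.integer(horizon_date - act)
    if (horizon < 0) next
    active_days <- integer()
    t <- 0L
    repeat {
      k <- 1L + rgeom(1, 1 - par$streak_continue_p)
      active_days <- c(active_days, t:min(t + k - 1L, horizon))
      t <- t + k
      if (t > horizon) break
      if (runif(1) >= config$p_return) break
      g <- rdiscrete_powerlaw(1, config$gap_exponent)
      if (runif(1) >= (1 - par$dropout_hazard)^g) break
      t <- t + g
      if (t > horizon) break
    }
    last_ips <- -Inf
    for (d in active_days) {
      dax <- runif(1) < config$p_dax_given_active
      da <- dax && runif(1) < config$p_da_given_active / config$p_dax_given_active
      two <- runif(1) < par$p_2mwt
      tests <- if (da) {
        c("DMQ", "IPSDD", "PT", "DaS", "SBT", "UTT")
      } else if (dax) {
        c("DMQ", "IPSDD", "PT", "DaS")
      } else {
        "DMQ"
      }
      if (dax && d - last_ips >= 7) {
        tests <- c(tests, "IPS")
        last_ips <- d
      }
      if (two) tests <- c(tests, "TwoMWT")
      base <- as.POSIXct(as.character(act + d), tz = "UTC") +
        (8 + floor(runif(1) * 10)) * 3600 + floor(runif(1) * 60) * 60
      ts <- base + 120 * (seq_along(tests) - 1)
      out_pid <- c(out_pid, rep(pid, length(tests)))
      out_test <- c(out_test, tests)
      out_ts <- c(out_ts, as.numeric(ts))
    }
  }
  event_log(out_pid, out_test,
            as.POSIXct(out_ts, origin = "1970-01-01", tz = "UTC"))
}

#' Simulate the push-notification policy
#'
#' Applies the notification trigger rules to the simulated day timelines:
#' * reengagement notifications (incomplete daily activities, completed only
#'   the daily activities, completed only the 2MWT) fire 4 hours after the
#'   day's last completed test, capped at 7 PM; nothing fires if the session
#'   already ran past 7 PM;
#' * an encouragement fires at 10 AM the day after 3 consecutive active
#'   days, at most twice per week;
#' * a lapse encouragement fires at 10 AM after 3 consecutive inactive days;
#' * an acknowledgment fires every 14 days at 6 PM while the participant is
#'   still active.
#'
#' Globally, at most 2 notifications per participant per day and none after
#' 7 PM. Notifications are descriptive output only: they do not feed back
#' into behavior (the reminder effect is parameterized instead).
#'
#' @param events an `event_log` of completed tests
#' @param config a [simulation_config()]; returns an empty table unless
#'   `notifications_enabled`
#' @return tibble (participant_id, timestamp, kind)
#' @export
simulate_notifications <- function(events, config) {
  empty <- tibble::tibble(participant_id = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          kind = character())
  if (!isTRUE(config$notifications_enabled)) return(empty)
  ev <- tibble::as_tibble(events)
  if (nrow(ev) == 0) return(empty)
  ev$date <- as.Date(ev$timestamp, tz = "UTC")
  da_tests <- c("DMQ", "IPSDD", "PT", "DaS", "SBT", "UTT")
  days <- ev |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      tests = list(unique(.data$test)),
      last_time = max(.data$timestamp),
      .groups = "drop"
    )
  days$da_done <- vapply(days$tests, function(ts) all(da_tests %in% ts), logical(1))
  days$da_started <- vapply(days$tests, function(ts) any(da_tests %in% ts), logical(1))
  days$two_done <- vapply(days$tests, function(ts) "TwoMWT" %in% ts, logical(1))

  seven_pm <- function(date) as.POSIXct(paste(date, "19:00:00"), tz = "UTC")
  out <- list()
  for (pid in unique(days$participant_id)) {
    pd <- days[days$participant_id == pid, , drop = FALSE]
    pd <- pd[order(pd$date), , drop = FALSE]
    notes <- list()
    # reengagement: one per day, picked by trigger priority
    for (i in seq_len(nrow(pd))) {
      kind <- if (pd$da_started[i] && !pd$da_done[i]) {
        "incomplete_daily"
      } else if (pd$da_done[i] && !pd$two_done[i]) {
        "completed_only_da"
      } else if (pd$two_done[i] && !pd$da_done[i] && !pd$da_started[i]) {
        "completed_only_2mwt"
      } else {
        NA_character_
      }
      if (is.na(kind)) next
      cap <- seven_pm(pd$date[i])
      if (pd$last_time[i] > cap) next
      notes[[length(notes) + 1]] <- tibble::tibble(
        participant_id = pid,
        timestamp = min(pd$last_time[i] + 4 * 3600, cap),
        kind = kind
      )
    }
    d <- as.integer(pd$date - min(pd$date))
    active <- sort(unique(d))
    # encouragement after 3 consecutive active days, <= twice a week
    streak3 <- active[(active - 1L) %in% active & (active - 2L) %in% active]
    sent_weeks <- integer()
    for (s3 in streak3) {
      day_after <- min(pd$date) + s3 + 1L
      wk <- as.integer(s3 %/% 7)
      if (sum(sent_weeks == wk) >= 2) next
      sent_weeks <- c(sent_weeks, wk)
      notes[[length(notes) + 1]] <- tibble::tibble(
        participant_id = pid,
        timestamp = as.POSIXct(paste(day_after, "10:00:00"), tz = "UTC"),
        kind = "encouragement_streak"
      )
    }
    # lapse encouragement after 3 consecutive inactive days
    rg <- runs_gaps_from_days(active)
    if (length(rg$gaps) > 0) {
      run_ends <- rg$run_starts + rg$run_lengths - 1L
      for (j in seq_along(rg$gaps)) {
        if (rg$gaps[j] >= 3) {
          lapse_day <- min(pd$date) + run_ends[j] + 3L + 1L
          notes[[length(notes) + 1]] <- tibble::tibble(
            participant_id = pid,
            timestamp = as.POSIXct(paste(lapse_day, "10:00:00"), tz = "UTC"),
            kind = "encouragement_lapse"
          )
        }
      }
    }
    # acknowledgment every 14 days at 6 PM while still active
    last_active <- max(d)
    ack_days <- if (last_active >= 14L) seq(14L, last_active, by = 14L) else integer()
    if (length(ack_days) > 0) {
      notes[[length(notes) + 1]] <- tibble::tibble(
        participant_id = pid,
        timestamp = as.POSIXct(paste(min(pd$date) + ack_days, "18:00:00"), tz = "UTC"),
        kind = "acknowledgment"
      )
    }
    if (length(notes) == 0) next
    nt <- dplyr::bind_rows(notes)
    nt <- nt[order(nt$timestamp), , drop = FALSE]
    # global caps: never more than 2 per day, never after 7 PM
    nt$day <- as.Date(nt$timestamp, tz = "UTC")
    nt <- nt |>
      dplyr::group_by(.data$day) |>
      dplyr::slice_head(n = 2) |>
      dplyr::ungroup()
    nt <- nt[nt$timestamp <= seven_pm(nt$day), , drop = FALSE]
    nt$day <- NULL
    out[[length(out) + 1]] <- nt
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$participant_id, .data$timestamp)
}

#' Simulate a full two-period study
#'
#' Generates the study structure end to end: an original-journey arm
#' registering before deep linking and a seamless-journey arm registering
#' after, behavior for every activated participant, and notifications for
#' participants activated after the reminders rollout (who also receive the
#' reminder effect on their behavior parameters).
#'
#' @param config a [simulation_config()]; `config$seed` makes the whole
#'   dataset reproducible
#' @param windows cohort windows used to anchor the arms (default
#'   [cohort_preset()])
#' @return list with `registry`, `events`, `notifications`, `scenario`
#' @export
simulate_study <- function(config = simulation_config(),
                           windows = cohort_preset()) {
  set.seed(config$seed)
  wj1 <- windows$journey_original
  wj2 <- windows$journey_seamless
  w_without <- windows$reminders_without
  w_with <- windows$reminders_with

  cfg1 <- config
  cfg1$start_date <- wj1$start_date
  cfg1$registration_span_days <- as.integer(wj1$end_date - wj1$start_date) + 1L
  reg1 <- simulate_funnel(cfg1, "original", id_prefix = "O")

  cfg2 <- config
  cfg2$start_date <- wj2$start_date
  cfg2$registration_span_days <- as.integer(wj2$end_date - wj2$start_date) + 1L
  reg2 <- simulate_funnel(cfg2, "seamless", id_prefix = "S")

  registry <- participant_registry(
    participant_id = c(reg1$participant_id, reg2$participant_id),
    registration_date = c(reg1$registration_date, reg2$registration_date),
    consent_date = c(reg1$consent_date, reg2$consent_date),
    activation_date = c(reg1$activation_date, reg2$activation_date),
    ms_status = c(reg1$ms_status, reg2$ms_status),
    platform = c(reg1$platform, reg2$platform)
  )

  study_end <- wj2$end_date
  with_reminders <- !is.na(registry$activation_date) &
    registry$activation_date >= w_with$start_date
  cfg_off <- config; cfg_off$notifications_enabled <- FALSE
  cfg_on <- config; cfg_on$notifications_enabled <- TRUE
  ev_off <- simulate_behavior(registry[!with_reminders, , drop = FALSE],
                              cfg_off, horizon_date = study_end)
  ev_on <- simulate_behavior(registry[with_reminders, , drop = FALSE],
                             cfg_on, horizon_date = study_end)
  events <- event_log(
    c(ev_off$participant_id, ev_on$participant_id),
    c(ev_off$test, ev_on$test),
    c(ev_off$timestamp, ev_on$timestamp)
  )
  notifications <- simulate_notifications(ev_on, cfg_on)
  list(registry = registry, events = events, notifications = notifications,
       scenario = config)
}

#' Write a simulated dataset to a directory
#'
#' Emits `registry.csv`, `events.csv`, `notifications.csv` in the canonical
#' dialect plus a `scenario.yml` with all parameters and the seed for
#' provenance.
#'
#' @param sim output of [simulate_study()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_registry(sim$registry, file.path(dir, "registry.csv"))
  write_event_log(sim$events, file.path(dir, "events.csv"))
  notes <- sim$notifications
  notes$timestamp <- format(notes$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(notes, file.path(dir, "notifications.csv"), progress = FALSE)
  scenario <- unclass(sim$scenario)
  scenario$start_date <- as.character(scenario$start_date)
  yaml::write_yaml(scenario, file.path(dir, "scenario.yml"))
  invisible(dir)
}
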