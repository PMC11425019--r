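# Shared fixture builders: cohorts realizing the published retention table
# and small event logs built in code.

# retention/completion profiles of the two reminders cohorts, as printed
# (days 1, 3, 7, 14, 30 with numerators over the cohort denominator)
table5_without_profiles <- function() {
  list(
    DA = list(days = c(1, 3, 7, 14, 30), retained = c(216, 112, 82, 57, 34),
              ever = 234),
    DAx = list(days = c(1, 3, 7, 14, 30), retained = c(290, 171, 121, 98, 60),
               ever = 301),
    TwoMWT = list(days = c(1, 3, 7, 14, 30), retained = c(113, 64, 50, 39, 22),
                  ever = 122)
  )
}

table5_with_profiles <- function() {
  list(
    DA = list(days = c(1, 3, 7, 14, 30), retained = c(113, 63, 56, 53, 53),
              ever = 113),
    DAx = list(days = c(1, 3, 7, 14, 30), retained = c(137, 88, 63, 53, 53),
               ever = 140),
    TwoMWT = list(days = c(1, 3, 7, 14, 30), retained = c(70, 56, 49, 42, 39),
                  ever = 72)
  )
}

fixture_without_cohort <- function() {
  fixture_retention_cohort(350, table5_without_profiles(),
                           activation_date = as.Date("2019-02-01"),
                           id_prefix = "W")
}

fixture_with_cohort <- function() {
  fixture_retention_cohort(172, table5_with_profiles(),
                           activation_date = as.Date("2020-03-01"),
                           id_prefix = "N")
}

# completion tables/registries built directly on day indices
completions_from_days <- function(day_sets, series = "DA",
                                  activation = as.Date("2019-02-01")) {
  rows <- lapply(names(day_sets), function(pid) {
    tibble::tibble(participant_id = pid,
                   date = activation + day_sets[[pid]],
                   series = series)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(participant_id = character(),
                          date = as.Date(character()), series = character())
  }
  out
}

registry_for <- function(ids, activation = as.Date("2019-02-01")) {
  participant_registry(
    participant_id = ids,
    registration_date = activation - 1,
    consent_date = activation - 1,
    activation_date = activation,
    ms_status = "MS"
  )
}

summaries_from_gaps <- function(gap_values) {
  gap_values <- as.integer(gap_values)
  tibble::tibble(
    participant_id = "x", series = "DA",
    run_starts = list(integer()), run_lengths = list(integer()),
    gaps = list(gap_values), n_active = 0L, max_run = 0L,
    max_gap = if (length(gap_values)) max(gap_values) else 0L,
    truncated_at = NA_integer_
  )
}

# a small clean log: 3 participants, a few days of full activity
tiny_log <- function() {
  reg <- participant_registry(
    participant_id = c("a", "b", "c"),
    registration_date = as.Date("2019-01-01"),
    consent_date = as.Date("2019-01-01"),
    activation_date = as.Date("2019-01-02"),
    ms_status = "MS"
  )
  all7 <- c("DMQ", "IPS", "IPSDD", "PT", "DaS", "SBT", "UTT")
  ev <- event_log(
    participant_id = c(rep("a", 7), rep("b", 7), "c"),
    test = c(all7, all7, "TwoMWT"),
    timestamp = as.Date(c(rep("2019-01-02", 7), rep("2019-01-03", 7), "2019-01-05"))
  )
  validate_log(reg, ev)
}
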