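# Deterministic synthetic fixtures: minimal registries/event logs that
# realize a prescribed funnel or retention table exactly. Used as worked
# examples and in tests; every printed rate with a numerator/denominator
# can be reconstructed at desk scale from one of these.

#' Build a registry realizing given funnel counts
#'
#' @param n_registered number of registrants
#' @param n_activated number of those who activated (`<= n_consented`)
#' @param n_consented number who consented (default: all registrants, as in
#'   flows where e-consent is part of registration)
#' @param start_date registration date used for all rows
#' @param id_prefix participant-id prefix
#' @param ms_status status given to activated participants
#' @return a `participant_registry`
#' @export
fixture_funnel_registry <- function(n_registered, n_activated,
                                    n_consented = n_registered,
                                    start_date = as.Date("2019-01-15"),
                                    id_prefix = "F", ms_status = "unknown") {
  stopifnot(n_registered >= n_consented, n_consented >= n_activated)
  start_date <- as.Date(start_date)
  idx <- seq_len(n_registered)
  consent <- as.Date(ifelse(idx <= n_consented, start_date, NA),
                     origin = "1970-01-01")
  activation <- as.Date(ifelse(idx <= n_activated, start_date + 1L, NA),
                        origin = "1970-01-01")
  participant_registry(
    participant_id = sprintf("%s%05d", id_prefix, idx),
    registration_date = start_date,
    consent_date = consent,
    activation_date = activation,
    ms_status = ifelse(idx <= n_activated, ms_status, "unknown")
  )
}

# day-after-activation assignment realizing a retention profile:
# rank-ordered so that pointwise-larger profiles dominate participant-wise
assign_last_days <- function(n, days, retained, ever) {
  stopifnot(length(days) == length(retained),
            all(diff(days) > 0), all(diff(retained) <= 0),
            ever >= retained[1], n >= ever)
  last <- rep(NA_integer_, n)
  k <- length(days)
  last[seq_len(retained[k])] <- days[k]
  for (j in rev(seq_len(k - 1))) {
    lo <- retained[j + 1] + 1L
    if (lo <= retained[j]) last[lo:retained[j]] <- days[j]
  }
  if (retained[1] < ever) last[(retained[1] + 1L):ever] <- 0L
  last
}

#' Build a cohort realizing a prescribed retention table
#'
#' Constructs a registry of `n` participants (common activation date) and an
#' event log such that, for each requested series, the number of
#' participants with a completion on day >= d equals `retained[d]` for every
#' tabulated day, and the number with at least one completion equals `ever`.
#' Participants are rank-aligned across series, so a series whose counts
#' dominate another's pointwise (as DAx dominates DA) automatically
#' dominates it participant-wise, preserving the DA-subset invariant: DA
#' days carry the full seven-test battery, DAx-only days the five-test
#' subset.
#'
#' @param n cohort size
#' @param profiles named list per series (`DA`, `DAx`, `TwoMWT`), each a
#'   list with `days` (increasing), `retained` (non-increasing counts of
#'   participants retained at those days) and `ever` (participants with >= 1
#'   completion)
#' @param activation_date common activation date
#' @param ms_status status for all participants
#' @param id_prefix participant-id prefix
#' @return list with `registry` and `events`
#' @export
fixture_retention_cohort <- function(n, profiles,
                                     activation_date = as.Date("2019-02-01"),
                                     ms_status = "MS", id_prefix = "R") {
  activation_date <- as.Date(activation_date)
  ids <- sprintf("%s%05d", id_prefix, seq_len(n))
  registry <- participant_registry(
    participant_id = ids,
    registration_date = activation_date - 2L,
    consent_date = activation_date - 2L,
    activation_date = activation_date,
    ms_status = ms_status
  )
  last <- lapply(profiles, function(p) {
    assign_last_days(n, as.integer(p$days), as.integer(p$retained),
                     as.integer(p$ever))
  })
  if (all(c("DA", "DAx") %in% names(last))) {
    bad <- !is.na(last$DA) &
      (is.na(last$DAx) | last$DAx < last$DA)
    if (any(bad)) {
      stop_dhengage("DAx retention profile must dominate DA's pointwise",
                    "dhengage_invariant_error")
    }
  }
  da_day_tests <- c("DMQ", "IPS", "IPSDD", "PT", "DaS", "SBT", "UTT")
  dax_day_tests <- c("DMQ", "IPS", "IPSDD", "PT", "DaS")
  pid <- character(); test <- character(); date <- as.Date(character())
  add_day <- function(i, day, tests) {
    pid <<- c(pid, rep(ids[i], length(tests)))
    test <<- c(test, tests)
    date <<- c(date, rep(activation_date + day, length(tests)))
  }
  for (i in seq_len(n)) {
    lda <- last$DA[i] %||% NA_integer_
    ldax <- last$DAx[i] %||% NA_integer_
    if (!is.na(lda)) add_day(i, lda, da_day_tests)
    if (!is.na(ldax) && (is.na(lda) || ldax > lda)) add_day(i, ldax, dax_day_tests)
    l2 <- last$TwoMWT[i] %||% NA_integer_
    if (!is.na(l2)) add_day(i, l2, "TwoMWT")
    if (is.na(lda) && is.na(ldax) && is.na(l2)) {
      # cohort member who opened the app but never completed a series:
      # a lone mood question keeps them in activity-based cohorts without
      # contributing any series completion
      add_day(i, 0L, "DMQ")
    }
  }
  list(registry = registry, events = event_log(pid, test, date))
}
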