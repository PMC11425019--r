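# Day-level sessionization: events -> daily activity profiles -> test-series
# completions (DA, DAx, TwoMWT).

#' Default test-series definitions
#'
#' Three series are analysed:
#' * `DA` — the full daily-activities sequence: DMQ, IPS, IPSDD, PT, DaS,
#'   SBT, UTT. IPS can only be taken weekly, so it enters as weekly credit
#'   rather than a strictly daily requirement (see below).
#' * `DAx` — DA without the gait/balance tests (SBT, UTT): DMQ, IPS, IPSDD,
#'   PT, DaS, again with IPS as weekly credit.
#' * `TwoMWT` — the two-minute walk test alone.
#'
#' A series is completed on a calendar day when all `required_daily` tests
#' were done that day and every `weekly_credit` test was done that day or
#' within the trailing `ips_weekly_window_days` window. With
#' `ips_weekly_window_days = 0` the weekly-credit tests move into
#' `required_daily` (strict mode).
#'
#' @param config an [analysis_config()]
#' @return named list of series definitions, each with `series`,
#'   `required_daily`, `weekly_credit`
#' @export
default_series_definitions <- function(config = analysis_config()) {
  defs <- list(
    DA = list(series = "DA",
              required_daily = c("DMQ", "IPSDD", "PT", "DaS", "SBT", "UTT"),
              weekly_credit = "IPS"),
    DAx = list(series = "DAx",
               required_daily = c("DMQ", "IPSDD", "PT", "DaS"),
               weekly_credit = "IPS"),
    TwoMWT = list(series = "TwoMWT",
                  required_daily = "TwoMWT",
                  weekly_credit = character())
  )
  if (config$ips_weekly_window_days == 0) {
    for (s in c("DA", "DAx")) {
      defs[[s]]$required_daily <- c(defs[[s]]$required_daily, defs[[s]]$weekly_credit)
      defs[[s]]$weekly_credit <- character()
    }
  }
  defs
}

#' Collapse events into per-day activity profiles
#'
#' Groups kept events by (participant, calendar day under the timezone
#' policy); `tests` is the set (list-column) of distinct tests completed
#' that day.
#'
#' @param log a `study_log` from [validate_log()] (or an `event_log`)
#' @param config an [analysis_config()]
#' @return tibble (participant_id, date, tests) sorted by participant, date
#' @export
build_daily_profiles <- function(log, config = analysis_config()) {
  ev <- if (!is.data.frame(log) && is.list(log) && !is.null(log$events)) {
    log$events
  } else {
    log
  }
  ev <- tibble::as_tibble(ev)
  if (nrow(ev) == 0) {
    return(tibble::tibble(participant_id = character(), date = as.Date(character()),
                          tests = list()))
  }
  ev$date <- event_date(ev$timestamp, config)
  prof <- ev |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(tests = list(sort(unique(.data$test))), .groups = "drop") |>
    dplyr::arrange(.data$participant_id, .data$date)
  prof
}

#' Detect test-series completions
#'
#' For every profile day and series definition, a completion is emitted iff
#' all `required_daily` tests are in that day's test set and every
#' `weekly_credit` test appears on some day in the trailing window of
#' `ips_weekly_window_days` days ending on (and including) the day. At most
#' one completion per (participant, day, series). Because the DAx
#' requirement set is a subset of DA's, every DA completion day is also a
#' DAx completion day.
#'
#' @param profiles output of [build_daily_profiles()]
#' @param definitions output of [default_series_definitions()]
#' @param config an [analysis_config()]
#' @return tibble (participant_id, date, series)
#' @export
detect_series_completions <- function(profiles,
                                      definitions = default_series_definitions(config),
                                      config = analysis_config()) {
  if (nrow(profiles) == 0) {
    return(tibble::tibble(participant_id = character(), date = as.Date(character()),
                          series = character()))
  }
  window <- config$ips_weekly_window_days
  out <- vector("list", length(definitions))
  names(out) <- names(definitions)

  by_pid <- split(seq_len(nrow(profiles)), profiles$participant_id)

  for (dname in names(definitions)) {
    def <- definitions[[dname]]
    daily_ok <- vapply(profiles$tests, function(ts) all(def$required_daily %in% ts),
                       logical(1))
    ok <- daily_ok
    if (length(def$weekly_credit) > 0 && any(daily_ok)) {
      for (credit in def$weekly_credit) {
        has_credit <- vapply(profiles$tests, function(ts) credit %in% ts, logical(1))
        credit_ok <- logical(nrow(profiles))
        for (idx in by_pid) {
          cand <- idx[ok[idx]]
          if (length(cand) == 0) next
          credit_days <- as.integer(profiles$date[idx][has_credit[idx]])
          if (length(credit_days) == 0) next
          for (i in cand) {
            d <- as.integer(profiles$date[i])
            credit_ok[i] <- any(credit_days >= d - (window - 1L) & credit_days <= d)
          }
        }
        ok <- ok & credit_ok
      }
    }
    out[[dname]] <- tibble::tibble(
      participant_id = profiles$participant_id[ok],
      date = profiles$date[ok],
      series = def$series
    )
  }
  comp <- dplyr::bind_rows(out) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$participant_id, .data$date, .data$series)
  comp
}

#' Write series completions to CSV (participant_id, ISO date, series)
#' @param completions tibble from [detect_series_completions()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_completions <- function(completions, path) {
  readr::write_csv(completions, path, progress = FALSE)
  invisible(path)
}

#' One-call sessionization: study log to completions
#' @param log a `study_log`
#' @param config an [analysis_config()]
#' @return tibble (participant_id, date, series)
#' @export
sessionize <- function(log, config = analysis_config()) {
  detect_series_completions(
    build_daily_profiles(log, config),
    default_series_definitions(config),
    config
  )
}
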