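# Analysis configuration and the calendar-window cohort presets.

#' Define a calendar cohort window
#'
#' @param label unique cohort label
#' @param start_date first day, inclusive
#' @param end_date last day, inclusive
#' @param assign_by how participants join the cohort: `"activity"` (at least
#'   one event dated inside the window) or `"registration"`
#'   (registration_date inside the window)
#' @param ms_only restrict the cohort to participants with self-declared MS
#' @param reminders whether reminders/notifications were available in this
#'   window (metadata used by reports and the simulator)
#' @return a `cohort_window` list
#' @export
cohort_window <- function(label, start_date, end_date,
                          assign_by = c("activity", "registration"),
                          ms_only = FALSE, reminders = NA) {
  assign_by <- match.arg(assign_by)
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || start_date > end_date) {
    stop_dhengage("cohort window requires start_date <= end_date", "dhengage_config_error")
  }
  structure(
    list(label = label, start_date = start_date, end_date = end_date,
         assign_by = assign_by, ms_only = ms_only, reminders = reminders),
    class = "cohort_window"
  )
}

#' Study cohort window presets
#'
#' The four calendar windows of the UX study, shipped as data rather than
#' hard-wired constants:
#' * `journey_original` (2018-11-12 to 2019-07-17): registrations under the
#'   original activation journey, before deep linking.
#' * `journey_seamless` (2019-10-21 to 2021-11-02): registrations under the
#'   seamless deep-linked journey.
#' * `reminders_without` (2018-11-12 to 2019-10-20): activity before
#'   reminders and push notifications were available (MS participants only).
#' * `reminders_with` (2020-02-19 to 2021-11-02): activity after reminders
#'   and push notifications were fully rolled out (MS participants only).
#'
#' The gaps between the windows (staggered iOS/Android feature releases)
#' belong to no cohort. The end of the without-reminders window is taken as
#' October 20, 2019, inclusive.
#'
#' @param which `"journey"`, `"reminders"`, or `"all"`
#' @return named list of [cohort_window()] objects
#' @export
cohort_preset <- function(which = c("all", "journey", "reminders")) {
  which <- match.arg(which)
  journey <- list(
    journey_original = cohort_window(
      "journey_original", "2018-11-12", "2019-07-17",
      assign_by = "registration", ms_only = FALSE, reminders = FALSE
    ),
    journey_seamless = cohort_window(
      "journey_seamless", "2019-10-21", "2021-11-02",
      assign_by = "registration", ms_only = FALSE, reminders = NA
    )
  )
  reminders <- list(
    reminders_without = cohort_window(
      "reminders_without", "2018-11-12", "2019-10-20",
      assign_by = "activity", ms_only = TRUE, reminders = FALSE
    ),
    reminders_with = cohort_window(
      "reminders_with", "2020-02-19", "2021-11-02",
      assign_by = "activity", ms_only = TRUE, reminders = TRUE
    )
  )
  switch(which,
    journey = journey,
    reminders = reminders,
    all = c(journey, reminders)
  )
}

#' Analysis configuration
#'
#' Collects every tunable the pipeline consults, with the study defaults.
#'
#' @param timezone_policy `"utc"` (default; deterministic) or
#'   `"source_local"` for logs that ship local timestamps
#' @param day0_is_activation if `TRUE` (default) day indices are counted
#'   from each participant's activation date (activation day = day 0)
#' @param truncation_days usage/inactivity metrics only consider the first
#'   this-many days of data per participant (default 343, so cohorts
#'   observed for different calendar spans stay comparable)
#' @param ips_weekly_window_days the IPS test can be taken at most weekly;
#'   a daily-series completion credits an IPS done on the same day or within
#'   this trailing window (default 7 days including the day itself; 0 makes
#'   IPS strictly daily)
#' @param retention_definition `"still_active_at_or_after_n"` (default; the
#'   complementary cumulative distribution of the last active day) or
#'   `"active_exactly_day_n"`
#' @param usage_unit `"participant_max_run"` (default) or `"pooled_episodes"`
#' @param rounding percentage rounding convention (only `"half_up_1dp"`)
#' @param cohort_windows list of [cohort_window()]s; default [cohort_preset()]
#' @return an `analysis_config` list
#' @export
analysis_config <- function(timezone_policy = c("utc", "source_local"),
                            day0_is_activation = TRUE,
                            truncation_days = 343L,
                            ips_weekly_window_days = 7L,
                            retention_definition = c("still_active_at_or_after_n",
                                                     "active_exactly_day_n"),
                            usage_unit = c("participant_max_run", "pooled_episodes"),
                            rounding = "half_up_1dp",
                            cohort_windows = cohort_preset()) {
  timezone_policy <- match.arg(timezone_policy)
  retention_definition <- match.arg(retention_definition)
  usage_unit <- match.arg(usage_unit)
  if (truncation_days <= 0) {
    stop_dhengage("truncation_days must be positive", "dhengage_config_error")
  }
  if (ips_weekly_window_days < 0) {
    stop_dhengage("ips_weekly_window_days must be >= 0", "dhengage_config_error")
  }
  labels <- vapply(cohort_windows, function(w) w$label, character(1))
  if (anyDuplicated(labels)) {
    stop_dhengage("cohort window labels must be unique", "dhengage_config_error")
  }
  structure(
    list(
      timezone_policy = timezone_policy,
      day0_is_activation = day0_is_activation,
      truncation_days = as.integer(truncation_days),
      ips_weekly_window_days = as.integer(ips_weekly_window_days),
      retention_definition = retention_definition,
      usage_unit = usage_unit,
      rounding = rounding,
      cohort_windows = cohort_windows
    ),
    class = "analysis_config"
  )
}
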