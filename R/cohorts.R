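# Calendar-window cohort assignment and the side-by-side comparison report.

#' Assign participants to calendar-window cohorts
#'
#' Membership rules follow each window's `assign_by`:
#' * `"registration"` — registration_date inside the window (used for the
#'   activation-journey cohorts, where the journey variant is determined at
#'   registration);
#' * `"activity"` — at least one kept event dated inside the window (used
#'   for the reminders cohorts). A participant active in both observation
#'   periods belongs to both cohorts, with disjoint clipped data.
#'
#' Windows with `ms_only = TRUE` keep only participants with self-declared
#' MS. Events are clipped per cohort to the window's date range.
#'
#' @param log a `study_log`
#' @param windows list of [cohort_window()]s (default from `config`)
#' @param config an [analysis_config()]
#' @return tibble (participant_id, cohort, clip_start, clip_end)
#' @export
assign_cohorts <- function(log, windows = config$cohort_windows,
                           config = analysis_config()) {
  labels <- vapply(windows, function(w) w$label, character(1))
  if (anyDuplicated(labels)) {
    stop_dhengage("cohort window labels must be unique", "dhengage_config_error")
  }
  reg <- tibble::as_tibble(log$registry)
  ev <- tibble::as_tibble(log$events)
  ev_date <- event_date(ev$timestamp, config)
  out <- lapply(windows, function(w) {
    pool <- reg
    if (isTRUE(w$ms_only)) pool <- pool[pool$ms_status == "MS", , drop = FALSE]
    members <- if (w$assign_by == "registration") {
      pool$participant_id[!is.na(pool$registration_date) &
                            pool$registration_date >= w$start_date &
                            pool$registration_date <= w$end_date]
    } else {
      active <- unique(ev$participant_id[ev_date >= w$start_date &
                                           ev_date <= w$end_date])
      intersect(pool$participant_id, active)
    }
    tibble::tibble(
      participant_id = members,
      cohort = w$label,
      clip_start = w$start_date,
      clip_end = w$end_date
    )
  })
  dplyr::bind_rows(out)
}

# subset a study_log to one cohort: member registry + window-clipped events
clip_cohort_log <- function(log, assignment, label, config) {
  a <- assignment[assignment$cohort == label, , drop = FALSE]
  reg <- log$registry[log$registry$participant_id %in% a$participant_id, ,
                      drop = FALSE]
  ev <- tibble::as_tibble(log$events)
  if (nrow(a) == 0 || nrow(ev) == 0) {
    ev <- ev[0, , drop = FALSE]
  } else {
    d <- event_date(ev$timestamp, config)
    ev <- ev[ev$participant_id %in% a$participant_id &
               d >= a$clip_start[1] & d <= a$clip_end[1], , drop = FALSE]
  }
  list(registry = reg,
       events = structure(ev, class = c("event_log", class(ev))))
}

series_metrics <- function(completions, registry, series, config) {
  summaries <- run_gap_summaries(completions, registry, series, config)
  comp_curve <- completion_rate_curve(completions, registry, series, config)
  list(
    usage_max_run = usage_ccdf(summaries, unit = "participant_max_run", config = config),
    usage_pooled = usage_ccdf(summaries, unit = "pooled_episodes", config = config),
    inactivity = inactivity_ccdf(summaries, config),
    completion = comp_curve,
    retention = retention_curve(completions, registry, series, config),
    max_run = if (nrow(summaries)) max(summaries$max_run) else 0L,
    max_gap = if (nrow(summaries)) max(summaries$max_gap) else 0L,
    max_series_count = attr(comp_curve, "max_count")
  )
}

#' Two-cohort (or n-cohort) comparison report
#'
#' Runs the full pipeline per configured cohort window: clip events, build
#' profiles, detect completions, then compute all four UX metrics for every
#' series (DA, DAx, TwoMWT). Registration-assigned windows additionally get
#' a funnel section. Empty cohorts are marked empty and the run continues.
#'
#' @param log a `study_log` from [validate_log()]
#' @param config an [analysis_config()] whose `cohort_windows` define the
#'   comparison
#' @param series series to analyse (default all three)
#' @return a `comparison_report` list: `cohorts` (per label: window, n,
#'   per-series metrics), `funnels`, `assignment`, `config`
#' @export
compare_cohorts <- function(log, config = analysis_config(),
                            series = c("DA", "DAx", "TwoMWT")) {
  windows <- config$cohort_windows
  assignment <- assign_cohorts(log, windows, config)
  cohorts <- list()
  funnels <- list()
  for (w in windows) {
    sub <- clip_cohort_log(log, assignment, w$label, config)
    if (w$assign_by == "registration") {
      funnels[[w$label]] <- compute_funnel(sub$registry, w)
    }
    if (nrow(sub$registry) == 0) {
      cohorts[[w$label]] <- list(window = w, n_participants = 0L, empty = TRUE)
      next
    }
    completions <- sessionize(sub, config)
    metrics <- lapply(series, function(s) {
      series_metrics(completions, sub$registry, s, config)
    })
    names(metrics) <- series
    cohorts[[w$label]] <- list(
      window = w,
      n_participants = sum(!is.na(sub$registry$activation_date)),
      empty = FALSE,
      completions = completions,
      registry = sub$registry,
      metrics = metrics
    )
  }
  structure(
    list(cohorts = cohorts, funnels = funnels, assignment = assignment,
         config = config, series = series),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d cohort(s): %s\n",
              length(x$cohorts), paste(names(x$cohorts), collapse = ", ")))
  for (label in names(x$cohorts)) {
    co <- x$cohorts[[label]]
    if (isTRUE(co$empty)) {
      cat(sprintf("  %s: empty\n", label))
    } else {
      cat(sprintf("  %s: %d participants, %d completions\n",
                  label, co$n_participants, nrow(co$completions)))
    }
  }
  invisible(x)
}
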