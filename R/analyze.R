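# End-to-end drivers: the programmatic equivalents of "simulate" and
# "analyze" pipeline runs. The scripts under analysis/ are thin wrappers
# around these.

#' Simulate a study and write it to disk
#'
#' @param config a [simulation_config()]
#' @param out_dir output directory
#' @return the simulated dataset (list), invisibly; prints a summary
#' @export
run_simulation <- function(config = simulation_config(), out_dir) {
  sim <- simulate_study(config)
  write_simulated_dataset(sim, out_dir)
  n_act <- sum(!is.na(sim$registry$activation_date))
  cat(sprintf("simulated %d registrants, %d activated, %d events, %d notifications\n",
              nrow(sim$registry), n_act, nrow(sim$events),
              nrow(sim$notifications)))
  invisible(sim)
}

#' Analyze a registry and event log end to end
#'
#' Runs validate -> sessionize -> metrics -> cohort comparison, and (when
#' `out_dir` is given) writes the report bundle with its manifest.
#'
#' @param registry a `participant_registry` or path to a registry CSV
#' @param events an `event_log` or path to an event-log CSV
#' @param config an [analysis_config()]
#' @param out_dir optional output directory for the report bundle
#' @return a `comparison_report` (with the `study_log` attached as
#'   attribute `"log"`), invisibly
#' @export
analyze_study <- function(registry, events, config = analysis_config(),
                          out_dir = NULL) {
  inputs <- character()
  if (is.character(registry)) {
    inputs["registry"] <- registry
    registry <- read_registry(registry)
  }
  if (is.character(events)) {
    inputs["events"] <- events
    events <- read_event_log(events)
  }
  log <- validate_log(registry, events, config)
  report <- compare_cohorts(log, config)
  if (!is.null(out_dir)) {
    write_report(report, out_dir, inputs = inputs)
    if (nrow(log$quarantine) > 0) {
      write_quarantine(log, file.path(out_dir, "quarantine.csv"))
    }
  }
  attr(report, "log") <- log
  invisible(report)
}
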