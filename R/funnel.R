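# Registration -> consent -> activation conversion funnel.

#' Funnel counts for a cohort window
#'
#' Counts participants whose registration date lies inside the window, by the
#' furthest milestone reached. Milestones are nested: everyone activated has
#' consented, everyone consented has registered, so
#' `registered >= consented >= activated`.
#'
#' @param registry `participant_registry`
#' @param window a [cohort_window()]; `NULL` counts the whole registry
#' @return a `funnel_counts` object (label, registered, consented, activated)
#' @export
compute_funnel <- function(registry, window = NULL) {
  reg <- tibble::as_tibble(registry)
  label <- "all"
  if (!is.null(window)) {
    reg <- reg[reg$registration_date >= window$start_date &
                 reg$registration_date <= window$end_date, , drop = FALSE]
    label <- window$label
  }
  structure(
    list(
      label = label,
      registered = nrow(reg),
      consented = sum(!is.na(reg$consent_date)),
      activated = sum(!is.na(reg$activation_date))
    ),
    class = "funnel_counts"
  )
}

#' Registration-to-activation conversion rate
#'
#' @param funnel a `funnel_counts` object
#' @return list with `fraction` (activated / registered), `percent`
#'   (half-up, 1 decimal) and `formatted` (e.g. `"53.9 (328/608)"`)
#' @export
conversion_rate <- function(funnel) {
  if (funnel$registered <= 0) {
    stop_dhengage("conversion rate undefined: no registrants", "dhengage_undefined_rate")
  }
  frac <- funnel$activated / funnel$registered
  list(
    fraction = frac,
    percent = round_half_up(100 * frac, 1),
    formatted = format_pct(funnel$activated, funnel$registered)
  )
}

#' @export
print.funnel_counts <- function(x, ...) {
  cat(funnel_diagram(x), sep = "\n")
  invisible(x)
}

#' Plain-text three-step funnel diagram
#'
#' @param funnel a `funnel_counts` object
#' @return character vector of diagram lines
#' @export
funnel_diagram <- function(funnel) {
  conv <- if (funnel$registered > 0) {
    sprintf(" (conversion %s%%)", format(round_half_up(
      100 * funnel$activated / funnel$registered, 1), trim = TRUE))
  } else {
    ""
  }
  c(
    sprintf("[%s]", funnel$label),
    sprintf("  registered  %6d", funnel$registered),
    "      |",
    sprintf("  consented   %6d", funnel$consented),
    "      |",
    sprintf("  activated   %6d%s", funnel$activated, conv)
  )
}

#' @export
as.list.funnel_counts <- function(x, ...) unclass(x)

#' Write a funnel report (one or more cohorts) as JSON
#'
#' @param funnels a `funnel_counts` or list of them
#' @param path output file
#' @return `path`, invisibly
#' @export
write_funnel_json <- function(funnels, path) {
  if (inherits(funnels, "funnel_counts")) funnels <- list(funnels)
  payload <- lapply(funnels, function(f) {
    out <- unclass(f)
    if (f$registered > 0) {
      out$conversion_pct <- round_half_up(100 * f$activated / f$registered, 1)
    }
    out
  })
  names(payload) <- vapply(payload, function(f) f$label, character(1))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
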