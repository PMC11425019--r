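# Report rendering: retention tables in the study's cell format, tidy curve
# exports, run manifests, and the full report bundle on disk.

#' Render the day-n retention table
#'
#' One row per cohort x series; cells are `"pct (num/denom)"` with the
#' percentage rounded half-up to one decimal. A requested day beyond a
#' cohort's observation span is marked `"censored"`.
#'
#' @param report a `comparison_report` from [compare_cohorts()]
#' @param days days after activation to tabulate
#' @return tibble with columns cohort, series, `day_<n>`...
#' @export
render_retention_table <- function(report, days = c(1, 3, 7, 14, 30)) {
  rows <- list()
  for (label in names(report$cohorts)) {
    co <- report$cohorts[[label]]
    for (s in report$series) {
      cells <- setNames(vector("list", length(days)),
                        paste0("day_", days))
      if (isTRUE(co$empty)) {
        cells[] <- "censored"
      } else {
        ret <- co$metrics[[s]]$retention
        reg <- co$registry[!is.na(co$registry$activation_date), , drop = FALSE]
        max_obs <- if (nrow(reg) > 0) {
          max(as.integer(co$window$end_date - reg$activation_date))
        } else {
          -1L
        }
        for (i in seq_along(days)) {
          n <- days[i]
          if (n > max_obs) {
            cells[[i]] <- "censored"
          } else {
            row <- ret[ret$day == n, , drop = FALSE]
            retained <- if (nrow(row) == 1) row$retained else {
              # beyond the computed grid means nobody retained
              0L
            }
            cells[[i]] <- format_pct(retained, ret$cohort_size[1] %||% 0L)
          }
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        cohort = label, series = s, !!!cells
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Collect every CCDF curve of a report as one tidy table
#'
#' @param report a `comparison_report`
#' @return tibble (cohort, metric, unit, series, n, numerator, denominator,
#'   probability)
#' @export
tidy_report_curves <- function(report) {
  rows <- list()
  for (label in names(report$cohorts)) {
    co <- report$cohorts[[label]]
    if (isTRUE(co$empty)) next
    for (s in report$series) {
      m <- co$metrics[[s]]
      for (metric in c("usage_max_run", "usage_pooled", "inactivity", "completion")) {
        cur <- as_tidy_ccdf(m[[metric]])
        if (nrow(cur) == 0) next
        cur$cohort <- label
        cur$metric <- metric
        rows[[length(rows) + 1]] <- cur
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(cohort = character(), metric = character(),
                          unit = character(), series = character(),
                          n = integer(), numerator = integer(),
                          denominator = integer(), probability = double()))
  }
  dplyr::bind_rows(rows)[, c("cohort", "metric", "unit", "series", "n",
                             "numerator", "denominator", "probability")]
}

#' Tidy retention curves of a report
#' @param report a `comparison_report`
#' @return tibble (cohort, series, day, retained, cohort_size, fraction)
#' @export
tidy_report_retention <- function(report) {
  rows <- list()
  for (label in names(report$cohorts)) {
    co <- report$cohorts[[label]]
    if (isTRUE(co$empty)) next
    for (s in report$series) {
      ret <- tibble::as_tibble(co$metrics[[s]]$retention)
      ret$cohort <- label
      ret$series <- s
      rows[[length(rows) + 1]] <- ret
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(cohort = character(), series = character(),
                          day = integer(), retained = integer(),
                          cohort_size = integer(), fraction = double()))
  }
  dplyr::bind_rows(rows)[, c("cohort", "series", "day", "retained",
                             "cohort_size", "fraction")]
}

#' Write a run manifest
#'
#' Records what produced an output directory: a digest of the configuration,
#' digests of the input files, the package version, a timestamp and the
#' output inventory — enough to re-run the pipeline.
#'
#' @param dir output directory (must contain the outputs already)
#' @param config the configuration object used
#' @param inputs named character vector of input file paths (digested)
#' @param extra optional named list merged into the manifest
#' @return path of the manifest, invisibly
#' @export
write_manifest <- function(dir, config, inputs = character(), extra = list()) {
  inventory <- setdiff(list.files(dir), "manifest.json")
  manifest <- c(list(
    tool = "dhengage",
    version = as.character(utils::packageVersion("dhengage")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    config_digest = digest::digest(config),
    inputs = as.list(vapply(inputs, function(p) {
      if (file.exists(p)) digest::digest(file = p) else NA_character_
    }, character(1))),
    outputs = inventory
  ), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a comparison report bundle to a directory
#'
#' Produces `curves.csv`, `retention_curves.csv`, `retention_table.csv`
#' (cohort x series rows, days 1/3/7/14/30), `funnel.json` (when journey
#' cohorts are configured), a `config.yml` echo, a plain-text `report.log`,
#' and `manifest.json`. Identical inputs and config give byte-identical CSV
#' and JSON outputs.
#'
#' @param report a `comparison_report`
#' @param dir output directory (created if needed)
#' @param days retention-table days
#' @param inputs optional named input paths recorded in the manifest
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir, days = c(1, 3, 7, 14, 30),
                         inputs = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy_report_curves(report), file.path(dir, "curves.csv"),
                   progress = FALSE)
  readr::write_csv(tidy_report_retention(report),
                   file.path(dir, "retention_curves.csv"), progress = FALSE)
  readr::write_csv(render_retention_table(report, days),
                   file.path(dir, "retention_table.csv"), progress = FALSE)
  if (length(report$funnels) > 0) {
    write_funnel_json(report$funnels, file.path(dir, "funnel.json"))
  }
  cfg <- report$config
  cfg_echo <- unclass(cfg)
  cfg_echo$cohort_windows <- lapply(cfg$cohort_windows, function(w) {
    w <- unclass(w)
    w$start_date <- as.character(w$start_date)
    w$end_date <- as.character(w$end_date)
    w
  })
  yaml::write_yaml(cfg_echo, file.path(dir, "config.yml"))
  log_lines <- c(
    sprintf("cohorts: %s", paste(names(report$cohorts), collapse = ", ")),
    vapply(names(report$cohorts), function(label) {
      co <- report$cohorts[[label]]
      if (isTRUE(co$empty)) {
        sprintf("%s: empty", label)
      } else {
        sprintf("%s: n=%d, completions=%d", label, co$n_participants,
                nrow(co$completions))
      }
    }, character(1))
  )
  writeLines(log_lines, file.path(dir, "report.log"))
  write_manifest(dir, report$config, inputs)
  invisible(dir)
}

#' Log-log CCDF plot
#'
#' Renders one or more CCDF curves on log-log axes (the conventional view
#' for heavy-tailed usage and inactivity distributions). Requires ggplot2.
#'
#' @param curves a `ccdf_curve` or named list of them
#' @return a ggplot object
#' @export
plot_ccdf <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_dhengage("plot_ccdf requires ggplot2", "dhengage_dependency_error")
  }
  if (inherits(curves, "ccdf_curve")) curves <- list(curve = curves)
  df <- dplyr::bind_rows(lapply(names(curves), function(nm) {
    cur <- as_tidy_ccdf(curves[[nm]])
    cur$label <- nm
    cur
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$probability,
                                   colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "n (days)", y = "P(X ≥ n)", colour = NULL) +
    ggplot2::theme_minimal()
}
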