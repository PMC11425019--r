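# The four UX metrics, each as a complementary cumulative distribution:
# continuous-usage runs, inactivity gaps, test completion rate, and day-n
# user retention; plus power-law tail fitting for the inactivity times.

#' Day indices of series completions relative to activation
#'
#' Converts completion dates to integer day indices (activation day = 0) for
#' one series, optionally truncating to the first `truncation_days` days of
#' observation so cohorts followed for different calendar spans stay
#' comparable.
#'
#' @param completions tibble from [detect_series_completions()]
#' @param registry `participant_registry` defining the cohort (participants
#'   without an activation date are dropped)
#' @param series one of `"DA"`, `"DAx"`, `"TwoMWT"`
#' @param config an [analysis_config()]
#' @param truncate apply the `truncation_days` cut (used for usage/gap
#'   metrics, not for completion/retention curves)
#' @return tibble (participant_id, day), day >= 0, deduplicated
#' @export
series_day_table <- function(completions, registry, series,
                             config = analysis_config(), truncate = FALSE) {
  reg <- tibble::as_tibble(registry)
  reg <- reg[!is.na(reg$activation_date), , drop = FALSE]
  comp <- completions[completions$series == series &
                        completions$participant_id %in% reg$participant_id, ,
                      drop = FALSE]
  act <- reg$activation_date[match(comp$participant_id, reg$participant_id)]
  day <- as.integer(comp$date - act)
  keep <- day >= 0
  if (truncate) keep <- keep & day <= config$truncation_days - 1L
  out <- tibble::tibble(participant_id = comp$participant_id[keep], day = day[keep])
  dplyr::distinct(dplyr::arrange(out, .data$participant_id, .data$day))
}

# core: maximal runs of consecutive integers and the gaps strictly between
# them; `days` must be sorted unique integers
runs_gaps_from_days <- function(days) {
  if (length(days) == 0) {
    return(list(run_starts = integer(), run_lengths = integer(), gaps = integer()))
  }
  brk <- which(diff(days) > 1L)
  starts <- days[c(1L, brk + 1L)]
  ends <- days[c(brk, length(days))]
  list(
    run_starts = starts,
    run_lengths = ends - starts + 1L,
    gaps = if (length(brk) > 0) starts[-1L] - ends[-length(ends)] - 1L else integer()
  )
}

#' Continuous-usage runs and inactivity gaps for every cohort participant
#'
#' A run is a maximal stretch of consecutive calendar days with a series
#' completion; a gap is the stretch of inactive days strictly *between* two
#' runs (a trailing inactive stretch after the last active day is censored,
#' not a gap). Activity beyond the first `truncation_days` days since
#' activation is discarded and flagged via `truncated_at`.
#'
#' @inheritParams series_day_table
#' @return tibble with one row per cohort participant: `participant_id`,
#'   `series`, list-columns `run_starts`, `run_lengths`, `gaps`, plus
#'   `n_active`, `max_run`, `max_gap`, `truncated_at`
#' @export
run_gap_summaries <- function(completions, registry, series,
                              config = analysis_config()) {
  reg <- tibble::as_tibble(registry)
  reg <- reg[!is.na(reg$activation_date), , drop = FALSE]
  full <- series_day_table(completions, registry, series, config, truncate = FALSE)
  cut <- config$truncation_days - 1L
  days_by_pid <- split(full$day, full$participant_id)
  res <- lapply(reg$participant_id, function(pid) {
    d <- days_by_pid[[pid]] %||% integer()
    truncated <- any(d > cut)
    d <- d[d <= cut]
    rg <- runs_gaps_from_days(d)
    tibble::tibble(
      participant_id = pid,
      series = series,
      run_starts = list(rg$run_starts),
      run_lengths = list(rg$run_lengths),
      gaps = list(rg$gaps),
      n_active = length(d),
      max_run = if (length(rg$run_lengths)) max(rg$run_lengths) else 0L,
      max_gap = if (length(rg$gaps)) max(rg$gaps) else 0L,
      truncated_at = if (truncated) config$truncation_days else NA_integer_
    )
  })
  dplyr::bind_rows(res)
}

#' Runs and gaps for a single participant
#'
#' @inheritParams series_day_table
#' @param participant a participant id present in `registry`
#' @return list with `participant_id`, `series`, `runs` (tibble of
#'   start_day/length), `gaps` (integer lengths), `truncated_at`
#' @export
runs_and_gaps <- function(completions, registry, participant, series,
                          config = analysis_config()) {
  s <- run_gap_summaries(completions,
                         registry[registry$participant_id == participant, ,
                                  drop = FALSE],
                         series, config)
  if (nrow(s) == 0) {
    stop_dhengage(sprintf("participant '%s' not in registry (or not activated)",
                          participant),
                  "dhengage_lookup_error")
  }
  list(
    participant_id = participant,
    series = series,
    runs = tibble::tibble(start_day = s$run_starts[[1]], length = s$run_lengths[[1]]),
    gaps = s$gaps[[1]],
    truncated_at = s$truncated_at[[1]]
  )
}

# ---- CCDF container ---------------------------------------------------------

#' Construct a CCDF curve directly
#'
#' Mostly useful for analytic curves (e.g. an exact power law) fed to
#' [fit_powerlaw()]; the pipeline builds its curves from data internally.
#'
#' @param n increasing integer support
#' @param probability P(X >= n) at each support point (non-increasing,
#'   in \[0, 1\])
#' @param unit label for the curve's unit
#' @param series optional series label
#' @return a `ccdf_curve`
#' @export
ccdf_curve <- function(n, probability, unit = "analytic", series = NA_character_) {
  stopifnot(length(n) == length(probability),
            all(diff(n) > 0), all(diff(probability) <= 0),
            all(probability >= 0 & probability <= 1))
  curve <- tibble::tibble(
    n = as.integer(n),
    numerator = NA_integer_,
    denominator = NA_integer_,
    probability = as.numeric(probability)
  )
  structure(curve, unit = unit, series = series,
            class = c("ccdf_curve", class(curve)))
}

new_ccdf_curve <- function(support, numerator, denominator, unit, series = NA_character_) {
  curve <- tibble::tibble(
    n = as.integer(support),
    numerator = as.integer(numerator),
    denominator = as.integer(denominator),
    probability = ifelse(denominator > 0, numerator / denominator, NA_real_)
  )
  structure(curve, unit = unit, series = series,
            class = c("ccdf_curve", class(curve)))
}

# CCDF over a multiset of non-negative integers: support = observed positive
# values; numerator(n) = #{x >= n}
ccdf_from_values <- function(values, denominator = length(values), unit,
                             series = NA_character_) {
  values <- as.integer(values)
  support <- sort(unique(values[values > 0]))
  numerator <- vapply(support, function(n) sum(values >= n), integer(1))
  new_ccdf_curve(support, numerator, denominator, unit, series)
}

#' Evaluate a CCDF curve at arbitrary n
#'
#' @param curve a `ccdf_curve`
#' @param n integer vector
#' @return P(X >= n) for each n (1 below the support, 0 above it)
#' @export
ccdf_prob <- function(curve, n) {
  vapply(as.integer(n), function(k) {
    if (nrow(curve) == 0) return(if (k <= 0) 1 else 0)
    if (k <= 0) return(1)
    idx <- which(curve$n >= k)
    if (length(idx) == 0) 0 else curve$probability[idx[1]]
  }, numeric(1))
}

#' @export
print.ccdf_curve <- function(x, ...) {
  cat(sprintf("<ccdf_curve> unit=%s series=%s, %d support points\n",
              attr(x, "unit"), attr(x, "series"), nrow(x)))
  NextMethod()
}

#' Continuous-usage CCDF
#'
#' With `unit = "participant_max_run"` the curve is over participants:
#' P(a participant's longest run of consecutive active days >= n), with the
#' cohort size as denominator — the unit behind headline statements like
#' "proportion of participants with >= 3 consecutive days of usage". With
#' `unit = "pooled_episodes"` the curve pools every run episode.
#'
#' @param summaries tibble from [run_gap_summaries()]
#' @param unit `"participant_max_run"` or `"pooled_episodes"`
#' @param config an [analysis_config()] (supplies the default unit)
#' @return a `ccdf_curve`
#' @export
usage_ccdf <- function(summaries, unit = config$usage_unit,
                       config = analysis_config()) {
  unit <- match.arg(unit, c("participant_max_run", "pooled_episodes"))
  series <- if (nrow(summaries) > 0) summaries$series[[1]] else NA_character_
  if (unit == "participant_max_run") {
    ccdf_from_values(summaries$max_run, denominator = nrow(summaries),
                     unit = unit, series = series)
  } else {
    runs <- unlist(summaries$run_lengths)
    ccdf_from_values(runs, denominator = length(runs), unit = unit, series = series)
  }
}

#' Inactivity-time CCDF
#'
#' CCDF over all inactivity gaps pooled across participants: P(gap >= n).
#'
#' @param summaries tibble from [run_gap_summaries()], or a bare integer
#'   vector of gap lengths (already pooled)
#' @param config an [analysis_config()]
#' @return a `ccdf_curve` with unit `"pooled_gaps"`
#' @export
inactivity_ccdf <- function(summaries, config = analysis_config()) {
  if (is.numeric(summaries)) {
    gaps <- as.integer(summaries)
    series <- NA_character_
  } else {
    series <- if (nrow(summaries) > 0) summaries$series[[1]] else NA_character_
    gaps <- unlist(summaries$gaps)
  }
  ccdf_from_values(gaps, denominator = length(gaps), unit = "pooled_gaps",
                   series = series)
}

#' Test-completion-rate curve
#'
#' P(a cohort participant completed at least n series) over the full
#' observation window, with the cohort size as denominator. The attribute
#' `max_count` records the largest number of series completed by anyone.
#'
#' @inheritParams series_day_table
#' @return a `ccdf_curve` with unit `"series_count"`
#' @export
completion_rate_curve <- function(completions, registry, series,
                                  config = analysis_config()) {
  reg <- tibble::as_tibble(registry)
  reg <- reg[!is.na(reg$activation_date), , drop = FALSE]
  tab <- series_day_table(completions, registry, series, config, truncate = FALSE)
  counts <- table(factor(tab$participant_id, levels = reg$participant_id))
  curve <- ccdf_from_values(as.integer(counts), denominator = nrow(reg),
                            unit = "series_count", series = series)
  attr(curve, "max_count") <- if (length(counts)) max(as.integer(counts)) else 0L
  curve
}

#' Day-n user retention curve
#'
#' Under the default definition (`still_active_at_or_after_n`) retention at
#' day n is the fraction of cohort participants with at least one completion
#' of the series on day >= n after activation (day 0 = activation day) —
#' i.e. the complementary cumulative distribution of the last active day,
#' which is non-increasing in n. The alternative `active_exactly_day_n`
#' counts completions exactly on day n.
#'
#' @inheritParams series_day_table
#' @param days integer days to evaluate; default 0..max observed last day
#' @return a `retention_curve` tibble (day, retained, cohort_size, fraction);
#'   participants without an activation date are excluded and counted in
#'   attribute `n_excluded`
#' @export
retention_curve <- function(completions, registry, series,
                            config = analysis_config(), days = NULL) {
  reg <- tibble::as_tibble(registry)
  n_excluded <- sum(is.na(reg$activation_date))
  reg <- reg[!is.na(reg$activation_date), , drop = FALSE]
  tab <- series_day_table(completions, registry, series, config, truncate = FALSE)
  cohort_size <- nrow(reg)
  last_day <- tapply(tab$day, tab$participant_id, max)
  last <- rep(-1L, cohort_size)
  idx <- match(names(last_day), reg$participant_id)
  last[idx] <- as.integer(last_day)
  if (is.null(days)) days <- 0:max(c(last, 0L))
  days <- as.integer(days)
  retained <- switch(config$retention_definition,
    still_active_at_or_after_n = vapply(days, function(n) sum(last >= n), integer(1)),
    active_exactly_day_n = {
      active_days <- split(tab$day, tab$participant_id)
      vapply(days, function(n) {
        sum(vapply(active_days, function(d) n %in% d, logical(1)))
      }, integer(1))
    }
  )
  frac <- if (cohort_size > 0) retained / cohort_size else rep(NA_real_, length(days))
  curve <- tibble::tibble(
    day = days,
    retained = retained,
    cohort_size = cohort_size,
    fraction = frac
  )
  structure(curve, series = series, definition = config$retention_definition,
            n_excluded = n_excluded,
            class = c("retention_curve", class(curve)))
}

# ---- power-law tail ---------------------------------------------------------

#' Sample a discrete power law by its CCDF exponent
#'
#' Draws positive integers with P(X >= n) = n^(-ccdf_exponent) exactly
#' (inverse-transform on the integer grid). This is the heavy-tailed law the
#' behavior simulator uses for inactivity gaps; its CCDF is an exact power
#' law, so a log-log slope fit recovers `ccdf_exponent`.
#'
#' @param n number of draws
#' @param ccdf_exponent positive CCDF slope magnitude
#' @return integer vector of draws >= 1
#' @export
rdiscrete_powerlaw <- function(n, ccdf_exponent) {
  stopifnot(ccdf_exponent > 0)
  as.integer(floor(runif(n)^(-1 / ccdf_exponent)))
}

# Hurwitz zeta via direct summation with an Euler-Maclaurin tail
hurwitz_zeta <- function(s, a, terms = 2000L) {
  k <- a + seq_len(terms) - 1
  n_tail <- a + terms
  sum(k^(-s)) + n_tail^(1 - s) / (s - 1) + 0.5 * n_tail^(-s) -
    (s / 12) * n_tail^(-s - 1)
}

#' Fit a power-law tail to a CCDF curve
#'
#' `method = "loglog_ls"` (the reporting convention here) regresses
#' log P(X >= n) on log n over support points n >= xmin with positive
#' probability and reports the slope magnitude `alpha` with r-squared as
#' goodness. When the curve carries empirical counts the regression is
#' variance-stabilized: var(log p-hat) is approximately (1 - p) / (N p), so
#' points are weighted by numerator / (1 - p), which keeps the handful of
#' noisy single-observation tail points from dominating the fit. On an
#' exact curve P(X >= n) = n^(-a) either way recovers a to machine
#' precision.
#'
#' `method = "discrete_mle"` maximizes the zeta-distribution likelihood for
#' the density exponent and reports it minus one — the CCDF-slope scale, so
#' the two methods are directly comparable — with the Kolmogorov-Smirnov
#' distance between the empirical and fitted CCDFs as goodness.
#'
#' @param curve a `ccdf_curve` whose support carries the raw counts
#' @param xmin lower cutoff for the fit (>= 1)
#' @param method `"loglog_ls"` or `"discrete_mle"`
#' @return a `powerlaw_fit` list: `alpha`, `xmin`, `method`, `goodness`,
#'   `n_points`
#' @export
fit_powerlaw <- function(curve, xmin = 1L, method = c("loglog_ls", "discrete_mle")) {
  method <- match.arg(method)
  stopifnot(xmin >= 1)
  use <- curve$n >= xmin & curve$probability > 0
  if (sum(use) < 3) {
    stop_dhengage("power-law fit undefined: fewer than 3 usable support points",
                  "dhengage_fit_error")
  }
  if (method == "loglog_ls") {
    x <- log(curve$n[use])
    y <- log(curve$probability[use])
    wt <- if (all(is.na(curve$numerator[use]))) {
      rep(1, sum(use))
    } else {
      # inverse-variance weights for log of a binomial proportion
      curve$numerator[use] / pmax(1 - curve$probability[use], 1e-9)
    }
    fit <- lm(y ~ x, weights = wt)
    alpha <- abs(unname(coef(fit)[2]))
    ybar <- sum(wt * y) / sum(wt)
    goodness <- 1 - sum(wt * fit$residuals^2) / sum(wt * (y - ybar)^2)
  } else {
    # recover the value counts from the CCDF numerators
    sub <- curve[curve$n >= xmin, , drop = FALSE]
    counts <- c(-diff(sub$numerator), sub$numerator[nrow(sub)])
    vals <- sub$n
    keep <- counts > 0
    vals <- vals[keep]; counts <- counts[keep]
    nll <- function(s) {
      sum(counts) * log(hurwitz_zeta(s, xmin)) + s * sum(counts * log(vals))
    }
    opt <- optimize(nll, interval = c(1.000001, 12))
    s_hat <- opt$minimum
    alpha <- s_hat - 1
    # KS distance between empirical and fitted CCDF on the observed support
    emp <- sub$numerator[keep] / sub$numerator[keep][1]
    z <- hurwitz_zeta(s_hat, xmin)
    pmf <- function(k) k^(-s_hat) / z
    grid <- xmin:max(vals)
    cdf <- cumsum(pmf(grid))
    fit_ccdf <- 1 - c(0, cdf[-length(cdf)])[match(vals, grid)]
    goodness <- max(abs(emp - fit_ccdf))
  }
  structure(
    list(alpha = alpha, xmin = as.integer(xmin), method = method,
         goodness = goodness, n_points = sum(use)),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  gname <- if (x$method == "loglog_ls") "r.squared" else "KS"
  cat(sprintf("<powerlaw_fit> alpha=%.4f (xmin=%d, %s, %s=%.4f, %d points)\n",
              x$alpha, x$xmin, x$method, gname, x$goodness, x$n_points))
  invisible(x)
}

#' Export a CCDF curve as a tidy data frame
#' @param x a `ccdf_curve`
#' @param ... unused
#' @return tibble with unit, series, n, numerator, denominator, probability
#' @export
as_tidy_ccdf <- function(x, ...) {
  tibble::tibble(
    unit = attr(x, "unit"),
    series = attr(x, "series"),
    n = x$n,
    numerator = x$numerator,
    denominator = x$denominator,
    probability = x$probability
  )
}
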