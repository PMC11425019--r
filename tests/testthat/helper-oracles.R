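# Independent brute-force oracles used to cross-check the implementation.

# consecutive-day scan: walk the day range one day at a time
oracle_runs_gaps <- function(days) {
  days <- sort(unique(days))
  if (length(days) == 0) {
    return(list(run_lengths = integer(), gaps = integer()))
  }
  runs <- integer(); gaps <- integer()
  cur_run <- 0L; cur_gap <- 0L
  for (d in min(days):max(days)) {
    if (d %in% days) {
      if (cur_gap > 0) { gaps <- c(gaps, cur_gap); cur_gap <- 0L }
      cur_run <- cur_run + 1L
    } else {
      if (cur_run > 0) { runs <- c(runs, cur_run); cur_run <- 0L }
      cur_gap <- cur_gap + 1L
    }
  }
  if (cur_run > 0) runs <- c(runs, cur_run)
  list(run_lengths = runs, gaps = gaps)
}

# per-participant milestone counting, one participant at a time
oracle_funnel <- function(registry, window = NULL) {
  reg <- as.data.frame(registry)
  counts <- c(registered = 0L, consented = 0L, activated = 0L)
  for (i in seq_len(nrow(reg))) {
    if (!is.null(window)) {
      if (is.na(reg$registration_date[i]) ||
          reg$registration_date[i] < window$start_date ||
          reg$registration_date[i] > window$end_date) next
    }
    counts["registered"] <- counts["registered"] + 1L
    if (!is.na(reg$consent_date[i])) counts["consented"] <- counts["consented"] + 1L
    if (!is.na(reg$activation_date[i])) counts["activated"] <- counts["activated"] + 1L
  }
  counts
}

# event grouping by concatenated key
oracle_daily_profiles <- function(events) {
  ev <- as.data.frame(events)
  ev$date <- as.Date(ev$timestamp, tz = "UTC")
  key <- paste(ev$participant_id, ev$date)
  split_tests <- lapply(split(ev$test, key), function(x) sort(unique(x)))
  out <- do.call(rbind, strsplit(names(split_tests), " "))
  df <- data.frame(participant_id = out[, 1], date = as.Date(out[, 2]))
  df$tests <- unname(split_tests)
  df[order(df$participant_id, df$date), ]
}

# retention by looping participants and counting last active day >= n
oracle_retention <- function(day_table, cohort_ids, n) {
  retained <- 0L
  for (pid in cohort_ids) {
    d <- day_table$day[day_table$participant_id == pid]
    if (length(d) > 0 && max(d) >= n) retained <- retained + 1L
  }
  retained
}

# P(G = g) for the discrete power law with CCDF g^(-a)
pl_pmf <- function(g, a) g^(-a) - (g + 1)^(-a)

# exact day-level recursion for the behavior process:
# phi(m) = P(some active day >= m | a streak starts at day 0)
# streaks geometric (continue prob s), stop after a streak w.p. 1 - p_return,
# gap G ~ discrete power law (CCDF slope a), gap survived w.p. (1-h)^G
oracle_retention_phi <- function(m, s, p_return, a, h, gmax = 20000L) {
  memo <- rep(NA_real_, m + 1)
  # discounted gap mass from g0 to infinity (tail beyond gmax is negligible
  # for h > 0; for h = 0 it is the exact CCDF tail)
  gap_tail <- function(g0) {
    if (h == 0) return(g0^(-a))
    g <- g0:gmax
    sum(pl_pmf(g, a) * (1 - h)^g)
  }
  phi <- function(mm) {
    if (mm <= 0) return(1)
    if (!is.na(memo[mm])) return(memo[mm])
    val <- s^mm
    for (k in 1:mm) {
      pk <- (1 - s) * s^(k - 1)
      inner <- gap_tail(max(1L, mm - k))
      if (mm - k > 1) {
        g <- 1:(mm - k - 1)
        inner <- inner + sum(pl_pmf(g, a) * (1 - h)^g *
                               vapply(mm - k - g, phi, numeric(1)))
      }
      val <- val + pk * p_return * inner
    }
    memo[mm] <<- val
    val
  }
  phi(m)
}

# inverse-CDF sampler for a true zeta (discrete Pareto) distribution,
# support truncated far into the tail; used to cross-check the MLE
oracle_rzeta <- function(n, s, kmax = 1e6) {
  k <- seq_len(kmax)
  pmf <- k^(-s)
  pmf <- pmf / sum(pmf)
  sample.int(kmax, n, replace = TRUE, prob = pmf)
}

# random sparse activity pattern on a day grid
random_day_pattern <- function(max_day = 60, p_active = 0.3) {
  sort(sample(0:max_day, size = max(1, rbinom(1, max_day + 1, p_active))))
}
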