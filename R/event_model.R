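# Domain types and file IO for participant registries and test-completion
# event logs. Containers are plain tibbles with validated columns; readers
# accept a column-name "dialect" so differently labelled exports map onto the
# canonical schema.

#' Canonical smartphone test battery
#'
#' The eight active tests a participant can complete in the app: the Daily
#' Mood Question (DMQ), Information Processing Speed test (IPS) and its
#' Digit-Digit control (IPSDD), Pinching Test (PT), Draw a Shape (DaS),
#' Static Balance Test (SBT), U-Turn Test (UTT), and the Two-Minute Walk
#' Test (TwoMWT), which is administered separately from the daily sequence.
#'
#' @return character vector of canonical test codes
#' @export
test_battery <- function() {
  c("DMQ", "IPS", "IPSDD", "PT", "DaS", "SBT", "UTT", "TwoMWT")
}

# synonym table: normalized source spelling -> canonical code
.test_synonyms <- local({
  syn <- c(
    "dmq" = "DMQ", "dailymoodquestion" = "DMQ", "mood" = "DMQ",
    "ips" = "IPS", "informationprocessingspeed" = "IPS", "symbols" = "IPS",
    "ipsdd" = "IPSDD", "ipsdigitdigit" = "IPSDD", "digitdigit" = "IPSDD",
    "pt" = "PT", "pinching" = "PT", "pinchingtest" = "PT", "pinchatomato" = "PT",
    "das" = "DaS", "drawashape" = "DaS", "shape" = "DaS",
    "sbt" = "SBT", "staticbalance" = "SBT", "staticbalancetest" = "SBT",
    "utt" = "UTT", "uturn" = "UTT", "uturntest" = "UTT",
    "twomwt" = "TwoMWT", "2mwt" = "TwoMWT", "twominutewalk" = "TwoMWT",
    "twominutewalktest" = "TwoMWT", "2minutewalktest" = "TwoMWT",
    "2minutewalk" = "TwoMWT"
  )
  syn
})

normalize_test_key <- function(x) {
  tolower(gsub("[^A-Za-z0-9]", "", x))
}

#' Map source test labels to canonical codes
#'
#' Resolves free-form test names ("2MWT", "Two-Minute Walk Test", "u-turn")
#' to the canonical battery codes via a synonym table. Unresolvable labels
#' return `NA` so callers can quarantine rather than silently drop them.
#'
#' @param x character vector of source labels
#' @param extra_synonyms optional named character vector of additional
#'   source-label -> canonical-code mappings
#' @return character vector of canonical codes, `NA` where unresolved
#' @export
resolve_test_names <- function(x, extra_synonyms = NULL) {
  syn <- .test_synonyms
  if (!is.null(extra_synonyms)) {
    names(extra_synonyms) <- normalize_test_key(names(extra_synonyms))
    syn <- c(extra_synonyms, syn)
  }
  out <- unname(syn[normalize_test_key(x)])
  out
}

.default_registry_dialect <- list(
  participant_id = "participant_id",
  registration_date = "registration_date",
  consent_date = "consent_date",
  activation_date = "activation_date",
  ms_status = "ms_status",
  platform = "platform"
)

.default_event_dialect <- list(
  participant_id = "participant_id",
  test = "test",
  timestamp = "timestamp"
)

parse_date_col <- function(x, col, what = "registry") {
  if (is_date(x)) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  nonblank <- !is.na(x) & nzchar(trimws(x))
  parsed <- suppressWarnings(as.Date(x[nonblank], format = "%Y-%m-%d"))
  bad <- which(nonblank)[is.na(parsed)]
  if (length(bad) > 0) {
    stop_dhengage(
      sprintf(
        "unparseable date in column '%s' (%s), line(s) %s",
        col, what, paste(bad + 1L, collapse = ", ")
      ),
      "dhengage_parse_error"
    )
  }
  out[nonblank] <- parsed
  out
}

#' Construct a participant registry
#'
#' Validates the registry invariants: non-empty ids, dates ordered
#' registration <= consent <= activation where present, and activation only
#' with consent. Unknown MS status / platform values map to `"unknown"`.
#'
#' @param participant_id character ids
#' @param registration_date Date of registration on the web portal
#' @param consent_date optional Date of e-consent
#' @param activation_date optional Date the app was activated
#' @param ms_status self-declared status, one of `"MS"`, `"non_MS"`, `"unknown"`
#' @param platform `"ios"`, `"android"` or `"unknown"`
#' @return tibble of class `participant_registry`
#' @export
participant_registry <- function(participant_id,
                                 registration_date,
                                 consent_date = as.Date(NA),
                                 activation_date = as.Date(NA),
                                 ms_status = "unknown",
                                 platform = "unknown") {
  n <- length(participant_id)
  reg <- tibble::tibble(
    participant_id = as.character(participant_id),
    registration_date = as.Date(registration_date),
    consent_date = rep_len(as.Date(consent_date), n),
    activation_date = rep_len(as.Date(activation_date), n),
    ms_status = rep_len(as.character(ms_status), n),
    platform = rep_len(as.character(platform), n)
  )
  reg$ms_status[!reg$ms_status %in% c("MS", "non_MS")] <- "unknown"
  reg$platform[!tolower(reg$platform) %in% c("ios", "android")] <- "unknown"
  reg$platform <- ifelse(reg$platform == "unknown", "unknown", tolower(reg$platform))
  bad <- registry_violations(reg)
  if (any(bad != "")) {
    stop_dhengage(
      sprintf(
        "invalid registry rows: %s",
        paste(sprintf("row %d (%s)", which(bad != ""), bad[bad != ""]), collapse = "; ")
      ),
      "dhengage_invariant_error"
    )
  }
  class(reg) <- c("participant_registry", class(reg))
  reg
}

# returns "" for valid rows, else the reason
registry_violations <- function(reg) {
  reason <- rep("", nrow(reg))
  reason[is.na(reg$participant_id) | !nzchar(reg$participant_id)] <- "empty participant_id"
  reason[is.na(reg$registration_date) & reason == ""] <- "missing registration_date"
  act_no_consent <- !is.na(reg$activation_date) & is.na(reg$consent_date)
  reason[act_no_consent & reason == ""] <- "activation requires consent"
  bad_order <-
    (!is.na(reg$consent_date) & reg$registration_date > reg$consent_date) |
    (!is.na(reg$activation_date) & !is.na(reg$consent_date) &
       reg$consent_date > reg$activation_date)
  reason[bad_order & reason == ""] <- "dates out of order"
  reason
}

#' Read a participant registry from delimited text
#'
#' @param path CSV file with a header row
#' @param dialect named list mapping canonical column names
#'   (`participant_id`, `registration_date`, `consent_date`,
#'   `activation_date`, `ms_status`, `platform`) to the file's column names;
#'   omitted entries use the canonical name itself
#' @return `participant_registry` tibble; rejected rows (invariant
#'   violations) are attached as attribute `"rejected"` with reasons and a
#'   warning is issued
#' @export
read_registry <- function(path, dialect = list()) {
  dialect <- utils::modifyList(.default_registry_dialect, dialect)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("participant_id", "registration_date")
  for (col in required) {
    if (!dialect[[col]] %in% names(raw)) {
      stop_dhengage(
        sprintf("registry is missing required column '%s'", dialect[[col]]),
        "dhengage_schema_error"
      )
    }
  }
  get_col <- function(canon, default) {
    src <- dialect[[canon]]
    if (src %in% names(raw)) raw[[src]] else rep(default, nrow(raw))
  }
  reg <- tibble::tibble(
    participant_id = as.character(get_col("participant_id", NA_character_)),
    registration_date = parse_date_col(get_col("registration_date", NA), "registration_date"),
    consent_date = parse_date_col(get_col("consent_date", NA_character_), "consent_date"),
    activation_date = parse_date_col(get_col("activation_date", NA_character_), "activation_date"),
    ms_status = as.character(get_col("ms_status", "unknown")),
    platform = as.character(get_col("platform", "unknown"))
  )
  reason <- registry_violations(reg)
  rejected <- reg[reason != "", , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- reason[reason != ""]
    rlang::warn(sprintf(
      "%d registry row(s) rejected: %s",
      nrow(rejected), paste(unique(rejected$reason), collapse = "; ")
    ))
  }
  out <- participant_registry(
    participant_id = reg$participant_id[reason == ""],
    registration_date = reg$registration_date[reason == ""],
    consent_date = reg$consent_date[reason == ""],
    activation_date = reg$activation_date[reason == ""],
    ms_status = reg$ms_status[reason == ""],
    platform = reg$platform[reason == ""]
  )
  attr(out, "rejected") <- rejected
  out
}

#' Write a participant registry to CSV
#' @param registry `participant_registry` tibble
#' @param path output file
#' @return `path`, invisibly
#' @export
write_registry <- function(registry, path) {
  readr::write_csv(tibble::as_tibble(registry), path, progress = FALSE)
  invisible(path)
}

#' Construct a test-completion event log
#'
#' One row per completed test: participant id, canonical test code and a
#' timestamp. Timestamps may be date-times (stored as POSIXct, UTC) or bare
#' dates; with bare dates within-day ordering is unknown and all analysis is
#' day-granular anyway.
#'
#' @param participant_id character ids
#' @param test canonical test codes (see [test_battery()])
#' @param timestamp POSIXct, Date, or parseable character
#' @return tibble of class `event_log`, sorted by (participant, timestamp)
#' @export
event_log <- function(participant_id, test, timestamp) {
  if (length(participant_id) == 0) {
    ev <- tibble::tibble(
      participant_id = character(),
      test = character(),
      timestamp = as.POSIXct(character(), tz = "UTC")
    )
    class(ev) <- c("event_log", class(ev))
    return(ev)
  }
  if (is_date(timestamp)) {
    ts <- as.POSIXct(as.character(timestamp), tz = "UTC")
  } else if (inherits(timestamp, "POSIXct")) {
    ts <- timestamp
  } else {
    ts <- parse_timestamp_col(as.character(timestamp))
  }
  bad_test <- !test %in% test_battery()
  if (any(bad_test)) {
    stop_dhengage(
      sprintf("unknown test code(s): %s", paste(unique(test[bad_test]), collapse = ", ")),
      "dhengage_invariant_error"
    )
  }
  if (any(is.na(participant_id) | !nzchar(participant_id))) {
    stop_dhengage("event with empty participant_id", "dhengage_invariant_error")
  }
  ev <- tibble::tibble(
    participant_id = as.character(participant_id),
    test = as.character(test),
    timestamp = ts
  )
  ev <- dplyr::arrange(ev, .data$participant_id, .data$timestamp, .data$test)
  class(ev) <- c("event_log", class(ev))
  ev
}

parse_timestamp_col <- function(x) {
  is_bare_date <- grepl("^\\s*\\d{4}-\\d{2}-\\d{2}\\s*$", x) | is.na(x)
  if (all(is_bare_date)) {
    out <- as.POSIXct(trimws(x), tz = "UTC", format = "%Y-%m-%d")
  } else {
    out <- as.POSIXct(trimws(x), tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                     "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  }
  bad <- which(!is.na(x) & nzchar(trimws(x)) & is.na(out))
  if (length(bad) > 0) {
    stop_dhengage(
      sprintf("unparseable timestamp at line(s) %s", paste(bad + 1L, collapse = ", ")),
      "dhengage_parse_error"
    )
  }
  out
}

#' Read a test-completion event log from delimited text
#'
#' Test labels are resolved through the synonym table (e.g. `"2MWT"` and
#' `"Two-Minute Walk Test"` both map to `TwoMWT`). Rows whose label cannot
#' be resolved are quarantined (attribute `"unknown_tests"`), never silently
#' dropped; if more than half the rows are unresolvable the file is assumed
#' to be the wrong one and reading fails.
#'
#' @param path CSV file with a header row
#' @param dialect named list mapping canonical names (`participant_id`,
#'   `test`, `timestamp`) to the file's column names
#' @param extra_synonyms additional test-label synonyms, named by source label
#' @return `event_log` tibble sorted by (participant, timestamp)
#' @export
read_event_log <- function(path, dialect = list(), extra_synonyms = NULL) {
  dialect <- utils::modifyList(.default_event_dialect, dialect)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    rlang::warn("event log is empty")
    return(event_log(character(), character(), as.Date(character())))
  }
  for (col in c("participant_id", "test", "timestamp")) {
    if (!dialect[[col]] %in% names(raw)) {
      stop_dhengage(
        sprintf("event log is missing required column '%s'", dialect[[col]]),
        "dhengage_schema_error"
      )
    }
  }
  test <- resolve_test_names(raw[[dialect$test]], extra_synonyms)
  unknown <- is.na(test)
  if (mean(unknown) > 0.5) {
    stop_dhengage(
      sprintf("%.0f%% of test names are unresolvable; is this the right file?",
              100 * mean(unknown)),
      "dhengage_schema_error"
    )
  }
  if (any(unknown)) {
    rlang::warn(sprintf("%d event(s) with unknown test names quarantined", sum(unknown)))
  }
  ev <- event_log(
    participant_id = raw[[dialect$participant_id]][!unknown],
    test = test[!unknown],
    timestamp = raw[[dialect$timestamp]][!unknown]
  )
  attr(ev, "unknown_tests") <- raw[unknown, , drop = FALSE]
  ev
}

#' Write an event log to CSV
#' @param events `event_log` tibble
#' @param path output file
#' @return `path`, invisibly
#' @export
write_event_log <- function(events, path) {
  out <- tibble::as_tibble(events)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Event calendar day under the configured timezone policy
#'
#' @param timestamp POSIXct vector
#' @param config an [analysis_config()]
#' @return Date vector
#' @export
event_date <- function(timestamp, config = analysis_config()) {
  tz <- switch(config$timezone_policy, utc = "UTC", source_local = "")
  as.Date(timestamp, tz = tz)
}

#' Validate an event log against a registry
#'
#' Partitions events into kept vs quarantined. Nothing is raised: every
#' problem becomes a quarantine row with a reason (`unknown_participant`,
#' `pre_activation`, `duplicate`) and the report counts them.
#'
#' @param registry `participant_registry`
#' @param events `event_log`
#' @param config an [analysis_config()]
#' @return a `study_log`: list with `registry`, `events` (kept),
#'   `quarantine` (events + `reason`), and `report` (counts by reason)
#' @export
validate_log <- function(registry, events, config = analysis_config()) {
  ev <- tibble::as_tibble(events)
  n_in <- nrow(ev)
  reason <- rep(NA_character_, n_in)

  known <- ev$participant_id %in% registry$participant_id
  reason[!known] <- "unknown_participant"

  act <- registry$activation_date[match(ev$participant_id, registry$participant_id)]
  d <- event_date(ev$timestamp, config)
  pre <- known & (is.na(act) | d < act)
  reason[pre & is.na(reason)] <- "pre_activation"

  dup <- duplicated(ev[, c("participant_id", "test", "timestamp")])
  reason[dup & is.na(reason)] <- "duplicate"

  kept <- ev[is.na(reason), , drop = FALSE]
  quarantine <- ev[!is.na(reason), , drop = FALSE]
  quarantine$reason <- reason[!is.na(reason)]

  stopifnot(nrow(kept) + nrow(quarantine) == n_in)
  report <- as.list(table(quarantine$reason))
  structure(
    list(
      registry = registry,
      events = structure(kept, class = c("event_log", class(kept))),
      quarantine = quarantine,
      report = list(n_input = n_in, n_kept = nrow(kept),
                    n_quarantined = nrow(quarantine), by_reason = report)
    ),
    class = "study_log"
  )
}

#' @export
print.study_log <- function(x, ...) {
  cat(sprintf(
    "<study_log> %d participants, %d events kept, %d quarantined\n",
    nrow(x$registry), nrow(x$events), nrow(x$quarantine)
  ))
  if (length(x$report$by_reason) > 0) {
    for (r in names(x$report$by_reason)) {
      cat(sprintf("  quarantined %s: %d\n", r, x$report$by_reason[[r]]))
    }
  }
  invisible(x)
}

#' Write quarantined events with reasons to CSV
#' @param log a `study_log`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_quarantine <- function(log, path) {
  q <- log$quarantine
  q$timestamp <- format(q$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(q, path, progress = FALSE)
  invisible(path)
}
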