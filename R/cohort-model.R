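# Cohort container: six related tables emulating a PDMS (patient data
# management system) export. One uniform timezone-naive clock; timestamps are
# stored as POSIXct in UTC and serialized as ISO-8601. Calendar days are
# midnight-to-midnight of that clock (configurable day-boundary offset in the
# day-labelling functions).

OBS_VARIABLES <- c("temperature", "heart_rate", "respiratory_rate",
                   "leukocyte_count", "immature_neutrophil_fraction")
CONTEXT_KINDS <- c("mechanical_ventilation", "pacemaker", "active_cooling")
SEX_LEVELS    <- c("female", "male", "other", "unknown")
SHIFT_LEVELS  <- c("early", "late", "night", "unspecified")
RATING_LEVELS <- c("positive", "negative", "missing")

COHORT_SCHEMA <- list(
  patients            = c("patient_id", "birth_datetime", "sex"),
  stays               = c("stay_id", "patient_id", "admit", "discharge"),
  observations        = c("patient_id", "timestamp", "variable", "value", "validated"),
  context             = c("patient_id", "kind", "acute", "start", "end"),
  reference_episodes  = c("patient_id", "stay_id", "start", "end"),
  routine_assessments = c("stay_id", "date", "shift", "rating")
)

#' Parse ISO-8601 timestamps on the cohort's uniform clock
#'
#' Accepts `"YYYY-MM-DD HH:MM:SS"` or the `"T"`-separated form, with seconds
#' optional. Empty strings and `NA` parse to `NA` (used for open-ended
#' reference episodes).
#'
#' @param x character vector.
#' @param what label used in error messages (e.g. `"stays$admit"`).
#' @return POSIXct vector (UTC, i.e. the uniform study clock).
#' @keywords internal
parse_timestamp <- function(x, what = "timestamp") {
  x <- as.character(x)
  blank <- is.na(x) | !nzchar(trimws(x))
  y <- gsub("T", " ", trimws(x), fixed = TRUE)
  y[!blank & !grepl(" ", y)] <- paste0(y[!blank & !grepl(" ", y)], " 00:00:00")
  out <- as.POSIXct(strptime(y, "%Y-%m-%d %H:%M:%S", tz = "UTC"), tz = "UTC")
  retry <- is.na(out) & !blank
  out[retry] <- as.POSIXct(strptime(y[retry], "%Y-%m-%d %H:%M", tz = "UTC"), tz = "UTC")
  out[blank] <- as.POSIXct(NA, tz = "UTC")
  bad <- which(!blank & is.na(out))
  if (length(bad)) {
    abort_schema(sprintf("unparseable timestamp in %s at row(s) %s: %s",
                         what, paste(utils::head(bad, 5), collapse = ", "),
                         paste(utils::head(x[bad], 5), collapse = ", ")),
                 rows = bad)
  }
  out
}

ts_chr <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out[is.na(x)] <- ""
  out
}

parse_date <- function(x, what = "date") {
  x <- as.character(x)
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad)) {
    abort_schema(sprintf("unparseable date in %s at row(s) %s",
                         what, paste(utils::head(bad, 5), collapse = ", ")),
                 rows = bad)
  }
  out
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

empty_table <- function(name) {
  cols <- COHORT_SCHEMA[[name]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}

#' Assemble a cohort from its component tables
#'
#' @param patients data.frame with columns `patient_id`, `birth_datetime`, `sex`.
#' @param stays data.frame with `stay_id`, `patient_id`, `admit`, `discharge`.
#' @param observations data.frame with `patient_id`, `timestamp`, `variable`
#'   (one of temperature, heart_rate, respiratory_rate, leukocyte_count,
#'   immature_neutrophil_fraction), `value`, `validated`.
#' @param context data.frame with `patient_id`, `kind` (mechanical_ventilation,
#'   pacemaker, active_cooling), `acute` (meaningful for ventilation only),
#'   `start`, `end`.
#' @param reference_episodes adjudicated SIRS episodes: `patient_id`,
#'   `stay_id`, `start`, `end` (`NA` end = ongoing at discharge).
#' @param routine_assessments per-shift bedside ratings: `stay_id`, `date`,
#'   `shift`, `rating`.
#' @param validate run [validate_cohort()] (default `TRUE`).
#' @return an object of class `sirs_cohort`: a list of the six tables with
#'   parsed timestamps.
#' @export
sirs_cohort <- function(patients = empty_table("patients"),
                        stays = empty_table("stays"),
                        observations = empty_table("observations"),
                        context = empty_table("context"),
                        reference_episodes = empty_table("reference_episodes"),
                        routine_assessments = empty_table("routine_assessments"),
                        validate = TRUE) {
  tabs <- list(patients = patients, stays = stays, observations = observations,
               context = context, reference_episodes = reference_episodes,
               routine_assessments = routine_assessments)
  for (nm in names(tabs)) {
    need <- COHORT_SCHEMA[[nm]]
    miss <- setdiff(need, names(tabs[[nm]]))
    if (length(miss)) {
      abort_schema(sprintf("table '%s' is missing column(s): %s",
                           nm, paste(miss, collapse = ", ")))
    }
    tabs[[nm]] <- tabs[[nm]][, need, drop = FALSE]
    rownames(tabs[[nm]]) <- NULL
  }

  tabs$patients$patient_id <- as.character(tabs$patients$patient_id)
  if (!inherits(tabs$patients$birth_datetime, "POSIXct"))
    tabs$patients$birth_datetime <- parse_timestamp(tabs$patients$birth_datetime,
                                                    "patients$birth_datetime")
  tabs$patients$sex <- as.character(tabs$patients$sex)

  tabs$stays$stay_id <- as.character(tabs$stays$stay_id)
  tabs$stays$patient_id <- as.character(tabs$stays$patient_id)
  for (f in c("admit", "discharge"))
    if (!inherits(tabs$stays[[f]], "POSIXct"))
      tabs$stays[[f]] <- parse_timestamp(tabs$stays[[f]], paste0("stays$", f))

  tabs$observations$patient_id <- as.character(tabs$observations$patient_id)
  if (!inherits(tabs$observations$timestamp, "POSIXct"))
    tabs$observations$timestamp <- parse_timestamp(tabs$observations$timestamp,
                                                   "observations$timestamp")
  tabs$observations$variable <- as.character(tabs$observations$variable)
  tabs$observations$value <- as.numeric(tabs$observations$value)
  tabs$observations$validated <- parse_logical(tabs$observations$validated)

  tabs$context$patient_id <- as.character(tabs$context$patient_id)
  tabs$context$kind <- as.character(tabs$context$kind)
  tabs$context$acute <- parse_logical(tabs$context$acute)
  for (f in c("start", "end"))
    if (!inherits(tabs$context[[f]], "POSIXct"))
      tabs$context[[f]] <- parse_timestamp(tabs$context[[f]], paste0("context$", f))

  tabs$reference_episodes$patient_id <- as.character(tabs$reference_episodes$patient_id)
  tabs$reference_episodes$stay_id <- as.character(tabs$reference_episodes$stay_id)
  for (f in c("start", "end"))
    if (!inherits(tabs$reference_episodes[[f]], "POSIXct"))
      tabs$reference_episodes[[f]] <-
        parse_timestamp(tabs$reference_episodes[[f]],
                        paste0("reference_episodes$", f))

  tabs$routine_assessments$stay_id <- as.character(tabs$routine_assessments$stay_id)
  if (!inherits(tabs$routine_assessments$date, "Date"))
    tabs$routine_assessments$date <- parse_date(tabs$routine_assessments$date,
                                                "routine_assessments$date")
  sh <- as.character(tabs$routine_assessments$shift)
  sh[is.na(sh) | !nzchar(sh)] <- "unspecified"
  tabs$routine_assessments$shift <- sh
  tabs$routine_assessments$rating <- as.character(tabs$routine_assessments$rating)

  out <- structure(tabs, class = "sirs_cohort")
  if (validate) validate_cohort(out)
  out
}

#' Validate a cohort's referential integrity and invariants
#'
#' Checks unique patient/stay identifiers, dangling references, admit <
#' discharge, non-overlapping stays and reference episodes per patient,
#' recognized categorical levels, finite values, the unit-interval constraint
#' on immature neutrophil fractions, and birth preceding all events.
#'
#' @param cohort a `sirs_cohort`.
#' @return the cohort, invisibly; errors are classed
#'   (`picusirs_schema_error`, `picusirs_integrity_error`,
#'   `picusirs_invariant_error`).
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$patients; s <- cohort$stays; o <- cohort$observations
  cx <- cohort$context; re <- cohort$reference_episodes
  ra <- cohort$routine_assessments

  if (anyDuplicated(p$patient_id))
    abort_integrity(sprintf("duplicate patient_id: %s",
                            paste(unique(p$patient_id[duplicated(p$patient_id)]), collapse = ", ")))
  if (anyDuplicated(s$stay_id))
    abort_integrity(sprintf("duplicate stay_id: %s",
                            paste(unique(s$stay_id[duplicated(s$stay_id)]), collapse = ", ")))

  bad_sex <- setdiff(unique(p$sex), SEX_LEVELS)
  if (length(bad_sex))
    abort_schema(sprintf("unknown sex level(s): %s", paste(bad_sex, collapse = ", ")))

  check_ref <- function(ids, known, from, field) {
    dangling <- setdiff(unique(ids), known)
    if (length(dangling))
      abort_integrity(sprintf("%s$%s references unknown id(s): %s",
                              from, field,
                              paste(utils::head(dangling, 10), collapse = ", ")))
  }
  check_ref(s$patient_id, p$patient_id, "stays", "patient_id")
  check_ref(o$patient_id, p$patient_id, "observations", "patient_id")
  check_ref(cx$patient_id, p$patient_id, "context", "patient_id")
  check_ref(re$patient_id, p$patient_id, "reference_episodes", "patient_id")
  check_ref(re$stay_id, s$stay_id, "reference_episodes", "stay_id")
  check_ref(ra$stay_id, s$stay_id, "routine_assessments", "stay_id")

  if (any(is.na(s$admit)) || any(is.na(s$discharge)))
    abort_schema("stays: admit and discharge must be present")
  if (any(s$admit >= s$discharge))
    abort_invariant(sprintf("stays with admit >= discharge: %s",
                            paste(s$stay_id[s$admit >= s$discharge], collapse = ", ")))
  for (pid in unique(s$patient_id[duplicated(s$patient_id)])) {
    w <- s[s$patient_id == pid, ]
    w <- w[order(w$admit), ]
    if (any(w$admit[-1] < w$discharge[-nrow(w)]))
      abort_invariant(sprintf("overlapping stays for patient %s", pid))
  }

  bad_var <- setdiff(unique(o$variable), OBS_VARIABLES)
  if (length(bad_var))
    abort_schema(sprintf("unknown observation variable(s): %s",
                         paste(bad_var, collapse = ", ")))
  if (nrow(o)) {
    if (any(!is.finite(o$value)))
      abort_invariant("observations: values must be finite")
    frac <- o$variable == "immature_neutrophil_fraction"
    if (any(frac) && any(o$value[frac] < 0 | o$value[frac] > 1))
      abort_invariant("immature_neutrophil_fraction values must lie in [0, 1]")
  }
  # birth precedes every observation and stay
  bmap <- setNames(as.numeric(p$birth_datetime), p$patient_id)
  if (nrow(o) && any(as.numeric(o$timestamp) < bmap[o$patient_id]))
    abort_invariant("observations timestamped before the patient's birth")
  if (nrow(s) && any(as.numeric(s$admit) < bmap[s$patient_id]))
    abort_invariant("stays admitted before the patient's birth")

  bad_kind <- setdiff(unique(cx$kind), CONTEXT_KINDS)
  if (length(bad_kind))
    abort_schema(sprintf("unknown context kind(s): %s", paste(bad_kind, collapse = ", ")))
  if (nrow(cx) && any(cx$start >= cx$end))
    abort_invariant("context intervals must have start < end")

  if (nrow(re)) {
    closed <- !is.na(re$end)
    if (any(closed & (re$start >= re$end)))
      abort_invariant("reference episodes must have start < end when closed")
    for (pid in unique(re$patient_id[duplicated(re$patient_id)])) {
      w <- re[re$patient_id == pid, ]
      w <- w[order(w$start), ]
      e <- ifelse(is.na(as.numeric(w$end)), Inf, as.numeric(w$end))
      if (any(as.numeric(w$start)[-1] < e[-nrow(w)]))
        abort_invariant(sprintf("overlapping reference episodes for patient %s", pid))
    }
  }

  bad_rating <- setdiff(unique(ra$rating), RATING_LEVELS)
  if (length(bad_rating))
    abort_schema(sprintf("unknown rating level(s): %s", paste(bad_rating, collapse = ", ")))
  bad_shift <- setdiff(unique(ra$shift), SHIFT_LEVELS)
  if (length(bad_shift))
    abort_schema(sprintf("unknown shift level(s): %s", paste(bad_shift, collapse = ", ")))
  if (nrow(ra)) {
    key <- paste(ra$stay_id, ra$date, ra$shift)
    if (anyDuplicated(key))
      abort_invariant(sprintf("duplicate routine assessment for (stay, date, shift): %s",
                              paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; ")))
  }
  invisible(cohort)
}

#' Read a cohort from a directory of delimited text files
#'
#' Expects the six comma-separated UTF-8 files written by [write_cohort()]:
#' `patients.csv`, `stays.csv`, `observations.csv`, `context.csv`,
#' `reference_episodes.csv`, `routine_assessments.csv`. Missing files are
#' treated as empty tables; empty strings are missing values.
#'
#' @param dir directory path.
#' @return a validated `sirs_cohort`.
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) abort_schema(sprintf("cohort directory not found: %s", dir))
  read_one <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) return(empty_table(name))
    df <- utils::read.csv(path, colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = NULL)
    miss <- setdiff(COHORT_SCHEMA[[name]], names(df))
    if (length(miss))
      abort_schema(sprintf("%s: missing column(s): %s",
                           path, paste(miss, collapse = ", ")))
    df
  }
  tabs <- lapply(names(COHORT_SCHEMA), read_one)
  names(tabs) <- names(COHORT_SCHEMA)
  do.call(sirs_cohort, tabs)
}

#' Write a cohort to a directory of delimited text files
#'
#' Inverse of [read_cohort()]; write then read is the identity on valid
#' cohorts and write -> read -> write is byte-stable. Open-ended episode ends
#' serialize as empty strings.
#'
#' @param cohort a `sirs_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, mode = 2) != 0)
    abort_schema(sprintf("cannot write to directory: %s", dir))
  fmt <- function(df) {
    for (nm in names(df)) {
      if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- ts_chr(df[[nm]])
      else if (inherits(df[[nm]], "Date")) df[[nm]] <- format(df[[nm]], "%Y-%m-%d")
      else if (is.logical(df[[nm]])) {
        v <- ifelse(is.na(df[[nm]]), "", ifelse(df[[nm]], "true", "false"))
        df[[nm]] <- v
      } else if (is.numeric(df[[nm]])) df[[nm]] <- format(df[[nm]], digits = 15, trim = TRUE)
    }
    df
  }
  for (name in names(COHORT_SCHEMA)) {
    utils::write.csv(fmt(cohort[[name]]), file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE, quote = FALSE, eol = "\n")
  }
  invisible(dir)
}

#' Enumerate the calendar days of an intensive-care stay
#'
#' Returns every calendar date whose intersection with the half-open stay
#' window `[admit, discharge)` is non-empty, in order. These are the
#' patient-days of the day-level analysis. A day boundary offset shifts
#' the midnight cut (e.g. `day_offset_hours = 6` makes days run 06:00-06:00).
#'
#' @param admit,discharge POSIXct stay boundaries.
#' @param day_offset_hours day-boundary offset, default 0 (midnight).
#' @return a `Date` vector.
#' @export
enumerate_patient_days <- function(admit, discharge, day_offset_hours = 0) {
  if (is.na(admit) || is.na(discharge) || !(admit < discharge))
    abort_invariant("enumerate_patient_days: admit must precede discharge")
  off <- day_offset_hours * 3600
  a <- as.numeric(admit) - off
  d <- as.numeric(discharge) - off
  first <- floor(a / 86400)
  last <- ceiling(d / 86400) - 1
  as.Date(seq(first, last), origin = "1970-01-01")
}

#' @export
print.sirs_cohort <- function(x, ...) {
  cat("<sirs_cohort>\n")
  for (nm in names(COHORT_SCHEMA))
    cat(sprintf("  %-20s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}
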