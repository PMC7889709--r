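# From a continuous SIRS state to discrete episodes (24-h closing rule) and
# SIRS-positive patient-days (one-full-hour rule).

state_iv <- function(state) {
  if (inherits(state, "sirs_state") || is.data.frame(state))
    iv_merge(iv(as.numeric(state$start), as.numeric(state$end)))
  else abort_parameter("expected a sirs_state or a data.frame with start/end")
}

#' Build SIRS episodes from a continuous state
#'
#' Raw SIRS intervals separated by less than `closing_gap_hours` of non-SIRS
#' time belong to one episode: an episode ends only once the criteria are
#' unfulfilled for at least the closing gap, and the documented end is the
#' last instant criteria held (not the end of the gap). Merged episodes whose
#' span falls short of `min_duration_minutes` are discarded.
#'
#' @param state a `sirs_state` (or data.frame with `start`, `end`).
#' @param closing_gap_hours episode closing rule, default 24.
#' @param min_duration_minutes minimum episode span, default 60.
#' @return data.frame `start`, `end` (numeric seconds), `criteria` provenance
#'   (comma-joined union over the merged raw intervals, `""` if unknown).
#' @export
build_episodes <- function(state, closing_gap_hours = 24, min_duration_minutes = 60) {
  if (closing_gap_hours <= 0) abort_parameter("closing_gap_hours must be positive")
  if (min_duration_minutes < 0) abort_parameter("min_duration_minutes must be non-negative")
  x <- state_iv(state)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      criteria = character(0), stringsAsFactors = FALSE)
  if (!nrow(x)) return(empty)
  merged <- iv_merge(x, gap = closing_gap_hours * 3600, open = TRUE)
  merged <- merged[(merged$end - merged$start) >= min_duration_minutes * 60, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  crit <- rep("", nrow(merged))
  if (is.data.frame(state) && "criteria" %in% names(state) && nrow(state)) {
    for (i in seq_len(nrow(merged))) {
      inside <- as.numeric(state$start) < merged$end[i] &
        as.numeric(state$end) > merged$start[i]
      cs <- unique(unlist(strsplit(state$criteria[inside], ",")))
      crit[i] <- paste(intersect(CRITERIA, cs), collapse = ",")
    }
  }
  data.frame(start = merged$start, end = merged$end, criteria = crit,
             stringsAsFactors = FALSE)
}

day_window <- function(date, day_offset_hours = 0) {
  s <- as.numeric(date) * 86400 + day_offset_hours * 3600
  c(s, s + 86400)
}

#' Label the calendar days of a stay by SIRS status
#'
#' For every patient-day of the stay, counts the SIRS minutes intersecting
#' that calendar date and applies the one-full-hour rule: under the default
#' cumulative reading a day is SIRS-positive when total SIRS time that date
#' reaches 60 minutes; under the contiguous reading a single uninterrupted
#' 60-minute run within the date is required.
#'
#' @param state a `sirs_state` or data.frame with `start`, `end`.
#' @param stay list/row with `stay_id`, `admit`, `discharge`.
#' @param config a [detect_config()] (uses `day_offset_hours`, `day_rule`).
#' @return data.frame `stay_id`, `date`, `sirs_positive`, `minutes_in_sirs`.
#' @export
label_days <- function(state, stay, config = detect_config()) {
  x <- iv_clip(state_iv(state), as.numeric(stay$admit), as.numeric(stay$discharge))
  dates <- enumerate_patient_days(stay$admit, stay$discharge, config$day_offset_hours)
  minutes <- numeric(length(dates))
  positive <- logical(length(dates))
  for (i in seq_along(dates)) {
    w <- day_window(dates[i], config$day_offset_hours)
    inside <- iv_clip(x, w[1], w[2])
    minutes[i] <- iv_length(inside) / 60
    positive[i] <- if (config$day_rule == "cumulative") minutes[i] >= 60
    else nrow(inside) > 0 && max(inside$end - inside$start) >= 3600
  }
  data.frame(stay_id = rep(stay$stay_id, length(dates)), date = dates,
             sirs_positive = positive, minutes_in_sirs = minutes,
             stringsAsFactors = FALSE)
}

#' Day labels implied by adjudicated reference episodes
#'
#' Treats the reference episodes of one stay as the SIRS state and applies
#' [label_days()]. Open-ended episodes (no documented end) are truncated at
#' discharge.
#'
#' @param episodes reference episode rows for this stay (`start`, `end`;
#'   `end` may be `NA` for ongoing episodes).
#' @param stay list/row with `stay_id`, `admit`, `discharge`.
#' @param config a [detect_config()].
#' @return as [label_days()].
#' @export
reference_day_labels <- function(episodes, stay, config = detect_config()) {
  s <- as.numeric(episodes$start)
  e <- as.numeric(episodes$end)
  e[is.na(e)] <- as.numeric(stay$discharge)
  label_days(data.frame(start = s, end = e), stay, config)
}

#' Detected episodes and day labels for a whole detection run
#'
#' Convenience wrapper applying [build_episodes()] and [label_days()] to the
#' per-stay states from [detect()].
#'
#' @param detection result of [detect()].
#' @param config a [detect_config()].
#' @return list with `episodes` (stay_id, patient_id, start, end, criteria as
#'   POSIXct-stamped data.frame) and `day_labels`.
#' @export
detection_tables <- function(detection, config = detect_config()) {
  eps <- list(); days <- list()
  for (state in detection) {
    stay <- list(stay_id = attr(state, "stay_id"),
                 admit = attr(state, "admit"),
                 discharge = attr(state, "discharge"))
    e <- build_episodes(state, config$closing_gap_hours, config$min_episode_minutes)
    if (nrow(e)) {
      eps[[length(eps) + 1]] <- data.frame(
        stay_id = stay$stay_id, patient_id = attr(state, "patient_id"),
        start = as.POSIXct(e$start, origin = "1970-01-01", tz = "UTC"),
        end = as.POSIXct(e$end, origin = "1970-01-01", tz = "UTC"),
        criteria = e$criteria, stringsAsFactors = FALSE)
    }
    days[[length(days) + 1]] <- label_days(state, stay, config)
  }
  ep_empty <- data.frame(stay_id = character(0), patient_id = character(0),
                         start = as.POSIXct(character(0), tz = "UTC"),
                         end = as.POSIXct(character(0), tz = "UTC"),
                         criteria = character(0), stringsAsFactors = FALSE)
  list(episodes = if (length(eps)) do.call(rbind, eps) else ep_empty,
       day_labels = if (length(days)) do.call(rbind, days) else
         data.frame(stay_id = character(0), date = as.Date(character(0)),
                    sirs_positive = logical(0), minutes_in_sirs = numeric(0)))
}
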