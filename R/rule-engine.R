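# The four IPSCC criteria evaluated as boolean step functions over time.
# Point measurements are extended by sample-and-hold, compared against
# age-band limits resolved at every instant, and combined under the
# mandatory-criterion rule (>= 2 of 4, at least one of temperature /
# leukocytes) into a continuous SIRS state.

#' Detection configuration
#'
#' @param vital_horizon_hours how long a vital-sign measurement (temperature,
#'   heart rate, respiratory rate) remains valid if not superseded; default 4.
#' @param lab_horizon_hours validity horizon for laboratory values (leukocyte
#'   count, immature neutrophil fraction); default 24.
#' @param hypothermia if `FALSE` the low-temperature sub-rule is disabled
#'   (the hypothermia ablation of the sensitivity analysis).
#' @param validated_only if `TRUE`, observations with `validated = FALSE`
#'   are dropped before evaluation (strict mode); default uses all.
#' @param day_offset_hours day-boundary offset for calendar-day labelling.
#' @param day_rule `"cumulative"` (default): a day is SIRS-positive when total
#'   SIRS time that date reaches 60 minutes; `"contiguous"`: requires a single
#'   uninterrupted 60-minute run within the date.
#' @param closing_gap_hours episode closing rule: an episode ends only once
#'   criteria are unfulfilled for at least this long; default 24.
#' @param min_episode_minutes episodes shorter than this are discarded
#'   (flicker suppression, aligned with the one-hour day rule); default 60.
#' @return a `detect_config` list.
#' @export
detect_config <- function(vital_horizon_hours = 4,
                          lab_horizon_hours = 24,
                          hypothermia = TRUE,
                          validated_only = FALSE,
                          day_offset_hours = 0,
                          day_rule = c("cumulative", "contiguous"),
                          closing_gap_hours = 24,
                          min_episode_minutes = 60) {
  if (vital_horizon_hours <= 0 || lab_horizon_hours <= 0)
    abort_parameter("validity horizons must be positive")
  if (closing_gap_hours <= 0)
    abort_parameter("closing_gap_hours must be positive")
  if (min_episode_minutes < 0)
    abort_parameter("min_episode_minutes must be non-negative")
  structure(list(
    vital_horizon_hours = vital_horizon_hours,
    lab_horizon_hours = lab_horizon_hours,
    hypothermia = isTRUE(hypothermia),
    validated_only = isTRUE(validated_only),
    day_offset_hours = day_offset_hours,
    day_rule = match.arg(day_rule),
    closing_gap_hours = closing_gap_hours,
    min_episode_minutes = min_episode_minutes
  ), class = "detect_config")
}

#' Extend point measurements to a held step function
#'
#' Each observation's value holds from its timestamp until the next
#' observation or until the validity horizon expires, whichever comes first;
#' outside held segments the signal is unknown (and no criterion can fire).
#'
#' @param series data.frame with `timestamp` (POSIXct or numeric seconds) and
#'   `value`, sorted by timestamp. Ties keep the last value.
#' @param horizon_hours validity horizon.
#' @return data.frame `start`, `end` (numeric seconds), `value`.
#' @export
sample_and_hold <- function(series, horizon_hours) {
  t <- as.numeric(series$timestamp)
  if (is.unsorted(t)) abort_parameter("sample_and_hold: series must be sorted by timestamp")
  if (!length(t)) return(data.frame(start = numeric(0), end = numeric(0), value = numeric(0)))
  keep <- !duplicated(t, fromLast = TRUE)  # simultaneous re-measurement: last wins
  t <- t[keep]; v <- series$value[keep]
  h <- horizon_hours * 3600
  end <- pmin(c(t[-1], Inf), t + h)
  data.frame(start = t, end = end, value = v)[end > t, , drop = FALSE]
}

# directed pieces -> disjoint sorted intervals with combined direction labels
normalize_directed <- function(df) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (is.null(df) || !nrow(df)) return(empty)
  bounds <- sort(unique(c(df$start, df$end)))
  if (length(bounds) < 2) return(empty)
  s <- bounds[-length(bounds)]; e <- bounds[-1]
  mid <- (s + e) / 2
  lab <- vapply(mid, function(t) {
    paste(sort(unique(df$direction[df$start <= t & df$end > t])), collapse = "+")
  }, character(1))
  keep <- nzchar(lab)
  s <- s[keep]; e <- e[keep]; lab <- lab[keep]
  if (!length(s)) return(empty)
  # merge touching runs with identical label
  out_s <- s[1]; out_e <- e[1]; out_l <- lab[1]
  if (length(s) > 1) for (i in 2:length(s)) {
    k <- length(out_s)
    if (s[i] <= out_e[k] && lab[i] == out_l[k]) out_e[k] <- max(out_e[k], e[i])
    else { out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i]); out_l <- c(out_l, lab[i]) }
  }
  data.frame(start = out_s, end = out_e, direction = out_l, stringsAsFactors = FALSE)
}

new_criterion_state <- function(criterion, pieces) {
  structure(list(criterion = criterion, intervals = normalize_directed(pieces)),
            class = "criterion_state")
}

criterion_union <- function(state) iv_merge(iv(state$intervals$start, state$intervals$end))

# held segments for one variable of one patient, clipped to the stay window
held_for <- function(obs, variable, stay_lo, stay_hi, horizon_hours, validated_only) {
  o <- obs[obs$variable == variable, , drop = FALSE]
  if (validated_only) o <- o[is.na(o$validated) | o$validated, , drop = FALSE]
  o <- o[order(as.numeric(o$timestamp)), , drop = FALSE]
  held <- sample_and_hold(o, horizon_hours)
  if (!nrow(held)) return(held)
  held$start <- pmax(held$start, stay_lo)
  held$end <- pmin(held$end, stay_hi)
  held[held$end > held$start, , drop = FALSE]
}

# split held segments by the patient's age bands; error if any held time is
# outside band coverage (thresholds must cover the age at every instant)
split_by_bands <- function(held, bw) {
  if (!nrow(held)) return(cbind(held, band = character(0)))
  pieces <- list()
  for (i in seq_len(nrow(bw))) {
    s <- pmax(held$start, bw$start[i]); e <- pmin(held$end, bw$end[i])
    keep <- e > s
    if (any(keep))
      pieces[[length(pieces) + 1]] <- data.frame(
        start = s[keep], end = e[keep], value = held$value[keep],
        band = bw$band[i], stringsAsFactors = FALSE)
  }
  out <- if (length(pieces)) do.call(rbind, pieces) else cbind(held[0, ], band = character(0))
  covered <- if (nrow(out)) sum(out$end - out$start) else 0
  if (covered < iv_length(iv(held$start, held$end)) - 1e-6) {
    abort_config(sprintf(
      "age outside threshold band coverage (bands span days %s to %s after birth)",
      format(min(bw$start)), format(max(bw$end))))
  }
  out
}

context_iv <- function(context, kind, acute_only = FALSE) {
  if (is.null(context) || !nrow(context)) return(iv_empty())
  cx <- context[context$kind == kind, , drop = FALSE]
  if (acute_only) cx <- cx[!is.na(cx$acute) & cx$acute, , drop = FALSE]
  iv_merge(iv(as.numeric(cx$start), as.numeric(cx$end)))
}

cmp_beyond <- function(v, lim, side, exclusive) {
  if (is.na(lim)) return(rep(FALSE, length(v)))
  if (side == "high") { if (exclusive) v > lim else v >= lim }
  else { if (exclusive) v < lim else v <= lim }
}

directed_from_split <- function(sp, thresholds, criterion, exclusive,
                                require_brady = FALSE) {
  # returns df(start, end, direction) of raw threshold violations
  if (!nrow(sp)) return(NULL)
  rows <- list()
  for (band in unique(sp$band)) {
    lim <- band_limits(thresholds, band, criterion)
    w <- sp[sp$band == band, , drop = FALSE]
    hi <- cmp_beyond(w$value, lim$upper, "high", exclusive)
    lo <- cmp_beyond(w$value, lim$lower, "low", exclusive)
    if (require_brady && !isTRUE(lim$bradycardia)) lo <- rep(FALSE, nrow(w))
    if (any(hi)) rows[[length(rows) + 1]] <-
        data.frame(start = w$start[hi], end = w$end[hi], direction = "high")
    if (any(lo)) rows[[length(rows) + 1]] <-
        data.frame(start = w$start[lo], end = w$end[lo], direction = "low")
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

subtract_from_direction <- function(df, direction, sub_iv) {
  # remove sub_iv from the intervals of one direction, keep others untouched
  if (is.null(df) || !nrow(df) || !nrow(sub_iv)) return(df)
  keep <- df[df$direction != direction, , drop = FALSE]
  target <- df[df$direction == direction, , drop = FALSE]
  if (!nrow(target)) return(df)
  cut <- iv_setdiff(iv(target$start, target$end), sub_iv)
  res <- if (nrow(cut)) data.frame(start = cut$start, end = cut$end, direction = direction) else NULL
  rbind(keep, res)
}

#' Evaluate one SIRS criterion for one patient's stay
#'
#' Compares sample-and-held observation values against the age-band limits
#' active at each instant, applying the context rules: low temperature does
#' not fire during active cooling; the heart-rate criterion is silent during
#' pacemaker intervals; during mechanical ventilation measured respiratory
#' rates are not compared at all, and the respiratory criterion fires on the
#' ventilated interval itself exactly when the ventilation is flagged acute
#' (direction `"context"`). The leukocyte criterion is delegated to
#' [leukocyte_criterion()] since it combines two series.
#'
#' @param observations this patient's observation rows (any variables; the
#'   relevant ones are selected by `criterion`).
#' @param criterion one of `"temperature"`, `"heart_rate"`,
#'   `"respiratory_rate"`, `"leukocytes"`.
#' @param thresholds a [load_thresholds()] table.
#' @param birth the patient's birth datetime (POSIXct).
#' @param stay list or row with `admit`, `discharge`.
#' @param context this patient's context-interval rows (may be `NULL`).
#' @param config a [detect_config()].
#' @return a `criterion_state`: disjoint sorted intervals with a fired
#'   direction (`high`, `low`, `context`, or combinations), clipped to the
#'   stay window.
#' @export
evaluate_criterion <- function(observations, criterion, thresholds, birth, stay,
                               context = NULL, config = detect_config()) {
  criterion <- match.arg(criterion, CRITERIA)
  if (criterion == "leukocytes")
    return(leukocyte_criterion(observations, thresholds, birth, stay, context, config))
  lo <- as.numeric(stay$admit); hi <- as.numeric(stay$discharge)
  bw <- band_windows(thresholds, birth)
  excl <- thresholds$limits_exclusive
  held <- held_for(observations, criterion, lo, hi,
                   config$vital_horizon_hours, config$validated_only)
  sp <- split_by_bands(held, bw)
  fired <- directed_from_split(sp, thresholds, criterion, excl,
                               require_brady = criterion == "heart_rate")

  if (criterion == "temperature") {
    if (!config$hypothermia) fired <- if (is.null(fired)) NULL else fired[fired$direction != "low", , drop = FALSE]
    else fired <- subtract_from_direction(fired, "low", context_iv(context, "active_cooling"))
  } else if (criterion == "heart_rate") {
    pm <- context_iv(context, "pacemaker")
    fired <- subtract_from_direction(fired, "high", pm)
    fired <- subtract_from_direction(fired, "low", pm)
  } else if (criterion == "respiratory_rate") {
    vent <- iv_clip(context_iv(context, "mechanical_ventilation"), lo, hi)
    fired <- subtract_from_direction(fired, "high", vent)
    acute <- iv_clip(context_iv(context, "mechanical_ventilation", acute_only = TRUE), lo, hi)
    if (nrow(acute))
      fired <- rbind(fired, data.frame(start = acute$start, end = acute$end,
                                       direction = "context"))
  }
  new_criterion_state(criterion, fired)
}

#' Evaluate the leukocyte criterion (count limits or left shift)
#'
#' Fires where the held leukocyte count violates the age-band limits, or
#' where the held immature-neutrophil fraction exceeds the configured left
#' shift limit, whichever applies.
#'
#' @inheritParams evaluate_criterion
#' @return a `criterion_state` for criterion `"leukocytes"`.
#' @export
leukocyte_criterion <- function(observations, thresholds, birth, stay,
                                context = NULL, config = detect_config()) {
  lo <- as.numeric(stay$admit); hi <- as.numeric(stay$discharge)
  bw <- band_windows(thresholds, birth)
  excl <- thresholds$limits_exclusive
  held_count <- held_for(observations, "leukocyte_count", lo, hi,
                         config$lab_horizon_hours, config$validated_only)
  sp <- split_by_bands(held_count, bw)
  fired <- directed_from_split(sp, thresholds, "leukocytes", excl)

  held_frac <- held_for(observations, "immature_neutrophil_fraction", lo, hi,
                        config$lab_horizon_hours, config$validated_only)
  if (nrow(held_frac)) {
    shift <- cmp_beyond(held_frac$value, thresholds$immature_neutrophil_limit,
                        "high", excl)
    if (any(shift))
      fired <- rbind(fired, data.frame(start = held_frac$start[shift],
                                       end = held_frac$end[shift],
                                       direction = "high"))
  }
  new_criterion_state("leukocytes", fired)
}

#' Combine the four criterion states under the mandatory-criterion rule
#'
#' SIRS holds at an instant iff at least two criteria fire and at least one
#' of the mandatory criteria (temperature, leukocytes) fires. The result is
#' normalized to disjoint maximal intervals carrying as provenance the set of
#' criteria that fire anywhere on the interval.
#'
#' @param states named list of four `criterion_state` objects, names
#'   `temperature`, `leukocytes`, `heart_rate`, `respiratory_rate`.
#' @param mandatory the mandatory-criterion set; fixed default.
#' @return a `sirs_state`: data.frame `start`, `end`, `criteria`
#'   (comma-joined provenance), class-tagged.
#' @export
combine_criteria <- function(states, mandatory = c("temperature", "leukocytes")) {
  if (!all(CRITERIA %in% names(states)))
    abort_parameter(sprintf("combine_criteria: states must be named %s",
                            paste(CRITERIA, collapse = ", ")))
  unions <- lapply(states[CRITERIA], criterion_union)
  bounds <- sort(unique(unlist(lapply(unions, function(u) c(u$start, u$end)))))
  empty <- structure(data.frame(start = numeric(0), end = numeric(0),
                                criteria = character(0), stringsAsFactors = FALSE),
                     class = c("sirs_state", "data.frame"))
  if (length(bounds) < 2) return(empty)
  s <- bounds[-length(bounds)]; e <- bounds[-1]
  mid <- (s + e) / 2
  firing <- vapply(CRITERIA, function(cr) iv_covers(unions[[cr]], mid),
                   logical(length(mid)))
  firing <- matrix(firing, nrow = length(mid),
                   dimnames = list(NULL, CRITERIA))
  pos <- rowSums(firing) >= 2 & rowSums(firing[, mandatory, drop = FALSE]) >= 1
  if (!any(pos)) return(empty)
  s <- s[pos]; e <- e[pos]
  crit <- apply(firing[pos, , drop = FALSE], 1,
                function(r) paste(CRITERIA[r], collapse = ","))
  # merge touching intervals; provenance = union of contributing criteria
  out_s <- s[1]; out_e <- e[1]; out_c <- list(strsplit(crit[1], ",")[[1]])
  if (length(s) > 1) for (i in 2:length(s)) {
    k <- length(out_s)
    if (s[i] <= out_e[k] + 1e-9) {
      out_e[k] <- max(out_e[k], e[i])
      out_c[[k]] <- union(out_c[[k]], strsplit(crit[i], ",")[[1]])
    } else {
      out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i])
      out_c[[length(out_c) + 1]] <- strsplit(crit[i], ",")[[1]]
    }
  }
  structure(data.frame(
    start = out_s, end = out_e,
    criteria = vapply(out_c, function(x) paste(intersect(CRITERIA, x), collapse = ","), ""),
    stringsAsFactors = FALSE), class = c("sirs_state", "data.frame"))
}

#' Run the SIRS detector over a whole cohort
#'
#' For every stay: sample-and-hold each variable, evaluate the four criteria
#' with their context rules, and combine them into a continuous SIRS state.
#' Deterministic.
#'
#' @param cohort a `sirs_cohort`.
#' @param thresholds a threshold table; packaged IPSCC defaults if omitted.
#' @param config a [detect_config()].
#' @return named list (by `stay_id`) of `sirs_state` objects, with the stay's
#'   `patient_id`, `admit`, `discharge` attached as attributes.
#' @export
detect <- function(cohort, thresholds = load_thresholds(), config = detect_config()) {
  stays <- cohort$stays
  out <- vector("list", nrow(stays))
  names(out) <- stays$stay_id
  birth_map <- setNames(cohort$patients$birth_datetime, cohort$patients$patient_id)
  for (i in seq_len(nrow(stays))) {
    st <- stays[i, ]
    pid <- st$patient_id
    obs <- cohort$observations[cohort$observations$patient_id == pid, , drop = FALSE]
    cx <- cohort$context[cohort$context$patient_id == pid, , drop = FALSE]
    birth <- birth_map[[pid]]
    states <- list(
      temperature = evaluate_criterion(obs, "temperature", thresholds, birth, st, cx, config),
      leukocytes = leukocyte_criterion(obs, thresholds, birth, st, cx, config),
      heart_rate = evaluate_criterion(obs, "heart_rate", thresholds, birth, st, cx, config),
      respiratory_rate = evaluate_criterion(obs, "respiratory_rate", thresholds, birth, st, cx, config)
    )
    state <- combine_criteria(states, thresholds$mandatory_criteria)
    attr(state, "stay_id") <- st$stay_id
    attr(state, "patient_id") <- pid
    attr(state, "admit") <- st$admit
    attr(state, "discharge") <- st$discharge
    out[[i]] <- state
  }
  out
}
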