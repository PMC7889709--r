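# Stay-level scoring: tolerance-window episode matching, the six-case
# classification, and contingency assembly at stay and day level.
#
# Six cases and their assessment-unit contributions:
#   1 -> {FP}, 2 -> {TP}, 3 -> {FN}, 4 -> {TN}, 5 -> {FN, FP}, 6 -> {FP, TP};
# cases 5 and 6 contribute two assessment units, the others one.

CASE_CONTRIBUTES <- list(`1` = "FP", `2` = "TP", `3` = "FN", `4` = "TN",
                         `5` = c("FN", "FP"), `6` = c("FP", "TP"))

#' Match detected to reference episodes within a start-time tolerance
#'
#' One-to-one matching: a pair is admissible iff the detected start lies
#' within `tolerance_hours` of the reference start (boundary inclusive).
#' Greedy in reference start order, each reference episode taking the nearest
#' admissible unmatched detected episode; ties broken toward the earlier
#' detected start. Greedy matching can be sub-maximal on contrived
#' overlapping configurations (a documented limitation).
#'
#' @param reference,detected data.frames with a `start` column (POSIXct or
#'   numeric), sorted by start.
#' @param tolerance_hours matching window half-width, default 4.
#' @return list with `pairs` (data.frame `reference`, `detected` of row
#'   indices), `unmatched_reference`, `unmatched_detected` (integer indices).
#' @export
match_episodes <- function(reference, detected, tolerance_hours = 4) {
  if (tolerance_hours < 0) abort_parameter("tolerance_hours must be non-negative")
  tol <- tolerance_hours * 3600
  rs <- as.numeric(reference$start); ds <- as.numeric(detected$start)
  if (is.unsorted(rs) || is.unsorted(ds))
    abort_parameter("match_episodes: episode lists must be sorted by start")
  used <- rep(FALSE, length(ds))
  pr <- integer(0); pd <- integer(0)
  for (i in seq_along(rs)) {
    d <- abs(ds - rs[i])
    cand <- which(!used & d <= tol + 1e-9)
    if (!length(cand)) next
    cand <- cand[order(d[cand], ds[cand])]
    j <- cand[1]
    used[j] <- TRUE
    pr <- c(pr, i); pd <- c(pd, j)
  }
  list(pairs = data.frame(reference = pr, detected = pd),
       unmatched_reference = setdiff(seq_along(rs), pr),
       unmatched_detected = which(!used))
}

#' Classify one stay into the six-case scheme
#'
#' TP contribution iff at least one matched pair; FN iff reference episodes
#' exist and none matched (a stay with a match never also contributes FN:
#' additional unmatched reference episodes are absorbed, since the six cases
#' exclude a TP+FN combination); FP iff at least one detected episode is
#' unmatched; TN iff both sides are empty.
#'
#' @param matching result of [match_episodes()] for the stay.
#' @param n_reference,n_detected episode counts for the stay.
#' @return list with `case` (integer 1-6) and `contributes` (character
#'   multiset of cells).
#' @export
classify_stay <- function(matching, n_reference, n_detected) {
  n_pairs <- nrow(matching$pairs)
  if (n_pairs > min(n_reference, n_detected))
    abort_invariant("matching has more pairs than episodes")
  tp <- n_pairs >= 1
  fn <- n_reference >= 1 && n_pairs == 0
  fp <- length(matching$unmatched_detected) >= 1
  tn <- n_reference == 0 && n_detected == 0
  cells <- c(if (tp) "TP", if (fn) "FN", if (fp) "FP", if (tn) "TN")
  case <- if (tp && fp) 6L else if (fn && fp) 5L else if (tn) 4L
  else if (fn) 3L else if (tp) 2L else if (fp) 1L
  else abort_invariant("stay yields no assessment cell")
  list(case = case, contributes = cells)
}

#' Assemble the stay-level contingency table from six-case counts
#'
#' Cells: `tp = #2 + #6`, `fn = #3 + #5`, `fp = #1 + #5 + #6`, `tn = #4`.
#' The grand total equals the number of stays plus the count of the two
#' double-contribution cases (5 and 6), since those stays yield two
#' assessment units.
#'
#' @param cases integer vector of per-stay cases (1-6), or a named/positional
#'   length-6 vector of case counts if `counts = TRUE`.
#' @param counts interpret `cases` as the six case counts directly.
#' @return a `contingency_table`: list with cells, row/column/grand totals,
#'   case counts, `n_stays`, `level = "stay"`.
#' @export
stay_contingency <- function(cases, counts = FALSE) {
  if (counts) {
    if (length(cases) != 6) abort_parameter("expected six case counts")
    k <- as.integer(cases)
  } else {
    if (length(cases) && (any(cases < 1) || any(cases > 6)))
      abort_parameter("cases must lie in 1..6")
    k <- vapply(1:6, function(i) sum(cases == i), 0L)
  }
  tp <- k[2] + k[6]; fn <- k[3] + k[5]; fp <- k[1] + k[5] + k[6]; tn <- k[4]
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    row_totals = c(positive = tp + fp, negative = fn + tn),
    col_totals = c(positive = tp + fn, negative = fp + tn),
    grand_total = tp + fp + fn + tn,
    case_counts = setNames(k, paste0("case", 1:6)),
    n_stays = sum(k), level = "stay"
  ), class = "contingency_table")
}

#' Day-level contingency table from aligned day labels
#'
#' Classifies every patient-day by the (reference, detected) boolean pair.
#' Both label sets must cover exactly the same (stay, date) grid.
#'
#' @param reference_days,detected_days data.frames with `stay_id`, `date`,
#'   `sirs_positive`.
#' @return a `contingency_table` with `level = "day"`.
#' @export
day_contingency <- function(reference_days, detected_days) {
  rk <- paste(reference_days$stay_id, reference_days$date)
  dk <- paste(detected_days$stay_id, detected_days$date)
  if (anyDuplicated(rk) || anyDuplicated(dk))
    abort_integrity("day labels contain duplicate (stay, date) entries")
  if (!setequal(rk, dk))
    abort_integrity(sprintf(
      "day-label grids do not align (%d reference vs %d detected days; %d shared)",
      length(rk), length(dk), length(intersect(rk, dk))))
  det <- detected_days$sirs_positive[match(rk, dk)]
  ref <- reference_days$sirs_positive
  tp <- sum(ref & det); fn <- sum(ref & !det)
  fp <- sum(!ref & det); tn <- sum(!ref & !det)
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    row_totals = c(positive = tp + fp, negative = fn + tn),
    col_totals = c(positive = tp + fn, negative = fp + tn),
    grand_total = tp + fp + fn + tn,
    n_days = length(rk), level = "day"
  ), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> level=%s\n", x$level))
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(c("test+", "test-"), c("ref+", "ref-")))
  print(cbind(m, total = rowSums(m)))
  cat(sprintf("column totals: %d / %d; grand total %d\n",
              x$col_totals[1], x$col_totals[2], x$grand_total))
  invisible(x)
}

#' Collapse per-shift routine assessment forms to day level
#'
#' A day is rated positive if any non-missing shift form that day is
#' positive, negative if all non-missing forms are negative, and missing if
#' no form exists (forms explicitly rated `"missing"` count as absent).
#'
#' @param forms routine assessment rows for this stay (`stay_id`, `date`,
#'   `shift`, `rating`).
#' @param stay list/row with `stay_id`, `admit`, `discharge`.
#' @param day_offset_hours day-boundary offset.
#' @return data.frame `stay_id`, `date`, `rating` in
#'   {positive, negative, missing} covering every patient-day of the stay.
#' @export
aggregate_routine_forms <- function(forms, stay, day_offset_hours = 0) {
  dates <- enumerate_patient_days(stay$admit, stay$discharge, day_offset_hours)
  rating <- character(length(dates))
  for (i in seq_along(dates)) {
    f <- forms[forms$date == dates[i] & forms$rating != "missing", , drop = FALSE]
    rating[i] <- if (!nrow(f)) "missing"
    else if (any(f$rating == "positive")) "positive" else "negative"
  }
  data.frame(stay_id = rep(stay$stay_id, length(dates)), date = dates,
             rating = rating, stringsAsFactors = FALSE)
}
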