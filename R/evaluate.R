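# Full diagnostic-accuracy evaluation of a detector (or rater) against the
# adjudicated reference standard: stay-level six-case scoring, day-level
# contingency, GEE sensitivity/specificity clustered on patients, the
# no-SIRS-patient specificity, and null-hypothesis verdicts comparing CI
# lower bounds to the design nulls.

estimate_pair <- function(outcome, cluster, measure, conf_level = 0.95,
                          ci_scale = "logit") {
  n <- length(outcome)
  if (n == 0) return(NULL)
  crude <- crude_estimate(sum(outcome), n, measure, conf_level, ci_scale)
  gee <- if (n >= 2) gee_estimate(outcome, cluster, measure, conf_level, ci_scale)
  else crude
  list(crude = crude, gee = gee)
}

stay_units <- function(assessments) {
  # stay-level assessment units implied by the six cases
  sens <- assessments[assessments$case %in% c(2, 3, 5, 6), , drop = FALSE]
  spec <- assessments[assessments$case %in% c(1, 4, 5, 6), , drop = FALSE]
  list(
    sensitivity = data.frame(outcome = as.numeric(sens$case %in% c(2, 6)),
                             cluster = sens$patient_id,
                             stringsAsFactors = FALSE),
    specificity = data.frame(outcome = as.numeric(spec$case == 4),
                             cluster = spec$patient_id,
                             stringsAsFactors = FALSE)
  )
}

#' Evaluate a detector against the reference standard
#'
#' Scores detected episodes (and day labels) against the adjudicated
#' reference episodes: per-stay tolerance-window matching and six-case
#' classification, stay- and day-level contingency tables, sensitivity and
#' specificity estimated crude and by GEE with clusters = patients, the
#' specificity restricted to patients with no reference SIRS in any stay,
#' and hypothesis verdicts comparing the GEE CI lower bounds to the
#' configured null proportions.
#'
#' @param cohort a `sirs_cohort` (supplies stays, patients and, by default,
#'   the reference episodes).
#' @param detected_episodes data.frame `stay_id`, `start`, `end`.
#' @param reference_episodes data.frame `stay_id`, `start`, `end` (default:
#'   the cohort's reference table). Open ends are truncated at discharge.
#' @param detected_days,reference_days optional day labels (`stay_id`,
#'   `date`, `sirs_positive`); when `NULL` they are derived from the episode
#'   lists. Pass the detector's raw day labels when the continuous state is
#'   available, since episode merging can bridge sub-threshold days.
#' @param tolerance_hours episode-start matching window, default 4.
#' @param null_sensitivity,null_specificity design null proportions compared
#'   against the GEE CI lower bounds (defaults 0.90 and 0.80).
#' @param conf_level,ci_scale interval construction, see [wald_ci()].
#' @param config a [detect_config()] (day labelling options).
#' @return a `sirs_evaluation` list: `stay_level` (assessments, table,
#'   estimates, no-SIRS-patient specificity), `day_level` (table, estimates),
#'   `verdicts`, and a `config` echo.
#' @export
evaluate_accuracy <- function(cohort, detected_episodes,
                              reference_episodes = cohort$reference_episodes,
                              detected_days = NULL, reference_days = NULL,
                              tolerance_hours = 4,
                              null_sensitivity = 0.90, null_specificity = 0.80,
                              conf_level = 0.95, ci_scale = "logit",
                              config = detect_config()) {
  stays <- cohort$stays
  pat_of <- setNames(stays$patient_id, stays$stay_id)

  # ---- stay level ----
  rows <- vector("list", nrow(stays))
  for (i in seq_len(nrow(stays))) {
    sid <- stays$stay_id[i]
    re <- reference_episodes[reference_episodes$stay_id == sid, , drop = FALSE]
    de <- detected_episodes[detected_episodes$stay_id == sid, , drop = FALSE]
    re <- re[order(as.numeric(re$start)), , drop = FALSE]
    de <- de[order(as.numeric(de$start)), , drop = FALSE]
    m <- match_episodes(re, de, tolerance_hours)
    cls <- classify_stay(m, nrow(re), nrow(de))
    rows[[i]] <- data.frame(stay_id = sid, patient_id = pat_of[[sid]],
                            case = cls$case,
                            contributes = paste(cls$contributes, collapse = "+"),
                            n_reference = nrow(re), n_detected = nrow(de),
                            stringsAsFactors = FALSE)
  }
  assessments <- do.call(rbind, rows)
  stay_table <- stay_contingency(assessments$case)
  units <- stay_units(assessments)
  stay_sens <- estimate_pair(units$sensitivity$outcome, units$sensitivity$cluster,
                             "sensitivity", conf_level, ci_scale)
  stay_spec <- estimate_pair(units$specificity$outcome, units$specificity$cluster,
                             "specificity", conf_level, ci_scale)

  # specificity among patients with no reference SIRS in any stay
  sirs_patients <- unique(pat_of[as.character(reference_episodes$stay_id)])
  no_sirs <- units$specificity[!(units$specificity$cluster %in% sirs_patients), , drop = FALSE]
  spec_no_sirs <- estimate_pair(no_sirs$outcome, no_sirs$cluster,
                                "specificity", conf_level, ci_scale)

  # ---- day level ----
  if (is.null(reference_days) || is.null(detected_days)) {
    rd <- list(); dd <- list()
    for (i in seq_len(nrow(stays))) {
      st <- stays[i, ]
      sid <- st$stay_id
      re <- reference_episodes[reference_episodes$stay_id == sid, , drop = FALSE]
      de <- detected_episodes[detected_episodes$stay_id == sid, , drop = FALSE]
      rd[[i]] <- reference_day_labels(re, st, config)
      dd[[i]] <- label_days(data.frame(start = as.numeric(de$start),
                                       end = as.numeric(de$end)), st, config)
    }
    if (is.null(reference_days)) reference_days <- do.call(rbind, rd)
    if (is.null(detected_days)) detected_days <- do.call(rbind, dd)
  }
  day_table <- day_contingency(reference_days, detected_days)
  key <- paste(reference_days$stay_id, reference_days$date)
  det <- detected_days$sirs_positive[match(key, paste(detected_days$stay_id,
                                                      detected_days$date))]
  ref <- reference_days$sirs_positive
  day_cluster <- pat_of[as.character(reference_days$stay_id)]
  day_sens <- estimate_pair(as.numeric(det[ref]), day_cluster[ref],
                            "sensitivity", conf_level, ci_scale)
  day_spec <- estimate_pair(as.numeric(!det[!ref]), day_cluster[!ref],
                            "specificity", conf_level, ci_scale)

  pick <- function(pair) if (is.null(pair)) NULL else pair$gee
  verdict <- function(pair, null) {
    est <- pick(pair)
    if (is.null(est)) return(NULL)
    list(null = null, ci_low = unname(est$ci[1]),
         reject_null = !est$degenerate && est$ci[1] > null,
         degenerate = est$degenerate)
  }

  structure(list(
    stay_level = list(assessments = assessments, table = stay_table,
                      sensitivity = stay_sens, specificity = stay_spec,
                      specificity_no_sirs_patients = spec_no_sirs,
                      n_no_sirs_units = nrow(no_sirs)),
    day_level = list(table = day_table, sensitivity = day_sens,
                     specificity = day_spec,
                     reference_days = reference_days,
                     detected_days = detected_days),
    verdicts = list(sensitivity = verdict(stay_sens, null_sensitivity),
                    specificity = verdict(stay_spec, null_specificity)),
    config = list(tolerance_hours = tolerance_hours,
                  null_sensitivity = null_sensitivity,
                  null_specificity = null_specificity,
                  conf_level = conf_level, ci_scale = ci_scale,
                  day_rule = config$day_rule,
                  day_offset_hours = config$day_offset_hours)
  ), class = "sirs_evaluation")
}

#' @export
print.sirs_evaluation <- function(x, ...) {
  cat("<sirs_evaluation>\n-- stay level --\n")
  print(x$stay_level$table)
  for (m in c("sensitivity", "specificity"))
    if (!is.null(x$stay_level[[m]])) print(x$stay_level[[m]]$gee)
  cat("-- day level --\n")
  print(x$day_level$table)
  for (m in c("sensitivity", "specificity"))
    if (!is.null(x$day_level[[m]])) print(x$day_level[[m]]$gee)
  invisible(x)
}

#' Age-stratified evaluation
#'
#' Splits the cohort's stays at the age cutoff (age at that stay's admission)
#' and re-runs [evaluate_accuracy()] per stratum. A patient whose stays fall
#' on both sides contributes each stay to its own stratum, so stratum unit
#' counts partition the full-cohort counts. Empty strata are reported as
#' such, not raised.
#'
#' @param cohort a `sirs_cohort`.
#' @param detected_episodes as in [evaluate_accuracy()].
#' @param cutoff_months age cutoff, default 12 months (365.25 days).
#' @param ... passed to [evaluate_accuracy()].
#' @return list with elements `young` and `old`, each either a
#'   `sirs_evaluation` or a list `(empty = TRUE, n_stays = 0)`.
#' @export
subgroup_by_age <- function(cohort, detected_episodes, cutoff_months = 12, ...) {
  birth <- setNames(as.numeric(cohort$patients$birth_datetime),
                    cohort$patients$patient_id)
  age_days <- (as.numeric(cohort$stays$admit) - birth[cohort$stays$patient_id]) / 86400
  cutoff_days <- cutoff_months * 365.25 / 12
  young_ids <- cohort$stays$stay_id[age_days < cutoff_days]
  one <- function(ids) {
    if (!length(ids)) return(list(empty = TRUE, n_stays = 0L))
    sub <- cohort
    sub$stays <- cohort$stays[cohort$stays$stay_id %in% ids, , drop = FALSE]
    sub$reference_episodes <-
      cohort$reference_episodes[cohort$reference_episodes$stay_id %in% ids, , drop = FALSE]
    evaluate_accuracy(sub, detected_episodes[detected_episodes$stay_id %in% ids, , drop = FALSE], ...)
  }
  list(young = one(young_ids),
       old = one(setdiff(cohort$stays$stay_id, young_ids)))
}

#' Hypothermia-rule ablation
#'
#' Re-runs the detector with the low-temperature sub-rule disabled and
#' evaluates both runs, mirroring the sensitivity analysis that asks how much
#' of the false-alarm load is hypothermia-driven. Removing a rule can only
#' shrink the detected SIRS state (monotonicity).
#'
#' @param cohort a `sirs_cohort` with reference episodes.
#' @param thresholds threshold table.
#' @param config a [detect_config()]; `hypothermia` is overridden per arm.
#' @param ... passed to [evaluate_accuracy()].
#' @return list with `with` and `without`, each a `sirs_evaluation`, plus
#'   the two detection table sets.
#' @export
sensitivity_analysis_exclude_hypothermia <- function(cohort,
                                                     thresholds = load_thresholds(),
                                                     config = detect_config(), ...) {
  run <- function(hypo) {
    cfg <- config; cfg$hypothermia <- hypo
    det <- detect(cohort, thresholds, cfg)
    tabs <- detection_tables(det, cfg)
    list(tables = tabs,
         report = evaluate_accuracy(cohort, tabs$episodes,
                                    detected_days = tabs$day_labels,
                                    config = cfg, ...))
  }
  a <- run(TRUE); b <- run(FALSE)
  list(with = a$report, without = b$report,
       with_tables = a$tables, without_tables = b$tables)
}

#' Best/worst-case bounds under day-level missingness
#'
#' Brackets the complete-case estimates under the two extreme imputations:
#' best case counts every missing SIRS day as true positive and every missing
#' non-SIRS day as true negative; worst case counts them as false negative
#' and false positive respectively.
#'
#' @param complete_case list or `contingency_table` with `tp`, `fp`, `fn`,
#'   `tn` from the complete-case analysis.
#' @param missing_pos_days missing days whose reference status is SIRS.
#' @param missing_neg_days missing days without reference SIRS.
#' @param units optional unit-level data for GEE re-estimation: data.frame
#'   `cluster`, `reference` (logical), `rated` (logical, `NA` = missing).
#' @param conf_level,ci_scale interval construction.
#' @return list of three scenarios (`complete_case`, `best_case`,
#'   `worst_case`), each with the scenario table and crude (plus GEE when
#'   `units` given) sensitivity and specificity.
#' @export
missingness_bounds <- function(complete_case, missing_pos_days, missing_neg_days,
                               units = NULL, conf_level = 0.95,
                               ci_scale = "logit") {
  if (missing_pos_days < 0 || missing_neg_days < 0)
    abort_parameter("missing day counts must be non-negative")
  base <- list(tp = complete_case$tp, fp = complete_case$fp,
               fn = complete_case$fn, tn = complete_case$tn)
  tabs <- list(
    complete_case = base,
    best_case = within(base, { tp <- tp + missing_pos_days
                               tn <- tn + missing_neg_days }),
    worst_case = within(base, { fn <- fn + missing_pos_days
                                fp <- fp + missing_neg_days })
  )
  impute <- list(complete_case = NA, best_case = TRUE, worst_case = FALSE)
  out <- lapply(names(tabs), function(nm) {
    tb <- tabs[[nm]]
    res <- list(table = tb)
    res$sensitivity <- if (tb$tp + tb$fn > 0)
      crude_estimate(tb$tp, tb$tp + tb$fn, "sensitivity", conf_level, ci_scale)
    res$specificity <- if (tb$tn + tb$fp > 0)
      crude_estimate(tb$tn, tb$tn + tb$fp, "specificity", conf_level, ci_scale)
    if (!is.null(units)) {
      u <- units
      if (identical(impute[[nm]], NA)) u <- u[!is.na(u$rated), , drop = FALSE]
      else {
        miss <- is.na(u$rated)
        u$rated[miss] <- if (isTRUE(impute[[nm]])) u$reference[miss] else !u$reference[miss]
      }
      su <- u[u$reference, , drop = FALSE]
      pu <- u[!u$reference, , drop = FALSE]
      if (nrow(su) >= 2)
        res$sensitivity_gee <- gee_estimate(as.numeric(su$rated), su$cluster,
                                            "sensitivity", conf_level, ci_scale)
      if (nrow(pu) >= 2)
        res$specificity_gee <- gee_estimate(as.numeric(!pu$rated), pu$cluster,
                                            "specificity", conf_level, ci_scale)
    }
    res
  })
  names(out) <- names(tabs)
  out
}
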