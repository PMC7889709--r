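small_gen <- function(seed = 11, n = 12)
  generate_cohort(cohort_scenario(seed = seed, n_patients = n))

test_that("a perfect detector scores 1 everywhere with flagged degenerate CIs", {
  gen <- small_gen()
  ref <- gen$cohort$reference_episodes
  rep <- evaluate_accuracy(gen$cohort, ref)
  expect_true(all(rep$stay_level$assessments$case %in% c(2, 4)))
  for (lvl in list(rep$stay_level, rep$day_level)) {
    for (m in c("sensitivity", "specificity")) {
      if (is.null(lvl[[m]])) next
      expect_equal(lvl[[m]]$gee$estimate, 1)
      expect_true(lvl[[m]]$gee$degenerate)
    }
  }
  expect_equal(rep$stay_level$table$fp + rep$stay_level$table$fn, 0)
  expect_equal(rep$day_level$table$fp + rep$day_level$table$fn, 0)
  # a perfect detector cannot reject a null through a degenerate interval
  expect_false(is.null(rep$verdicts$sensitivity))
})

test_that("one extra detected episode in one stay yields exactly one case-6 stay", {
  gen <- small_gen(seed = 12)
  ref <- gen$cohort$reference_episodes
  # pick a stay that already has an episode and add a spurious detection
  sid <- ref$stay_id[1]
  st <- gen$cohort$stays[gen$cohort$stays$stay_id == sid, ]
  spur_start <- st$discharge - 6 * 3600
  extra <- data.frame(patient_id = st$patient_id, stay_id = sid,
                      start = spur_start, end = spur_start + 2 * 3600)
  det <- rbind(ref, extra)
  rep <- evaluate_accuracy(gen$cohort, det)
  expect_equal(sum(rep$stay_level$assessments$case == 6), 1)
  expect_equal(rep$stay_level$table$fp, 1)
})

test_that("age strata partition the full-cohort assessment units", {
  gen <- small_gen(seed = 13, n = 20)
  det <- gen$cohort$reference_episodes
  full <- evaluate_accuracy(gen$cohort, det)
  sub <- subgroup_by_age(gen$cohort, det)
  n_units <- function(r) if (isTRUE(r$empty)) 0 else r$stay_level$table$grand_total
  expect_equal(n_units(sub$young) + n_units(sub$old),
               full$stay_level$table$grand_total)
  n_days <- function(r) if (isTRUE(r$empty)) 0 else r$day_level$table$grand_total
  expect_equal(n_days(sub$young) + n_days(sub$old),
               full$day_level$table$grand_total)
})

test_that("an empty age stratum is flagged rather than raised", {
  gen <- small_gen(seed = 14, n = 6)
  co <- gen$cohort
  # age everyone up: cutoff far below any patient
  sub <- subgroup_by_age(co, co$reference_episodes, cutoff_months = 0.001)
  expect_true(isTRUE(sub$young$empty))
  expect_s3_class(sub$old, "sirs_evaluation")
})

test_that("specificity among never-SIRS patients restricts to those patients", {
  gen <- small_gen(seed = 15, n = 15)
  co <- gen$cohort
  rep <- evaluate_accuracy(co, co$reference_episodes)
  pat_of <- setNames(co$stays$patient_id, co$stays$stay_id)
  sirs_pats <- unique(pat_of[co$reference_episodes$stay_id])
  no_sirs_stays <- co$stays$stay_id[!(co$stays$patient_id %in% sirs_pats)]
  expect_equal(rep$stay_level$n_no_sirs_units, length(no_sirs_stays))
})

test_that("hypothermia-driven false alarms vanish when the rule is ablated", {
  # one infant whose only abnormality is low temperature plus tachycardia
  patients <- data.frame(patient_id = "H", birth_datetime = ts0("2018-05-01 00:00:00"),
                         sex = "female")
  stays <- data.frame(stay_id = "H1", patient_id = "H",
                      admit = ts0("2018-10-01 00:00:00"),
                      discharge = ts0("2018-10-03 00:00:00"))
  hours <- ts0("2018-10-01 06:00:00") + 3600 * (0:5)
  obs <- rbind(make_obs("H", hours, "temperature", rep(34.8, 6)),
               make_obs("H", hours, "heart_rate", rep(195, 6)),
               make_obs("H", ts0("2018-10-01 12:00:00"), "temperature", 37.1),
               make_obs("H", ts0("2018-10-01 12:00:00"), "heart_rate", 120))
  co <- sirs_cohort(patients, stays, obs)
  abl <- sensitivity_analysis_exclude_hypothermia(co)
  spec_with <- abl$with$stay_level$specificity$crude$estimate
  spec_without <- abl$without$stay_level$specificity$crude$estimate
  expect_equal(spec_with, 0)      # the hypothermia alarm is a false positive
  expect_equal(spec_without, 1)   # ablating the rule removes it
  # monotonicity: the ablated run never detects more SIRS time
  expect_lte(nrow(abl$without_tables$episodes), nrow(abl$with_tables$episodes))
})

test_that("a cohort without hypothermic values is unaffected by the ablation", {
  gen <- small_gen(seed = 16, n = 8)  # clean generator drives criteria high only
  abl <- sensitivity_analysis_exclude_hypothermia(gen$cohort)
  expect_equal(abl$with$stay_level$table[c("tp", "fp", "fn", "tn")],
               abl$without$stay_level$table[c("tp", "fp", "fn", "tn")])
  expect_equal(abl$with$day_level$table[c("tp", "fp", "fn", "tn")],
               abl$without$day_level$table[c("tp", "fp", "fn", "tn")])
})

test_that("missingness bounds follow the forced arithmetic", {
  out <- missingness_bounds(list(tp = 3, fp = 0, fn = 1, tn = 0),
                            missing_pos_days = 2, missing_neg_days = 0)
  expect_equal(out$best_case$sensitivity$estimate, 5 / 6)
  expect_equal(out$worst_case$sensitivity$estimate, 3 / 6)
  expect_equal(out$complete_case$sensitivity$estimate, 3 / 4)
  # zero missing days: all three scenarios coincide
  same <- missingness_bounds(list(tp = 5, fp = 2, fn = 1, tn = 9), 0, 0)
  expect_equal(same$best_case$table, same$complete_case$table)
  expect_equal(same$worst_case$table, same$complete_case$table)
})

test_that("missingness bounds bracket the complete-case estimates", {
  set.seed(701)
  for (i in 1:1000) {
    tb <- list(tp = sample(1:50, 1), fp = sample(1:50, 1),
               fn = sample(1:50, 1), tn = sample(1:50, 1))
    out <- missingness_bounds(tb, sample(0:30, 1), sample(0:30, 1))
    for (m in c("sensitivity", "specificity")) {
      expect_gte(out$best_case[[m]]$estimate, out$complete_case[[m]]$estimate)
      expect_lte(out$worst_case[[m]]$estimate, out$complete_case[[m]]$estimate)
    }
  }
})

test_that("missingness bounds re-estimate by GEE when unit data are supplied", {
  set.seed(702)
  units <- data.frame(cluster = rep(1:40, each = 5),
                      reference = runif(200) < 0.4)
  units$rated <- ifelse(runif(200) < 0.75, units$reference, !units$reference)
  units$rated[sample(200, 50)] <- NA
  out <- missingness_bounds(list(tp = 0, fp = 0, fn = 0, tn = 0), 0, 0, units = units)
  expect_s3_class(out$complete_case$sensitivity_gee, "accuracy_estimate")
  expect_gte(out$best_case$sensitivity_gee$estimate,
             out$complete_case$sensitivity_gee$estimate - 1e-9)
  expect_lte(out$worst_case$specificity_gee$estimate,
             out$complete_case$specificity_gee$estimate + 1e-9)
})

test_that("the evaluation pipeline recovers a simulated rater's accuracy", {
  gen <- generate_cohort(cohort_scenario(seed = 21, n_patients = 40,
                                         episodes_per_stay = 1.4))
  truth <- gen$day_labels
  rs <- rater_spec(sensitivity = 0.62, specificity = 0.83, missing_rate = 0,
                   seed = 77)
  forms <- simulate_rater(truth, rs)
  rated <- merge(truth, forms[, c("stay_id", "date", "rating")],
                 by = c("stay_id", "date"))
  det_days <- data.frame(stay_id = rated$stay_id, date = rated$date,
                         sirs_positive = rated$rating == "positive")
  ref_days <- rated[, c("stay_id", "date", "sirs_positive")]
  tab <- day_contingency(ref_days, det_days)
  n_pos <- tab$tp + tab$fn; n_neg <- tab$tn + tab$fp
  expect_lt(abs(tab$tp / n_pos - 0.62), 3 * sqrt(0.62 * 0.38 / n_pos))
  expect_lt(abs(tab$tn / n_neg - 0.83), 3 * sqrt(0.83 * 0.17 / n_neg))
})
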