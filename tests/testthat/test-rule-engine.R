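th <- load_thresholds()

# an infant (age ~6 months at admission) with a 2-day stay
infant_birth <- ts0("2018-04-01 00:00:00")
infant_stay <- stay_row("S1", "2018-10-01 00:00:00", "2018-10-03 00:00:00")
T0 <- num("2018-10-01 00:00:00")

test_that("sample-and-hold extends values until superseded or expired", {
  s <- data.frame(timestamp = T0, value = 37)
  h <- sample_and_hold(s, 4)
  expect_equal(h$start, T0)
  expect_equal(h$end, T0 + 4 * 3600)

  s2 <- data.frame(timestamp = c(T0, T0 + 3600), value = c(37, 38))
  h2 <- sample_and_hold(s2, 4)
  expect_equal(h2$end[1] - h2$start[1], 3600)  # first value holds exactly 1 h
  expect_equal(h2$end[2], T0 + 3600 + 4 * 3600)

  expect_error(sample_and_hold(data.frame(timestamp = c(T0 + 10, T0), value = 1:2), 4),
               class = "picusirs_parameter_error")
})

test_that("threshold table validates structure and flags coverage gaps", {
  expect_s3_class(th, "threshold_table")
  expect_setequal(th$mandatory_criteria, c("temperature", "leukocytes"))
  bd <- unique(th$bands[, c("min_days", "max_days")])
  expect_equal(sort(bd$min_days), c(0, 7, 30, 365, 2190, 4745))

  # an adult patient falls outside the pediatric bands -> config error
  old_birth <- ts0("1990-01-01 00:00:00")
  obs <- make_obs("X", "2018-10-01 06:00:00", "temperature", 39.5)
  expect_error(
    evaluate_criterion(obs, "temperature", th, old_birth, infant_stay),
    class = "picusirs_config_error")
})

test_that("values inside the normal band never fire", {
  obs <- rbind(
    make_obs("X", c("2018-10-01 01:00:00", "2018-10-01 08:00:00"),
             "temperature", c(37.0, 37.8)),
    make_obs("X", "2018-10-01 02:00:00", "heart_rate", 120),
    make_obs("X", "2018-10-01 02:00:00", "respiratory_rate", 25),
    make_obs("X", "2018-10-01 03:00:00", "leukocyte_count", 9))
  for (cr in c("temperature", "heart_rate", "respiratory_rate", "leukocytes")) {
    st <- evaluate_criterion(obs, cr, th, infant_birth, infant_stay)
    expect_equal(nrow(st$intervals), 0, info = cr)
  }
})

test_that("limits are exclusive: a value exactly at the limit does not fire", {
  obs <- make_obs("X", "2018-10-01 01:00:00", "temperature", 38.5)
  st <- evaluate_criterion(obs, "temperature", th, infant_birth, infant_stay)
  expect_equal(nrow(st$intervals), 0)
  obs2 <- make_obs("X", "2018-10-01 01:00:00", "temperature", 38.51)
  st2 <- evaluate_criterion(obs2, "temperature", th, infant_birth, infant_stay)
  expect_equal(nrow(st2$intervals), 1)
})

test_that("hypothermia is suppressed during active cooling and resumes after", {
  obs <- make_obs("X", "2018-10-01 01:00:00", "temperature", 34.5)  # held 4 h
  cooling <- data.frame(patient_id = "X", kind = "active_cooling", acute = NA,
                        start = ts0("2018-10-01 00:30:00"),
                        end = ts0("2018-10-01 03:00:00"))
  st <- evaluate_criterion(obs, "temperature", th, infant_birth, infant_stay,
                           context = cooling)
  expect_equal(st$intervals$start, num("2018-10-01 03:00:00"))
  expect_equal(st$intervals$end, num("2018-10-01 05:00:00"))
  expect_equal(st$intervals$direction, "low")

  # with the hypothermia rule disabled the criterion is silent entirely
  st2 <- evaluate_criterion(obs, "temperature", th, infant_birth, infant_stay,
                            context = cooling,
                            config = detect_config(hypothermia = FALSE))
  expect_equal(nrow(st2$intervals), 0)
})

test_that("the heart-rate criterion is silent during pacemaker intervals", {
  obs <- make_obs("X", "2018-10-01 01:00:00", "heart_rate", 195)
  pm <- data.frame(patient_id = "X", kind = "pacemaker", acute = NA,
                   start = ts0("2018-10-01 00:00:00"),
                   end = ts0("2018-10-01 02:00:00"))
  st <- evaluate_criterion(obs, "heart_rate", th, infant_birth, infant_stay,
                           context = pm)
  expect_equal(st$intervals$start, num("2018-10-01 02:00:00"))
})

test_that("bradycardia applies only in the infant bands", {
  # age ~6 months: low heart rate fires
  obs <- make_obs("X", "2018-10-01 01:00:00", "heart_rate", 70)
  st <- evaluate_criterion(obs, "heart_rate", th, infant_birth, infant_stay)
  expect_equal(st$intervals$direction, "low")
  # a preschool child with the same rate: bradycardia not applicable
  birth3y <- ts0("2015-06-01 00:00:00")
  st2 <- evaluate_criterion(obs, "heart_rate", th, birth3y, infant_stay)
  expect_equal(nrow(st2$intervals), 0)
})

test_that("ventilation handles measured rates and the acute clause correctly", {
  vent_acute <- data.frame(patient_id = "X", kind = "mechanical_ventilation",
                           acute = TRUE, start = ts0("2018-10-01 06:00:00"),
                           end = ts0("2018-10-01 12:00:00"))
  # normal measured rate during acute ventilation: fires via the clause
  obs <- make_obs("X", "2018-10-01 06:00:00", "respiratory_rate", 20)
  st <- evaluate_criterion(obs, "respiratory_rate", th, infant_birth,
                           infant_stay, context = vent_acute)
  expect_equal(st$intervals$start, num("2018-10-01 06:00:00"))
  expect_equal(st$intervals$end, num("2018-10-01 12:00:00"))
  expect_equal(st$intervals$direction, "context")

  # high measured rate during non-acute ventilation: NOT compared, silent
  vent <- vent_acute; vent$acute <- FALSE
  obs2 <- make_obs("X", "2018-10-01 06:00:00", "respiratory_rate", 80)
  st2 <- evaluate_criterion(obs2, "respiratory_rate", th, infant_birth,
                            infant_stay, context = vent)
  expect_equal(nrow(st2$intervals), 0)
  # the same high rate outside ventilation fires
  st3 <- evaluate_criterion(obs2, "respiratory_rate", th, infant_birth, infant_stay)
  expect_equal(nrow(st3$intervals), 1)
})

test_that("the leukocyte criterion fires on count limits or left shift", {
  # normal count, elevated immature fraction -> left shift fires
  obs <- rbind(
    make_obs("X", "2018-10-01 01:00:00", "leukocyte_count", 9),
    make_obs("X", "2018-10-01 01:00:00", "immature_neutrophil_fraction", 0.15))
  st <- leukocyte_criterion(obs, th, infant_birth, infant_stay)
  expect_equal(nrow(st$intervals), 1)
  expect_equal(st$intervals$direction, "high")

  # fraction exactly at the limit does not fire (exclusive limits)
  obs2 <- make_obs("X", "2018-10-01 01:00:00", "immature_neutrophil_fraction", 0.10)
  expect_equal(nrow(leukocyte_criterion(obs2, th, infant_birth, infant_stay)$intervals), 0)

  # low count fires in bands with a lower limit
  obs3 <- make_obs("X", "2018-10-01 01:00:00", "leukocyte_count", 3)
  expect_equal(leukocyte_criterion(obs3, th, infant_birth, infant_stay)$intervals$direction, "low")
})

test_that("unvalidated observations are used by default and dropped in strict mode", {
  obs <- make_obs("X", "2018-10-01 01:00:00", "temperature", 39.5, validated = FALSE)
  st <- evaluate_criterion(obs, "temperature", th, infant_birth, infant_stay)
  expect_equal(nrow(st$intervals), 1)
  st2 <- evaluate_criterion(obs, "temperature", th, infant_birth, infant_stay,
                            config = detect_config(validated_only = TRUE))
  expect_equal(nrow(st2$intervals), 0)
})

test_that("combining requires two criteria including a mandatory one", {
  win <- c(T0, T0 + 7200)
  mk <- function(crits) {
    states <- lapply(setNames(nm = c("temperature", "leukocytes", "heart_rate",
                                     "respiratory_rate")),
                     function(cr) if (cr %in% crits) cstate(cr, win[1], win[2])
                     else cstate(cr))
    combine_criteria(states)
  }
  # heart rate + respiratory rate alone never constitute SIRS
  expect_equal(nrow(mk(c("heart_rate", "respiratory_rate"))), 0)
  # a single mandatory criterion is not enough
  expect_equal(nrow(mk("temperature")), 0)
  # temperature + heart rate qualifies
  s <- mk(c("temperature", "heart_rate"))
  expect_equal(c(s$start, s$end), win)
  expect_equal(s$criteria, "temperature,heart_rate")
})

test_that("combine agrees with brute-force enumeration of all 16 subsets", {
  crits <- c("temperature", "leukocytes", "heart_rate", "respiratory_rate")
  win <- c(T0, T0 + 3600)
  positive <- 0
  for (mask in 0:15) {
    on <- crits[bitwAnd(mask, c(1, 2, 4, 8)) > 0]
    states <- lapply(setNames(nm = crits), function(cr)
      if (cr %in% on) cstate(cr, win[1], win[2]) else cstate(cr))
    got <- nrow(combine_criteria(states)) > 0
    want <- length(on) >= 2 && any(c("temperature", "leukocytes") %in% on)
    expect_identical(got, want, info = paste(on, collapse = "+"))
    positive <- positive + got
  }
  expect_equal(positive, 10)  # all subsets of size >= 2 containing a mandatory
})

test_that("combine handles overlapping partial criteria with provenance", {
  states <- list(
    temperature = cstate("temperature", T0, T0 + 3 * 3600),
    leukocytes = cstate("leukocytes"),
    heart_rate = cstate("heart_rate", T0 + 3600, T0 + 5 * 3600),
    respiratory_rate = cstate("respiratory_rate", T0 + 2 * 3600, T0 + 6 * 3600))
  s <- combine_criteria(states)
  # SIRS only where temperature overlaps another criterion: [1 h, 3 h)
  expect_equal(s$start, T0 + 3600)
  expect_equal(s$end, T0 + 3 * 3600)
  expect_match(s$criteria, "temperature")
  expect_match(s$criteria, "heart_rate")
})

test_that("criterion states equal minute-grid pointwise evaluation on random stays", {
  set.seed(202)
  for (i in 1:40) {
    case <- rand_criterion_case(i)
    grid <- seq(as.numeric(case$stay$admit) + 30,
                as.numeric(case$stay$discharge) - 30, by = 60)
    for (cr in c("temperature", "heart_rate", "respiratory_rate", "leukocytes")) {
      st <- evaluate_criterion(case$obs, cr, th, case$birth, case$stay, case$ctx)
      got <- in_any(grid, st$intervals$start, st$intervals$end)
      want <- oracle_criterion(grid, case$obs, cr, th, case$birth, case$stay, case$ctx)
      expect_identical(got, want, info = paste("case", i, cr))
    }
  }
})

test_that("removing the hypothermia rule never adds SIRS time", {
  set.seed(303)
  for (i in 1:60) {
    case <- rand_criterion_case(i)
    run <- function(hypo) {
      cfg <- detect_config(hypothermia = hypo)
      states <- list(
        temperature = evaluate_criterion(case$obs, "temperature", th, case$birth,
                                         case$stay, case$ctx, cfg),
        leukocytes = leukocyte_criterion(case$obs, th, case$birth, case$stay,
                                         case$ctx, cfg),
        heart_rate = evaluate_criterion(case$obs, "heart_rate", th, case$birth,
                                        case$stay, case$ctx, cfg),
        respiratory_rate = evaluate_criterion(case$obs, "respiratory_rate", th,
                                              case$birth, case$stay, case$ctx, cfg))
      combine_criteria(states)
    }
    full <- run(TRUE); ablated <- run(FALSE)
    grid <- seq(as.numeric(case$stay$admit) + 30,
                as.numeric(case$stay$discharge) - 30, by = 60)
    on_full <- in_any(grid, full$start, full$end)
    on_abl <- in_any(grid, ablated$start, ablated$end)
    expect_true(all(on_full | !on_abl), info = paste("case", i))
  }
})
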