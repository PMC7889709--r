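# Shared fixture builders. All times on the uniform study clock (UTC).

ts0 <- function(x) as.POSIXct(x, tz = "UTC")
num <- function(x) as.numeric(ts0(x))

make_obs <- function(patient_id, times, variable, values, validated = TRUE) {
  data.frame(patient_id = patient_id,
             timestamp = if (inherits(times, "POSIXct")) times else ts0(times),
             variable = variable, value = values,
             validated = validated, stringsAsFactors = FALSE)
}

# A hand-built three-patient cohort exercising every table, including an
# open-ended reference episode and a routine form set.
tiny_cohort <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C"),
    birth_datetime = ts0(c("2018-06-01 04:00:00",  # infant at admission
                           "2014-03-10 00:00:00",  # preschool child
                           "2004-01-15 12:00:00")),# adolescent
    sex = c("female", "male", "unknown"), stringsAsFactors = FALSE)
  stays <- data.frame(
    stay_id = c("A1", "B1", "C1"),
    patient_id = c("A", "B", "C"),
    admit = ts0(c("2018-10-01 10:00:00", "2018-10-05 23:00:00", "2018-11-01 00:00:00")),
    discharge = ts0(c("2018-10-05 08:00:00", "2018-10-09 01:00:00", "2018-11-03 12:30:00")),
    stringsAsFactors = FALSE)
  observations <- rbind(
    make_obs("A", c("2018-10-01 10:00:00", "2018-10-01 12:00:00"),
             "temperature", c(37.0, 39.2)),
    make_obs("A", "2018-10-01 11:00:00", "heart_rate", 150),
    make_obs("B", "2018-10-06 06:00:00", "leukocyte_count", 12.0, validated = FALSE),
    make_obs("C", "2018-11-01 08:00:00", "respiratory_rate", 16))
  context <- data.frame(
    patient_id = "A", kind = "mechanical_ventilation", acute = TRUE,
    start = ts0("2018-10-02 00:00:00"), end = ts0("2018-10-02 12:00:00"),
    stringsAsFactors = FALSE)
  reference_episodes <- data.frame(
    patient_id = c("A", "C"), stay_id = c("A1", "C1"),
    start = ts0(c("2018-10-01 12:00:00", "2018-11-02 06:00:00")),
    end = ts0(c("2018-10-02 20:00:00", NA)),  # C's episode ongoing at discharge
    stringsAsFactors = FALSE)
  routine_assessments <- data.frame(
    stay_id = c("A1", "A1", "B1"),
    date = as.Date(c("2018-10-01", "2018-10-01", "2018-10-06")),
    shift = c("early", "late", "unspecified"),
    rating = c("negative", "positive", "negative"), stringsAsFactors = FALSE)
  sirs_cohort(patients, stays, observations, context,
              reference_episodes, routine_assessments)
}

# stay helper for episode/day functions
stay_row <- function(stay_id, admit, discharge)
  list(stay_id = stay_id, admit = ts0(admit), discharge = ts0(discharge))

# random minute-aligned disjoint interval set within [lo, hi] (numeric secs)
rand_state <- function(lo, hi, n_max = 8) {
  n <- sample(0:n_max, 1)
  if (n == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  pts <- sort(sample(seq(lo, hi, by = 60), 2 * n))
  s <- pts[seq(1, 2 * n, 2)]; e <- pts[seq(2, 2 * n, 2)]
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

# a random patient/stay/observation/context bundle for dense-grid rule checks;
# the sampled ages make many stays cross the infant/preschool band boundary,
# exercising age-band splits mid-stay
rand_criterion_case <- function(i) {
  birth <- ts0("2018-10-01 00:00:00") - sample(80:420, 1) * 86400 - sample(0:23, 1) * 3600
  admit <- ts0("2018-10-01 00:00:00")
  disch <- admit + sample(c(1, 2), 1) * 86400
  stay <- list(stay_id = "R", admit = admit, discharge = disch)
  span <- as.numeric(disch) - as.numeric(admit)
  mkobs <- function(variable, n, lo, hi) {
    tt <- sort(sample(seq(as.numeric(admit) - 3600, as.numeric(disch), by = 300),
                      n))
    make_obs("X", as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
             variable, round(runif(n, lo, hi), 2))
  }
  obs <- rbind(mkobs("temperature", sample(3:10, 1), 34, 40.5),
               mkobs("heart_rate", sample(3:10, 1), 60, 210),
               mkobs("respiratory_rate", sample(3:10, 1), 8, 60),
               mkobs("leukocyte_count", sample(2:4, 1), 2, 40),
               mkobs("immature_neutrophil_fraction", sample(1:3, 1), 0, 0.2))
  ctx <- NULL
  for (kind in c("mechanical_ventilation", "pacemaker", "active_cooling")) {
    if (runif(1) < 0.5) {
      s <- as.numeric(admit) + runif(1, 0, span * 0.8)
      ctx <- rbind(ctx, data.frame(
        patient_id = "X", kind = kind,
        acute = if (kind == "mechanical_ventilation") runif(1) < 0.5 else NA,
        start = as.POSIXct(s, origin = "1970-01-01", tz = "UTC"),
        end = as.POSIXct(s + runif(1, 3600, span / 2), origin = "1970-01-01", tz = "UTC")))
    }
  }
  list(birth = birth, stay = stay, obs = obs, ctx = ctx)
}

cstate <- function(criterion, start = numeric(0), end = numeric(0),
                   direction = rep("high", length(start))) {
  structure(list(criterion = criterion,
                 intervals = data.frame(start = as.numeric(start),
                                        end = as.numeric(end),
                                        direction = direction,
                                        stringsAsFactors = FALSE)),
            class = "criterion_state")
}
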