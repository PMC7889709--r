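# Seeded synthetic cohorts with known ground truth. The generator emulates a
# PICU PDMS export: per-patient vital-sign and laboratory streams sampled at
# realistic cadences, SIRS episodes injected by pushing the driving variables
# beyond the active age-band thresholds (always honouring the
# mandatory-criterion rule), context intervals, imperfect per-shift raters
# and day-level missingness. Identical scenario + seed => identical cohort.

substream_seed <- function(seed, label) {
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u))
  # double arithmetic stays exact well past 2^31 * 48271 (< 2^53)
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 1103) %% 2147483629)
}

with_substream <- function(seed, label, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(substream_seed(seed, label))
  code
}

round_minute <- function(x) round(x / 60) * 60

#' Scenario for the synthetic-cohort generator
#'
#' Defaults reproduce the evaluated study's cohort structure: 168 patients
#' distributed over the six baseline age bands, mean stay length 12 days with
#' a quarter of patients re-admitted, roughly 0.9 episodes per stay with
#' criterion involvement proportional to the observed alert mix, hourly
#' vitals and daily laboratory sampling.
#'
#' @param seed mandatory integer seed; every random draw derives from it via
#'   fixed-label substreams, so adding one draw never perturbs another's.
#' @param n_patients number of patients.
#' @param age_band_probs probabilities over the six age bands (newborn to
#'   adolescent); normalized internally.
#' @param stay_mean_days mean length of stay in days.
#' @param multi_stay_prob probability a patient has a second stay.
#' @param episodes_per_stay Poisson mean of injected episodes per stay.
#' @param episode_duration_mean_hours mean injected episode duration.
#' @param episode_min_hours minimum injected episode duration.
#' @param episode_gap_hours minimum non-SIRS separation between injected
#'   episodes (> 24 h so the closing rule keeps them distinct).
#' @param criteria_weights relative involvement of the four criteria in
#'   episodes (mandatory pick uses the temperature/leukocyte weights; at
#'   least one mandatory driver is always present).
#' @param vital_cadence_minutes,lab_cadence_hours observation cadences.
#' @param noise_sd per-variable Gaussian jitter around band-appropriate
#'   baselines.
#' @param context_rates per-stay probabilities of ventilation, pacemaker and
#'   cooling intervals (placed clear of injected episodes so context rules
#'   cannot mask injected ground truth).
#' @param acute_ventilation_prob probability a respiratory-driven episode is
#'   realized through the acute-ventilation clause instead of a high
#'   measured rate.
#' @param borderline_rate in noisy mode, per-sample probability that a
#'   non-episode value crosses its limit (borderline false alarms).
#' @param mode `"clean"` (values outside episodes stay strictly within
#'   limits) or `"noisy"`.
#' @return a validated `cohort_scenario` list.
#' @export
cohort_scenario <- function(seed,
                            n_patients = 168,
                            age_band_probs = c(newborn = 0.11, neonate = 0.06,
                                               infant = 0.36, toddler_preschool = 0.26,
                                               school_age = 0.15, adolescent = 0.07),
                            stay_mean_days = 12,
                            multi_stay_prob = 0.25,
                            episodes_per_stay = 0.9,
                            episode_duration_mean_hours = 48,
                            episode_min_hours = 3,
                            episode_gap_hours = 30,
                            criteria_weights = c(temperature = 58, leukocytes = 117,
                                                 heart_rate = 39, respiratory_rate = 123),
                            vital_cadence_minutes = 60,
                            lab_cadence_hours = 24,
                            noise_sd = c(temperature = 0.25, heart_rate = 6,
                                         respiratory_rate = 2.5, leukocyte_count = 1.2,
                                         immature_neutrophil_fraction = 0.015),
                            context_rates = c(mechanical_ventilation = 0.3,
                                              pacemaker = 0.05, active_cooling = 0.05),
                            acute_ventilation_prob = 0.3,
                            borderline_rate = 0.02,
                            mode = c("clean", "noisy")) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    abort_parameter("cohort_scenario: a seed is mandatory")
  mode <- match.arg(mode)
  if (n_patients < 1) abort_parameter("n_patients must be at least 1")
  if (any(age_band_probs < 0) || sum(age_band_probs) <= 0)
    abort_parameter("age_band_probs must be non-negative and sum positive")
  for (v in c(multi_stay_prob, acute_ventilation_prob, borderline_rate))
    if (v < 0 || v > 1) abort_parameter("probabilities must lie in [0, 1]")
  if (any(context_rates < 0) || any(context_rates > 1))
    abort_parameter("context_rates must lie in [0, 1]")
  if (episodes_per_stay > 0 &&
      criteria_weights[["temperature"]] <= 0 && criteria_weights[["leukocytes"]] <= 0)
    abort_parameter(paste("scenario error: episodes driven only by heart/respiratory",
                          "rate cannot satisfy the mandatory-criterion rule"))
  if (episode_gap_hours <= 24)
    abort_parameter("episode_gap_hours must exceed the 24-h closing rule")
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 age_band_probs = age_band_probs / sum(age_band_probs),
                 stay_mean_days = stay_mean_days, multi_stay_prob = multi_stay_prob,
                 episodes_per_stay = episodes_per_stay,
                 episode_duration_mean_hours = episode_duration_mean_hours,
                 episode_min_hours = episode_min_hours,
                 episode_gap_hours = episode_gap_hours,
                 criteria_weights = criteria_weights,
                 vital_cadence_minutes = vital_cadence_minutes,
                 lab_cadence_hours = lab_cadence_hours,
                 noise_sd = noise_sd, context_rates = context_rates,
                 acute_ventilation_prob = acute_ventilation_prob,
                 borderline_rate = borderline_rate, mode = mode),
            class = "cohort_scenario")
}

VAR_OF_CRIT <- c(temperature = "temperature", heart_rate = "heart_rate",
                 respiratory_rate = "respiratory_rate", leukocytes = "leukocyte_count")
ABNORMAL_OFFSET <- c(temperature = 0.7, heart_rate = 15, respiratory_rate = 8,
                     leukocyte_count = 4, immature_neutrophil_fraction = 0.05)

# band row index for each absolute time, given birth (numeric seconds)
band_at <- function(bw, t) {
  idx <- findInterval(t, c(bw$start, bw$end[nrow(bw)]))
  idx[idx < 1 | idx > nrow(bw)] <- NA
  idx
}

normal_value <- function(variable, lower, upper, sd) {
  # band-appropriate baseline: midpoint of the limits, or 60% of the upper
  # limit when no lower limit exists
  base <- ifelse(is.na(lower), 0.6 * upper, (lower + upper) / 2)
  v <- base + rnorm(length(base), 0, sd)
  m <- 0.75 * sd
  lo <- ifelse(is.na(lower), -Inf, lower + m)
  pmin(pmax(v, lo), upper - m)
}

#' Generate a synthetic cohort with ground truth
#'
#' Injects SIRS episodes by holding the driving variables beyond the active
#' thresholds over the episode window (with exact boundary samples, so the
#' sample-and-hold semantics are exercised and, in clean mode, the detected
#' state reproduces the injected windows exactly). Outside episodes, values
#' stay strictly within normal bands up to noise (clean mode) or cross the
#' limits at the borderline rate (noisy mode).
#'
#' @param scenario a [cohort_scenario()].
#' @param thresholds threshold table the injections are calibrated against
#'   (defaults to the packaged IPSCC limits, keeping generator and rule
#'   engine consistent if the limits change).
#' @return list with `cohort` (a validated `sirs_cohort`, reference episodes
#'   included), `reference_episodes`, `day_labels` (ground-truth day labels
#'   with `patient_id`), and the `scenario`.
#' @export
generate_cohort <- function(scenario, thresholds = load_thresholds()) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  sc <- scenario
  origin <- as.numeric(as.POSIXct("2018-08-01 00:00:00", tz = "UTC"))
  band_names <- names(sc$age_band_probs)
  bd <- unique(thresholds$bands[, c("band", "min_days", "max_days")])
  rownames(bd) <- bd$band

  patients <- list(); stays <- list(); obs <- list(); ctx <- list()
  refs <- list(); truth_days <- list()

  for (p in seq_len(sc$n_patients)) {
    pid <- sprintf("P%04d", p)
    pdat <- with_substream(sc$seed, paste0("patient_", p), {
      band <- sample(band_names, 1, prob = sc$age_band_probs)
      lo_d <- bd[band, "min_days"]; hi_d <- bd[band, "max_days"]
      age_days <- runif(1, lo_d + 0.5, hi_d - 0.5)
      admit1 <- round_minute(origin + runif(1, 0, 180) * 86400)
      n_stays <- 1L + rbinom(1, 1, sc$multi_stay_prob)
      los <- pmin(pmax(rgamma(n_stays, shape = 1.4,
                              scale = sc$stay_mean_days / 1.4), 0.75), 40)
      gap_days <- runif(1, 5, 30)
      sex <- sample(c("female", "male"), 1, prob = c(0.38, 0.62))
      list(age_days = age_days, admit1 = admit1, n_stays = n_stays,
           los = los, gap_days = gap_days, sex = sex)
    })
    # keep the whole observation window inside the threshold age coverage
    max_span_days <- sum(pdat$los) + pdat$gap_days + 2
    age_days <- min(pdat$age_days, 6570 - max_span_days - 1)
    birth <- round_minute(pdat$admit1 - age_days * 86400)
    patients[[p]] <- data.frame(patient_id = pid, birth_datetime = birth,
                                sex = pdat$sex, stringsAsFactors = FALSE)
    bw <- band_windows(thresholds, birth)

    admit <- pdat$admit1
    for (s in seq_len(pdat$n_stays)) {
      sid <- sprintf("S%04d_%d", p, s)
      discharge <- round_minute(admit + pdat$los[s] * 86400)
      stays[[length(stays) + 1]] <- data.frame(
        stay_id = sid, patient_id = pid, admit = admit, discharge = discharge,
        stringsAsFactors = FALSE)

      eps <- with_substream(sc$seed, paste0("episodes_", pid, "_", s), {
        k <- rpois(1, sc$episodes_per_stay)
        placed <- iv_empty(); rows <- list()
        for (e in seq_len(k)) {
          for (try in 1:20) {
            dur <- min(max(rexp(1, 1 / (sc$episode_duration_mean_hours * 3600)),
                           sc$episode_min_hours * 3600),
                       0.6 * (discharge - admit))
            if (admit + dur + 7200 > discharge - 3600) next
            st <- round_minute(runif(1, admit + 3600, discharge - dur - 3600))
            en <- round_minute(st + dur)
            prox <- iv_merge(iv(placed$start - sc$episode_gap_hours * 3600,
                                placed$end + sc$episode_gap_hours * 3600))
            if (nrow(iv_intersect(iv(st, en), prox))) next
            placed <- iv_union(placed, iv(st, en))
            mand <- sample(c("temperature", "leukocytes"), 1,
                           prob = sc$criteria_weights[c("temperature", "leukocytes")] +
                             1e-12)
            drivers <- mand
            tot <- sum(sc$criteria_weights)
            if (runif(1) < sc$criteria_weights[["heart_rate"]] / tot * 2)
              drivers <- c(drivers, "heart_rate")
            if (runif(1) < sc$criteria_weights[["respiratory_rate"]] / tot * 2)
              drivers <- c(drivers, "respiratory_rate")
            if (runif(1) < 0.15)
              drivers <- union(drivers, setdiff(c("temperature", "leukocytes"), mand))
            if (length(drivers) < 2)
              drivers <- c(drivers, if (sc$criteria_weights[["respiratory_rate"]] >=
                                        sc$criteria_weights[["heart_rate"]])
                "respiratory_rate" else "heart_rate")
            leuk_mode <- if ("leukocytes" %in% drivers &&
                             runif(1) < 0.35) "left_shift" else "count"
            rr_mode <- if ("respiratory_rate" %in% drivers &&
                           runif(1) < sc$acute_ventilation_prob) "vent" else "measured"
            rows[[length(rows) + 1]] <- list(start = st, end = en,
                                             drivers = drivers,
                                             leuk_mode = leuk_mode,
                                             rr_mode = rr_mode)
            break
          }
        }
        rows
      })
      ep_iv <- if (length(eps)) iv(vapply(eps, `[[`, 0, "start"),
                                   vapply(eps, `[[`, 0, "end")) else iv_empty()
      for (e in eps) {
        refs[[length(refs) + 1]] <- data.frame(
          patient_id = pid, stay_id = sid, start = e$start, end = e$end,
          stringsAsFactors = FALSE)
        if (e$rr_mode == "vent")
          ctx[[length(ctx) + 1]] <- data.frame(
            patient_id = pid, kind = "mechanical_ventilation", acute = TRUE,
            start = e$start, end = e$end, stringsAsFactors = FALSE)
      }

      # measurement streams
      obs[[length(obs) + 1]] <- with_substream(sc$seed, paste0("obs_", pid, "_", s), {
        out <- list()
        for (variable in OBS_VARIABLES) {
          cadence <- if (variable %in% c("leukocyte_count", "immature_neutrophil_fraction"))
            sc$lab_cadence_hours * 3600 else sc$vital_cadence_minutes * 60
          times <- seq(admit, discharge - 1, by = cadence)
          crit <- names(VAR_OF_CRIT)[VAR_OF_CRIT == variable]
          driving <- Filter(function(e) {
            if (variable == "immature_neutrophil_fraction")
              return("leukocytes" %in% e$drivers && e$leuk_mode == "left_shift")
            if (variable == "leukocyte_count")
              return("leukocytes" %in% e$drivers && e$leuk_mode == "count")
            if (variable == "respiratory_rate")
              return("respiratory_rate" %in% e$drivers && e$rr_mode == "measured")
            length(crit) && crit %in% e$drivers
          }, eps)
          if (length(driving))
            times <- sort(unique(c(times,
                                   vapply(driving, `[[`, 0, "start"),
                                   vapply(driving, `[[`, 0, "end"))))
          bidx <- band_at(bw, times)
          sd <- sc$noise_sd[[variable]]
          if (variable == "immature_neutrophil_fraction") {
            v <- pmin(pmax(0.02 + rnorm(length(times), 0, sd), 0),
                      thresholds$immature_neutrophil_limit - 0.02)
            lim_hi <- rep(thresholds$immature_neutrophil_limit, length(times))
          } else {
            cr <- if (variable == "leukocyte_count") "leukocytes" else variable
            lims <- t(vapply(bw$band[bidx], function(b) {
              l <- band_limits(thresholds, b, cr); c(l$lower, l$upper)
            }, numeric(2)))
            v <- normal_value(variable, lims[, 1], lims[, 2], sd)
            lim_hi <- lims[, 2]
          }
          if (sc$mode == "noisy" && sc$borderline_rate > 0) {
            flip <- runif(length(times)) < sc$borderline_rate
            v[flip] <- lim_hi[flip] + 0.1 * sd + abs(rnorm(sum(flip), 0, 0.3 * sd))
          }
          for (e in driving) {
            inside <- times >= e$start & times < e$end
            v[inside] <- lim_hi[inside] + ABNORMAL_OFFSET[[variable]] +
              abs(rnorm(sum(inside), 0, sd))
          }
          out[[variable]] <- data.frame(patient_id = pid, timestamp = times,
                                        variable = variable, value = v,
                                        validated = TRUE, stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
      })

      # non-interacting context intervals, placed clear of injected episodes
      ctx_new <- with_substream(sc$seed, paste0("context_", pid, "_", s), {
        rows <- list()
        for (kind in CONTEXT_KINDS) {
          if (runif(1) >= sc$context_rates[[kind]]) next
          margin <- 2 * 3600
          free <- iv_setdiff(iv(admit, discharge),
                             iv(ep_iv$start - margin, ep_iv$end + margin))
          free <- free[(free$end - free$start) >= 4 * 3600, , drop = FALSE]
          if (!nrow(free)) next
          g <- free[which.max(free$end - free$start), ]
          len <- runif(1, 0.25, 0.75) * (g$end - g$start)
          st <- round_minute(runif(1, g$start, g$end - len))
          rows[[length(rows) + 1]] <- data.frame(
            patient_id = pid, kind = kind,
            acute = if (kind == "mechanical_ventilation") FALSE else NA,
            start = st, end = round_minute(st + len), stringsAsFactors = FALSE)
        }
        rows
      })
      ctx <- c(ctx, ctx_new)

      admit <- round_minute(discharge + pdat$gap_days * 86400)
    }
  }

  to_ct <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")
  patients <- do.call(rbind, patients)
  patients$birth_datetime <- to_ct(patients$birth_datetime)
  stays_df <- do.call(rbind, stays)
  stays_df$admit <- to_ct(stays_df$admit); stays_df$discharge <- to_ct(stays_df$discharge)
  obs_df <- do.call(rbind, obs)
  obs_df$timestamp <- to_ct(obs_df$timestamp)
  rownames(obs_df) <- NULL
  ctx_df <- if (length(ctx)) do.call(rbind, ctx) else empty_table("context")
  if (nrow(ctx_df)) { ctx_df$start <- to_ct(ctx_df$start); ctx_df$end <- to_ct(ctx_df$end) }
  refs_df <- if (length(refs)) do.call(rbind, refs) else empty_table("reference_episodes")
  if (nrow(refs_df)) { refs_df$start <- to_ct(refs_df$start); refs_df$end <- to_ct(refs_df$end) }

  cohort <- sirs_cohort(patients = patients, stays = stays_df,
                        observations = obs_df, context = ctx_df,
                        reference_episodes = refs_df)

  labels <- list()
  for (i in seq_len(nrow(stays_df))) {
    st <- stays_df[i, ]
    re <- refs_df[refs_df$stay_id == st$stay_id, , drop = FALSE]
    lab <- reference_day_labels(re, st)
    lab$patient_id <- st$patient_id
    labels[[i]] <- lab
  }
  day_labels <- do.call(rbind, labels)

  list(cohort = cohort, reference_episodes = refs_df,
       day_labels = day_labels, scenario = sc)
}

#' Specification of a simulated bedside rater
#'
#' @param sensitivity per-day probability of rating a true SIRS day positive.
#' @param specificity per-day probability of rating a non-SIRS day negative.
#' @param missing_rate per-day probability that no form is filed.
#' @param icc intraclass correlation of rating accuracy between days of one
#'   stay (0 = independent days; positive values draw per-stay accuracy from
#'   a beta distribution with the stated marginal mean).
#' @param seed mandatory integer seed.
#' @return a `rater_spec` list.
#' @export
rater_spec <- function(sensitivity, specificity, missing_rate = 0, icc = 0, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    abort_parameter("rater_spec: a seed is mandatory")
  for (v in c(sensitivity, specificity, missing_rate, icc))
    if (!is.numeric(v) || v < 0 || v > 1)
      abort_parameter("rater_spec: probabilities must lie in [0, 1]")
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 missing_rate = missing_rate, icc = icc, seed = as.integer(seed)),
            class = "rater_spec")
}

rbeta_mean <- function(n, mean, icc) {
  if (icc <= 0 || mean <= 0 || mean >= 1) return(rep(mean, n))
  a <- mean * (1 - icc) / icc
  b <- (1 - mean) * (1 - icc) / icc
  rbeta(n, a, b)
}

#' Simulate per-shift routine assessment forms
#'
#' Independent per-day Bernoulli rating given the ground-truth day label;
#' days drawn as missing produce no form. Deterministic given the spec's
#' seed.
#'
#' @param truth ground-truth day labels (`stay_id`, `date`, `sirs_positive`).
#' @param spec a [rater_spec()].
#' @return routine assessment rows (`stay_id`, `date`, `shift`, `rating`)
#'   for the non-missing days.
#' @export
simulate_rater <- function(truth, spec) {
  stopifnot(inherits(spec, "rater_spec"))
  with_substream(spec$seed, "rater", {
    stay_ids <- unique(truth$stay_id)
    sens_i <- setNames(rbeta_mean(length(stay_ids), spec$sensitivity, spec$icc), stay_ids)
    spec_i <- setNames(rbeta_mean(length(stay_ids), spec$specificity, spec$icc), stay_ids)
    miss <- runif(nrow(truth)) < spec$missing_rate
    p_pos <- ifelse(truth$sirs_positive, sens_i[truth$stay_id],
                    1 - spec_i[truth$stay_id])
    pos <- runif(nrow(truth)) < p_pos
    keep <- which(!miss)
    data.frame(stay_id = truth$stay_id[keep], date = truth$date[keep],
               shift = rep("early", length(keep)),
               rating = ifelse(pos[keep], "positive", "negative"),
               stringsAsFactors = FALSE)
  })
}

#' Mask a fixed fraction of each day stratum as missing
#'
#' Marks a simple random sample of SIRS days and of non-SIRS days as missing,
#' with stratum counts equal to the fractions rounded to the nearest integer.
#'
#' @param day_labels day labels with `sirs_positive`.
#' @param fraction_pos,fraction_neg stratum missingness fractions in [0, 1].
#' @param seed integer seed.
#' @return `day_labels` with an added logical `missing` column.
#' @export
inject_missingness <- function(day_labels, fraction_pos, fraction_neg, seed) {
  if (fraction_pos < 0 || fraction_pos > 1 || fraction_neg < 0 || fraction_neg > 1)
    abort_parameter("missingness fractions must lie in [0, 1]")
  with_substream(seed, "missingness", {
    miss <- rep(FALSE, nrow(day_labels))
    for (stratum in c(TRUE, FALSE)) {
      idx <- which(day_labels$sirs_positive == stratum)
      frac <- if (stratum) fraction_pos else fraction_neg
      k <- round(frac * length(idx))
      if (k > 0) miss[sample(idx, k)] <- TRUE
    }
    day_labels$missing <- miss
    day_labels
  })
}
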