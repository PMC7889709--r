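# Independent brute-force oracles. These deliberately re-derive every rule
# pointwise (or by exhaustive search) without using the package's interval
# machinery, so agreement is a genuine cross-check.

in_any <- function(t, start, end) {
  if (!length(start)) return(rep(FALSE, length(t)))
  vapply(t, function(x) any(start <= x & x < end), logical(1))
}

# held value of a point series at each grid time (NA = unknown)
oracle_hold <- function(times, values, horizon_sec, grid) {
  out <- rep(NA_real_, length(grid))
  if (!length(times)) return(out)
  k <- findInterval(grid, times)
  has <- k >= 1
  nxt <- c(times[-1], Inf)
  live <- has & grid < pmin(nxt[pmax(k, 1)], times[pmax(k, 1)] + horizon_sec)
  out[live] <- values[k[live]]
  out
}

# pointwise criterion evaluation at grid times; obs is the patient's
# observation data.frame, context the patient's context rows (or NULL)
oracle_criterion <- function(grid, obs, criterion, th, birth, stay,
                             context = NULL, hypothermia = TRUE,
                             vital_h = 4, lab_h = 24) {
  bb <- th$bands[th$bands$criterion == criterion, ]
  bb <- bb[order(bb$min_days), ]
  age <- (grid - as.numeric(birth)) / 86400
  bi <- findInterval(age, bb$min_days)
  ok <- bi >= 1 & age < bb$max_days[pmax(bi, 1)]
  bi[!ok] <- NA
  upper <- bb$upper[bi]; lower <- bb$lower[bi]; brady <- bb$bradycardia[bi]

  held_of <- function(variable, horizon_h) {
    o <- obs[obs$variable == variable, ]
    o <- o[order(as.numeric(o$timestamp)), ]
    oracle_hold(as.numeric(o$timestamp), o$value, horizon_h * 3600, grid)
  }
  ctx_at <- function(kind, acute_only = FALSE) {
    if (is.null(context) || !nrow(context)) return(rep(FALSE, length(grid)))
    cx <- context[context$kind == kind, ]
    if (acute_only) cx <- cx[!is.na(cx$acute) & cx$acute, ]
    in_any(grid, as.numeric(cx$start), as.numeric(cx$end))
  }
  inside_stay <- grid >= as.numeric(stay$admit) & grid < as.numeric(stay$discharge)
  no_na <- function(x) !is.na(x) & x

  if (criterion == "temperature") {
    v <- held_of("temperature", vital_h)
    hi <- no_na(v > upper)
    lo <- hypothermia & no_na(v < lower) & !ctx_at("active_cooling")
    fires <- hi | lo
  } else if (criterion == "heart_rate") {
    v <- held_of("heart_rate", vital_h)
    hi <- no_na(v > upper)
    lo <- no_na(brady) & no_na(v < lower)
    fires <- (hi | lo) & !ctx_at("pacemaker")
  } else if (criterion == "respiratory_rate") {
    v <- held_of("respiratory_rate", vital_h)
    measured <- no_na(v > upper) & !ctx_at("mechanical_ventilation")
    fires <- measured | ctx_at("mechanical_ventilation", acute_only = TRUE)
  } else if (criterion == "leukocytes") {
    v <- held_of("leukocyte_count", lab_h)
    f <- held_of("immature_neutrophil_fraction", lab_h)
    cnt <- no_na(v > upper) | no_na(v < lower)
    fires <- cnt | no_na(f > th$immature_neutrophil_limit)
  }
  fires & inside_stay & !is.na(bi)
}

# episode building by linear scan over sorted disjoint intervals
oracle_episodes <- function(state, closing_gap_h = 24, min_min = 60) {
  x <- state[order(state$start), , drop = FALSE]
  if (!nrow(x)) return(x)
  es <- x$start[1]; ee <- x$end[1]; out <- NULL
  if (nrow(x) > 1) for (i in 2:nrow(x)) {
    if (x$start[i] - ee < closing_gap_h * 3600) ee <- max(ee, x$end[i])
    else { out <- rbind(out, data.frame(start = es, end = ee)); es <- x$start[i]; ee <- x$end[i] }
  }
  out <- rbind(out, data.frame(start = es, end = ee))
  out[out$end - out$start >= min_min * 60, , drop = FALSE]
}

# minute-grid day labelling for minute-aligned states and stays
oracle_day_labels <- function(state, admit, discharge, rule = "cumulative") {
  a <- as.numeric(admit); d <- as.numeric(discharge)
  mins <- seq(floor(a / 60) * 60, d - 60, by = 60)
  mins <- mins[mins >= a]
  covered <- in_any(mins, pmax(state$start, a), pmin(state$end, d))
  date <- as.Date(floor(mins / 86400), origin = "1970-01-01")
  all_dates <- as.Date(seq(floor(a / 86400), ceiling(d / 86400) - 1),
                       origin = "1970-01-01")
  minutes <- vapply(all_dates, function(dd) sum(covered[date == dd]), 0)
  positive <- if (rule == "cumulative") minutes >= 60 else
    vapply(all_dates, function(dd) {
      runs <- rle(covered[date == dd])
      any(runs$values & runs$lengths >= 60)
    }, logical(1))
  data.frame(date = all_dates, minutes = minutes, positive = positive)
}

# exhaustive maximum-cardinality matching under the tolerance window
oracle_max_matching <- function(rs, ds, tol_sec) {
  best <- 0
  recurse <- function(i, used) {
    if (i > length(rs)) { best <<- max(best, sum(used)); return() }
    recurse(i + 1, used)  # leave ref i unmatched
    for (j in which(!used)) {
      if (abs(ds[j] - rs[i]) <= tol_sec) {
        used[j] <- TRUE; recurse(i + 1, used); used[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, length(ds)))
  best
}

# direct matrix-algebra sandwich variance for the intercept-only exchangeable
# GEE at a given (p, alpha)
oracle_sandwich <- function(y, cluster, p, alpha) {
  B <- 0; M <- 0
  for (cl in unique(cluster)) {
    yi <- y[cluster == cl]; n <- length(yi)
    R <- matrix(alpha, n, n); diag(R) <- 1
    A <- diag(rep(p * (1 - p), n), n)
    V <- sqrt(A) %*% R %*% sqrt(A)
    D <- matrix(p * (1 - p), n, 1)
    Vi <- solve(V)
    B <- B + t(D) %*% Vi %*% D
    r <- matrix(yi - p, n, 1)
    M <- M + (t(D) %*% Vi %*% r) %*% (t(r) %*% Vi %*% D)
  }
  sqrt(as.numeric(M)) / as.numeric(B)
}

# estimating-equation value at mean p given alpha
oracle_ee <- function(y, cluster, p, alpha) {
  n_i <- tapply(y, cluster, length)
  S_i <- tapply(y, cluster, sum)
  sum((S_i - n_i * p) / (1 + (n_i - 1) * alpha))
}
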