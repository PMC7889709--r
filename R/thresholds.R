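CRITERIA <- c("temperature", "leukocytes", "heart_rate", "respiratory_rate")

#' Load an age-banded SIRS threshold table
#'
#' Reads a YAML threshold configuration (the packaged default transcribes the
#' IPSCC consensus limits) and validates it: age bands must partition
#' `[0, 18 years)` in days, every present limit must be finite, and the
#' mandatory criteria are fixed to temperature and leukocytes.
#'
#' @param path YAML file; default is the packaged `ipscc_thresholds.yaml`.
#' @return a `threshold_table`: list with `version`, `limits_exclusive`,
#'   `mandatory_criteria`, `immature_neutrophil_limit`, and `bands`, a
#'   data.frame with one row per (band, criterion) limit set.
#' @export
load_thresholds <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ipscc_thresholds.yaml", package = "picusirs")
  if (!file.exists(path)) abort_config(sprintf("threshold file not found: %s", path))
  raw <- yaml::yaml.load_file(path)

  for (f in c("version", "age_bands", "mandatory_criteria", "immature_neutrophil_limit"))
    if (is.null(raw[[f]])) abort_config(sprintf("threshold config: missing field '%s'", f))
  if (!setequal(raw$mandatory_criteria, c("temperature", "leukocytes")))
    abort_config("mandatory_criteria must be exactly {temperature, leukocytes}")
  lim <- raw$immature_neutrophil_limit
  if (!is.numeric(lim) || lim < 0 || lim > 1)
    abort_config("immature_neutrophil_limit must be a fraction in [0, 1]")

  rows <- list()
  for (b in raw$age_bands) {
    for (f in c("name", "min_days", "max_days"))
      if (is.null(b[[f]])) abort_config(sprintf("age band missing field '%s'", f))
    for (cr in CRITERIA) {
      spec <- b[[cr]]
      if (is.null(spec)) abort_config(sprintf("band '%s': missing criterion '%s'", b$name, cr))
      lo <- if (is.null(spec$lower)) NA_real_ else as.numeric(spec$lower)
      hi <- if (is.null(spec$upper)) NA_real_ else as.numeric(spec$upper)
      if ((is.na(lo) || is.finite(lo)) && (is.na(hi) || is.finite(hi))) NULL
      else abort_config(sprintf("band '%s', criterion '%s': limits must be finite", b$name, cr))
      if (is.na(lo) && is.na(hi))
        abort_config(sprintf("band '%s', criterion '%s': needs at least one limit", b$name, cr))
      rows[[length(rows) + 1]] <- data.frame(
        band = b$name, min_days = as.numeric(b$min_days),
        max_days = as.numeric(b$max_days), criterion = cr,
        lower = lo, upper = hi,
        bradycardia = isTRUE(spec$bradycardia),
        stringsAsFactors = FALSE)
    }
  }
  bands <- do.call(rbind, rows)

  bd <- unique(bands[, c("band", "min_days", "max_days")])
  bd <- bd[order(bd$min_days), ]
  if (bd$min_days[1] != 0 || abs(bd$max_days[nrow(bd)] - 6570) > 1e-9 ||
      any(abs(bd$min_days[-1] - bd$max_days[-nrow(bd)]) > 1e-9)) {
    gap_at <- if (nrow(bd) > 1) bd$max_days[which(abs(bd$min_days[-1] - bd$max_days[-nrow(bd)]) > 1e-9)[1]] else NA
    abort_config(sprintf(
      "age bands must partition [0, 6570) days; coverage breaks near day %s",
      format(if (is.na(gap_at)) bd$min_days[1] else gap_at)))
  }

  structure(list(
    version = as.character(raw$version),
    limits_exclusive = !isFALSE(raw$limits_exclusive),
    mandatory_criteria = c("temperature", "leukocytes"),
    immature_neutrophil_limit = lim,
    bands = bands
  ), class = "threshold_table")
}

# Band windows (absolute numeric time) for one patient: birth + band bounds.
band_windows <- function(thresholds, birth) {
  bd <- unique(thresholds$bands[, c("band", "min_days", "max_days")])
  bd <- bd[order(bd$min_days), ]
  data.frame(band = bd$band,
             start = as.numeric(birth) + bd$min_days * 86400,
             end = as.numeric(birth) + bd$max_days * 86400,
             stringsAsFactors = FALSE)
}

# Limits for one criterion in one named band.
band_limits <- function(thresholds, band, criterion) {
  r <- thresholds$bands[thresholds$bands$band == band &
                          thresholds$bands$criterion == criterion, ]
  list(lower = r$lower[1], upper = r$upper[1], bradycardia = r$bradycardia[1])
}

#' @export
print.threshold_table <- function(x, ...) {
  cat(sprintf("<threshold_table> version %s (%d age bands; limits %s)\n",
              x$version, length(unique(x$bands$band)),
              if (x$limits_exclusive) "exclusive" else "inclusive"))
  invisible(x)
}
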