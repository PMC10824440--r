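#' Default laboratory analyte panel
#'
#' Thirty analytes with pediatric reference ranges, a wider plausibility
#' range used to clip generated values, the direction in which values move as
#' latent severity rises (`direction = +1` rises, `-1` falls), a noise scale
#' expressed as a fraction of the reference span, and per-location sampling
#' rates (probability that the analyte is measured in a given hour). Routine
#' wards draw labs roughly daily, intensive care roughly every six hours,
#' which is what motivates 6-hour discretization downstream.
#'
#' @param n Number of analytes to keep (first `n` rows; 1-30). A reduced
#'   panel shrinks the feature space for small worked examples.
#' @return A `data.table` with one row per analyte.
#' @export
default_lab_panel <- function(n = 30L) {
  spec <- list(
    # name,            lo,    hi,   plo,  phi,  dir
    c("sodium",         135,   145,  110,  170,  -1),
    c("potassium",      3.5,   5.0,  1.5,  9.0,   1),
    c("chloride",       98,    107,  75,   130,  -1),
    c("bicarbonate",    20,    28,   5,    45,   -1),
    c("bun",            5,     18,   1,    120,   1),
    c("creatinine",     0.3,   0.9,  0.1,  8.0,   1),
    c("glucose",        70,    140,  20,   600,   1),
    c("calcium",        8.8,   10.8, 5.0,  14.0, -1),
    c("magnesium",      1.6,   2.4,  0.5,  5.0,   1),
    c("phosphate",      3.5,   5.5,  1.0,  9.0,   1),
    c("wbc",            5.0,   14.5, 0.5,  60,    1),
    c("hemoglobin",     10.5,  14.0, 3.0,  20,   -1),
    c("hematocrit",     32,    42,   10,   60,   -1),
    c("platelets",      150,   450,  10,   900,  -1),
    c("lactate",        0.5,   2.2,  0.1,  15,    1),
    c("ph",             7.32,  7.43, 6.8,  7.7,  -1),
    c("pco2",           35,    45,   15,   110,   1),
    c("po2",            80,    100,  30,   250,  -1),
    c("albumin",        3.5,   5.0,  1.0,  6.0,  -1),
    c("bilirubin",      0.2,   1.2,  0.0,  25,    1),
    c("alt",            10,    40,   2,    1000,  1),
    c("ast",            15,    45,   2,    1000,  1),
    c("inr",            0.9,   1.2,  0.7,  8.0,   1),
    c("ptt",            25,    35,   15,   150,   1),
    c("crp",            0.0,   0.8,  0.0,  40,    1),
    c("band_pct",       0,     5,    0,    50,    1),
    c("base_excess",    -2,    2,    -25,  15,   -1),
    c("anion_gap",      6,     14,   2,    40,    1),
    c("ionized_ca",     1.1,   1.3,  0.6,  1.8,  -1),
    c("ammonia",        15,    45,   5,    400,   1)
  )
  n <- as.integer(n)
  if (n < 1L || n > length(spec)) stopf("lab_panel: n must be in 1..%d", length(spec))
  dt <- data.table::rbindlist(lapply(spec[seq_len(n)], function(r) {
    data.table::data.table(
      name = r[1],
      normal_lo = as.numeric(r[2]), normal_hi = as.numeric(r[3]),
      plaus_lo = as.numeric(r[4]), plaus_hi = as.numeric(r[5]),
      direction = as.numeric(r[6])
    )
  }))
  dt[, `:=`(noise_frac = 0.80, rate_routine = 1 / 24, rate_icu = 1 / 6)]
  dt[]
}

#' Default vital-sign panel
#'
#' Six vital signs with the same schema as [default_lab_panel()]. Vitals are
#' sampled roughly every four hours on routine wards and roughly hourly in
#' intensive care.
#'
#' @return A `data.table` with one row per vital sign.
#' @export
default_vital_panel <- function() {
  dt <- data.table::rbindlist(list(
    data.table::data.table(name = "heart_rate",  normal_lo = 80,  normal_hi = 130,
                           plaus_lo = 30,  plaus_hi = 250, direction = 1),
    data.table::data.table(name = "resp_rate",   normal_lo = 18,  normal_hi = 30,
                           plaus_lo = 5,   plaus_hi = 90,  direction = 1),
    data.table::data.table(name = "sbp",         normal_lo = 90,  normal_hi = 115,
                           plaus_lo = 40,  plaus_hi = 200, direction = -1),
    data.table::data.table(name = "dbp",         normal_lo = 50,  normal_hi = 75,
                           plaus_lo = 20,  plaus_hi = 130, direction = -1),
    data.table::data.table(name = "spo2",        normal_lo = 95,  normal_hi = 100,
                           plaus_lo = 60,  plaus_hi = 100, direction = -1),
    data.table::data.table(name = "temperature", normal_lo = 36.5, normal_hi = 37.5,
                           plaus_lo = 33,  plaus_hi = 42,  direction = 1)
  ))
  dt[, `:=`(noise_frac = 0.90, rate_routine = 0.25, rate_icu = 0.95)]
  dt[]
}

#' Default medication class table
#'
#' Synthetic medication classes (IDs `1..n`) with per-location administration
#' start rates (expected administrations per patient-hour), a severity gain
#' multiplying the rate for sicker patients, and a log-normal administration
#' duration. A deterministic pattern assigns roughly a third of classes as
#' ICU-leaning, a third as ward-leaning and a third as neutral, so that care
#' location carries a medication signature. Three classes carry the names of
#' therapies whose usage differs across institutions in practice
#' (bronchodilators, antipsychotics, lubricants/irrigations); the remainder
#' are synthetic identifiers with no external vocabulary mapping.
#'
#' @param n Number of classes (default 143).
#' @return A `data.table` with one row per medication class.
#' @export
default_med_classes <- function(n = 143L) {
  n <- as.integer(n)
  if (n < 1L) stopf("med_classes: n must be >= 1")
  i <- seq_len(n)
  # deterministic size variation, no RNG so all sites share physiology
  size <- 0.5 + ((i * 7L) %% 10L) / 10L
  group <- c("icu", "ward", "neutral")[(i %% 3L) + 1L]
  # ICU-leaning classes behave like infusions: frequent starts, long runs
  rate_icu <- ifelse(group == "icu", 0.0040 * size,
                     ifelse(group == "ward", 0.00015 * size, 0.0005 * size))
  rate_routine <- ifelse(group == "icu", 0.0002 * size,
                         ifelse(group == "ward", 0.0014 * size, 0.0005 * size))
  lab <- sprintf("med_class_%03d", i)
  if (n >= 12L) lab[12L] <- "bronchodilators"
  if (n >= 27L) lab[27L] <- "antipsychotics"
  if (n >= 33L) lab[33L] <- "lubricants_irrigations"
  data.table::data.table(
    class_id = i, label = lab, group = group,
    rate_routine = rate_routine, rate_icu = rate_icu,
    severity_gain = ifelse(group == "icu", 1.5, 0.5),
    dur_meanlog = ifelse(group == "icu", log(10), log(5)), dur_sdlog = 0.6
  )
}
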