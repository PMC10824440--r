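#' Cohort generator configuration
#'
#' Builds a validated configuration for [generate_cohort()]. Defaults emulate
#' the population structure of a large pediatric inpatient sample admitted
#' through the emergency department: 19.2 % of admissions direct to the ICU,
#' 3.0 % of routine admissions later transferred to the ICU, 78.1 % of
#' ICU admissions later transferred to routine care, age with median 68
#' months (IQR 15-157), and hospital length of stay whose mixture median is
#' about 2.7 days (routine-only stays shorter than ICU stays), which together
#' put roughly 20.8 % of 6-hour periods in the ICU.
#'
#' A latent severity score in (0, 1) follows a discrete-time mean-reverting
#' process sampled hourly. Care-location transfers occur when severity
#' crosses location-specific thresholds with hysteresis (`icu_entry` >
#' `icu_exit`); per-patient drift rates are calibrated so expected crossing
#' times match planned transfer times, which is what pins the realized
#' transfer rates to the configured probabilities. Observables (labs, vitals,
#' coma score, medication administrations) are driven by severity and by
#' current location only, so a model built on observables can never beat a
#' predictor with access to the latent trace.
#'
#' @param n_admissions Number of hospital admissions to simulate.
#' @param p_direct_icu Probability an admission goes directly to the ICU.
#' @param p_routine_to_icu Probability a routine admission later transfers to
#'   the ICU.
#' @param p_icu_to_routine Fraction of ICU admissions (direct or transferred
#'   in) later transferred out to routine care.
#' @param age_months Log-normal parameters (`meanlog`, `sdlog`, `max`) for
#'   age in months.
#' @param los_days Per-type log-normal stay lengths: lists `routine` and
#'   `icu`, each with `meanlog`/`sdlog`, plus `min`/`max` clamps in days.
#' @param lab_panel,vital_panel Variable panels, see [default_lab_panel()]
#'   and [default_vital_panel()].
#' @param med_classes Medication class table, see [default_med_classes()].
#' @param coma Coma-score process: integer range `min`..`max` (3-15),
#'   hourly sampling rates by location, severity-to-score `slope`, threshold
#'   `onset` (severity above which the score falls), observation noise, and
#'   a persistent neurologic-impairment component: a fraction `p_impaired`
#'   of patients carries a patient-level downward score offset (uniform on
#'   1..`offset_max`) that is independent of systemic severity — the
#'   population whose care location is decided by neuro practice rules
#'   rather than physiology.
#' @param coma_icu_threshold Practice parameter: minimum admission coma score
#'   tolerated on a routine ward. Admissions scoring below it are admitted
#'   directly to the ICU regardless of the physiologic plan, so raising the
#'   threshold admits milder patients to the ICU. The default (4) almost
#'   never binds.
#' @param severity Latent-process parameters: reversion rate `theta` (per
#'   hour, stable phases), innovation standard deviation `vol`, thresholds
#'   `icu_entry` and `icu_exit`, phase targets `routine_mu`, `icu_mu`,
#'   `deteriorate_mu`, `improve_mu`, and admission spread `sd0`.
#' @param transfer_fracs Planned transfer-time fractions of the stay: beta
#'   parameters for the ICU fraction of direct admissions transferred out
#'   (`direct_icu_out`), the routine residence fraction before a
#'   routine-to-ICU transfer (`r2i_routine`), and the ICU fraction of the
#'   remaining stay for those transferred back (`r2i_return`).
#' @param sex_female,race_probs Demographic draws (descriptive only, never
#'   model features).
#' @param seed Integer seed; identical `(config, seed)` pairs generate
#'   byte-identical cohorts.
#' @return An object of class `ci_cohort_config`.
#' @seealso [generate_cohort()], [site_shift()], [make_site_pair()]
#' @export
cohort_config <- function(n_admissions = 20000L,
                          p_direct_icu = 0.192,
                          p_routine_to_icu = 0.030,
                          p_icu_to_routine = 0.781,
                          age_months = list(meanlog = log(68), sdlog = 1.45, max = 252),
                          los_days = list(
                            routine = list(meanlog = log(2.4), sdlog = 1.00),
                            icu     = list(meanlog = log(4.2), sdlog = 0.93),
                            min = 0.15, max = 45),
                          lab_panel = default_lab_panel(),
                          vital_panel = default_vital_panel(),
                          med_classes = default_med_classes(),
                          coma = list(min = 3L, max = 15L, rate_routine = 0.10,
                                      rate_icu = 0.50, slope = 20, onset = 0.30,
                                      noise_sd = 1.0, p_impaired = 0.12,
                                      offset_max = 9),
                          coma_icu_threshold = 4,
                          severity = list(theta = 0.12, vol = 0.03,
                                          icu_entry = 0.65, icu_exit = 0.50,
                                          routine_mu = 0.30, icu_mu = 0.80,
                                          deteriorate_mu = 0.88, improve_mu = 0.15,
                                          sd0 = 0.05),
                          transfer_fracs = list(
                            direct_icu_out = c(shape1 = 6.1, shape2 = 3.9),
                            r2i_routine    = c(shape1 = 2.8, shape2 = 5.2),
                            r2i_return     = c(shape1 = 5.2, shape2 = 2.8)),
                          sex_female = 0.475,
                          race_probs = c(black = 0.434, white = 0.198, other = 0.368),
                          seed = 1L) {
  cfg <- structure(list(
    n_admissions = as.integer(n_admissions),
    p_direct_icu = p_direct_icu,
    p_routine_to_icu = p_routine_to_icu,
    p_icu_to_routine = p_icu_to_routine,
    age_months = age_months, los_days = los_days,
    lab_panel = data.table::as.data.table(lab_panel),
    vital_panel = data.table::as.data.table(vital_panel),
    med_classes = data.table::as.data.table(med_classes),
    coma = coma, coma_icu_threshold = coma_icu_threshold,
    severity = severity, transfer_fracs = transfer_fracs,
    sex_female = sex_female, race_probs = race_probs,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "ci_cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  for (p in c("p_direct_icu", "p_routine_to_icu", "p_icu_to_routine", "sex_female"))
    if (!is_probability(cfg[[p]]))
      stopf("cohort_config: field '%s' must be a probability in [0, 1]", p)
  if (cfg$p_direct_icu + (1 - cfg$p_direct_icu) * cfg$p_routine_to_icu >= 1)
    stopf("cohort_config: direct-ICU plus routine-to-ICU mass must stay below 1")
  if (cfg$n_admissions < 1L)
    stopf("cohort_config: field 'n_admissions' must be >= 1")
  sv <- cfg$severity
  if (sv$icu_exit >= sv$icu_entry)
    stopf("cohort_config: severity 'icu_exit' must lie below 'icu_entry' (hysteresis)")
  if (sv$vol < 0 || sv$theta < 0 || sv$theta > 1)
    stopf("cohort_config: severity 'theta' in [0,1] and 'vol' >= 0 required")
  for (pan in c("lab_panel", "vital_panel")) {
    p <- cfg[[pan]]
    need <- c("name", "normal_lo", "normal_hi", "plaus_lo", "plaus_hi",
              "direction", "noise_frac", "rate_routine", "rate_icu")
    if (!all(need %in% names(p)))
      stopf("cohort_config: field '%s' is missing columns: %s", pan,
            paste(setdiff(need, names(p)), collapse = ", "))
    if (any(p$plaus_lo > p$normal_lo) || any(p$normal_hi > p$plaus_hi))
      stopf("cohort_config: field '%s' has reference ranges outside plausible ranges", pan)
    if (any(p$rate_routine < 0 | p$rate_routine > 1 | p$rate_icu < 0 | p$rate_icu > 1))
      stopf("cohort_config: field '%s' sampling rates must be in [0, 1]", pan)
  }
  if (any(cfg$med_classes$rate_routine < 0) || any(cfg$med_classes$rate_icu < 0))
    stopf("cohort_config: field 'med_classes' rates must be non-negative")
  if (cfg$coma$min < 3L || cfg$coma$max > 15L || cfg$coma$min >= cfg$coma$max)
    stopf("cohort_config: field 'coma' range must sit within 3..15")
  if (abs(sum(cfg$race_probs) - 1) > 1e-8)
    stopf("cohort_config: field 'race_probs' must sum to 1")
  invisible(cfg)
}

#' @export
print.ci_cohort_config <- function(x, ...) {
  cat("<ci_cohort_config>\n")
  cat(sprintf("  admissions: %d  (direct ICU %.1f%%, routine->ICU %.1f%%, ICU->routine %.1f%%)\n",
              x$n_admissions, 100 * x$p_direct_icu, 100 * x$p_routine_to_icu,
              100 * x$p_icu_to_routine))
  cat(sprintf("  panels: %d labs, %d vitals, coma %d..%d, %d medication classes\n",
              nrow(x$lab_panel), nrow(x$vital_panel), x$coma$min, x$coma$max,
              nrow(x$med_classes)))
  cat(sprintf("  severity: theta %.2f vol %.3f entry %.2f exit %.2f; ward coma floor %g\n",
              x$severity$theta, x$severity$vol, x$severity$icu_entry,
              x$severity$icu_exit, x$coma_icu_threshold))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Describe an inter-institutional practice shift
#'
#' A practice shift perturbs only how a site uses therapies and how readily
#' it admits to the ICU; it never touches physiology (panels, severity
#' process, population rates). `med_multipliers` scales the ICU-side
#' administration rate of selected classes (values > 1 increase ICU usage at
#' the shifted site, values < 1 decrease it); `med_routine_multipliers` does
#' the same for ward-side rates; `coma_threshold_delta` shifts the minimum
#' coma score tolerated on the ward (positive values admit milder patients
#' to the ICU).
#'
#' @param med_multipliers Named numeric vector, names are medication class
#'   IDs, values multiply `rate_icu` at the shifted site.
#' @param med_routine_multipliers Same, for `rate_routine`.
#' @param coma_threshold_delta Added to `coma_icu_threshold` at the shifted
#'   site.
#' @return An object of class `ci_site_shift`.
#' @export
site_shift <- function(med_multipliers = numeric(),
                       med_routine_multipliers = numeric(),
                       coma_threshold_delta = 0) {
  for (m in list(med_multipliers, med_routine_multipliers)) {
    if (length(m) && (is.null(names(m)) || any(!nzchar(names(m)))))
      stopf("site_shift: medication multipliers must be named by class id")
    if (any(m < 0)) stopf("site_shift: multipliers must be non-negative")
  }
  structure(list(med_multipliers = med_multipliers,
                 med_routine_multipliers = med_routine_multipliers,
                 coma_threshold_delta = coma_threshold_delta),
            class = "ci_site_shift")
}

#' Default practice shift used in the two-site experiment
#'
#' Inverts the location association of a block of medication classes (the
#' shifted site uses some reference-ICU therapies on the ward and some
#' reference-ward therapies in its ICU) and raises the ward coma floor so
#' milder neurologic impairment is admitted to intensive care. This is the
#' kind of practice divergence that degrades a model transported from
#' another institution while leaving physiology untouched.
#'
#' @param med_classes Medication class table of the reference configuration.
#' @return A `ci_site_shift`.
#' @export
default_site_shift <- function(med_classes = default_med_classes()) {
  icu_cls <- med_classes$class_id[med_classes$group == "icu"]
  ward_cls <- med_classes$class_id[med_classes$group == "ward"]
  flip_icu <- head(icu_cls, 24L)   # ICU therapies the local site rarely uses
  flip_ward <- head(ward_cls, 24L) # ward therapies the local ICU leans on
  mult <- c(stats::setNames(rep(0.05, length(flip_icu)), flip_icu),
            stats::setNames(rep(26.0, length(flip_ward)), flip_ward))
  rmult <- c(stats::setNames(rep(25.0, length(flip_icu)), flip_icu),
             stats::setNames(rep(0.15, length(flip_ward)), flip_ward))
  site_shift(med_multipliers = mult, med_routine_multipliers = rmult,
             coma_threshold_delta = 6)
}

#' Build a reference/local configuration pair
#'
#' Returns two configurations differing only in practice parameters: the
#' reference config is returned untouched, the local config applies the
#' shift to medication usage rates and the ward coma floor. Any attempt to
#' express a physiologic change (unknown class IDs, negative rates) is
#' rejected.
#'
#' @param config A `ci_cohort_config`.
#' @param shift A `ci_site_shift` (zero shift returns two identical
#'   configurations).
#' @return `list(reference = config, local = shifted config)`.
#' @export
make_site_pair <- function(config, shift = site_shift()) {
  stopifnot(inherits(config, "ci_cohort_config"), inherits(shift, "ci_site_shift"))
  local <- config
  local$med_classes <- data.table::copy(config$med_classes)
  apply_mult <- function(mult, col) {
    if (!length(mult)) return()
    ids <- as.integer(names(mult))
    bad <- setdiff(ids, local$med_classes$class_id)
    if (length(bad))
      stopf("make_site_pair: shift names unknown medication classes: %s",
            paste(bad, collapse = ", "))
    idx <- match(ids, local$med_classes$class_id)
    data.table::set(local$med_classes, i = idx, j = col,
                    value = local$med_classes[[col]][idx] * unname(mult))
  }
  apply_mult(shift$med_multipliers, "rate_icu")
  apply_mult(shift$med_routine_multipliers, "rate_routine")
  local$coma_icu_threshold <- config$coma_icu_threshold + shift$coma_threshold_delta
  if (local$coma_icu_threshold < config$coma$min - 1 ||
      local$coma_icu_threshold > config$coma$max)
    stopf("make_site_pair: shifted coma threshold leaves the score range")
  validate_cohort_config(local)
  list(reference = config, local = local)
}
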