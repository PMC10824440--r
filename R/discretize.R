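#' Discretize encounters into labeled 6-hour periods
#'
#' Cuts each hospital course into consecutive 6-hour windows measured from
#' admission. Windows are half-open `[start, end)`; the final window may be
#' shorter than 6 hours and is retained (configurable off). A window whose
#' interior contains a care-location change is labeled `transition` and is
#' excluded from modeling and evaluation downstream; all other windows carry
#' the location that covers them.
#'
#' @param cohort A `ci_cohort`.
#' @param period_hours Window length in hours (6 by default).
#' @param keep_partial Keep the final partial window (< `period_hours`)?
#' @return A `data.table` with one row per period: `encounter_id`,
#'   `period_index` (0-based), `p_start`, `p_end` (hours since admission) and
#'   `care_label` in `{routine, ICU, transition}`.
#' @export
discretize_periods <- function(cohort, period_hours = 6, keep_partial = TRUE) {
  stopifnot(inherits(cohort, "ci_cohort"))
  seg <- cohort$segments
  bad <- cohort$events[time_hr < 0 | time_hr >
                         cohort$encounters$los_hours[match(encounter_id,
                                                          cohort$encounters$encounter_id)]]
  if (nrow(bad))
    stopf("discretize_periods: events outside encounter bounds for encounter(s): %s",
          paste(unique(bad$encounter_id), collapse = ", "))
  los <- cohort$encounters[, .(encounter_id, los_hours)]
  n_per <- pmax(ceiling(los$los_hours / period_hours), 1L)
  per <- data.table::data.table(
    encounter_id = rep(los$encounter_id, n_per),
    period_index = sequence(n_per) - 1L
  )
  per[, p_start := period_index * period_hours]
  per[, p_end := pmin(p_start + period_hours,
                      rep(los$los_hours, n_per))]
  if (!keep_partial) per <- per[p_end - p_start >= period_hours]
  # interior segment boundaries -> transition
  bnd <- seg[start_hr > 0, .(encounter_id, t = start_hr)]
  per[, care_label := lookup_location(seg, encounter_id, p_start)]
  if (nrow(bnd)) {
    bnd[, period_index := floor(t / period_hours)]
    trans <- unique(bnd[t %% period_hours > 0, .(encounter_id, period_index)])
    per[trans, on = c("encounter_id", "period_index"), care_label := "transition"]
  }
  data.table::setkey(per, encounter_id, period_index)
  per[]
}

#' Label future-horizon outcomes for each period
#'
#' For an origin window `k`, horizon `Hj` (`j = 1..4`, the `>6-12`, `>12-18`,
#' `>18-24` and `>24-30` hour windows ahead) targets window `k + 1 + j`. The
#' outcome is the target window's care label, or `NA` (undefined) when the
#' target falls after discharge or on a transition window. Undefined
#' outcomes are dropped from training and evaluation by the callers.
#'
#' @param periods Output of [discretize_periods()].
#' @param horizons Integer horizon indices (default 1:4).
#' @return `periods` with added columns `H1..H4` coded 1 (ICU), 0 (routine)
#'   or `NA` (undefined).
#' @export
label_horizons <- function(periods, horizons = 1:4) {
  per <- data.table::copy(periods)
  data.table::setkey(per, encounter_id, period_index)
  lab_num <- ifelse(per$care_label == "ICU", 1,
                    ifelse(per$care_label == "routine", 0, NA_real_))
  for (j in horizons) {
    tgt <- data.table::data.table(encounter_id = per$encounter_id,
                                  period_index = per$period_index + 1L + j)
    m <- per[tgt, on = c("encounter_id", "period_index"), which = TRUE]
    per[, paste0("H", j) := lab_num[m]]
  }
  per[]
}

#' Fraction of ICU periods among non-transition periods
#'
#' @param periods Output of [discretize_periods()].
#' @return Proportion of `ICU` labels among `ICU` + `routine` labels.
#' @export
icu_period_fraction <- function(periods) {
  n_icu <- sum(periods$care_label == "ICU")
  n_rt <- sum(periods$care_label == "routine")
  n_icu / (n_icu + n_rt)
}

#' Assign patients to train/validation/test partitions
#'
#' Patient-level split with largest-remainder rounding of the partition
#' sizes, so all periods of one patient share a partition.
#'
#' @param patient_ids Vector of unique patient identifiers.
#' @param fractions Partition fractions summing to 1 (default 75/13/12).
#' @param seed Integer seed for the permutation.
#' @return A `data.table` with `patient_id` and `partition` in
#'   `{train, validation, test}`.
#' @export
split_patients <- function(patient_ids, fractions = c(train = 0.75,
                                                      validation = 0.13,
                                                      test = 0.12),
                           seed = 1L) {
  if (!length(patient_ids)) stopf("split_patients: empty patient id list")
  if (anyDuplicated(patient_ids)) stopf("split_patients: patient ids must be unique")
  if (abs(sum(fractions) - 1) > 1e-8)
    stopf("split_patients: fractions must sum to 1")
  n <- length(patient_ids)
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  perm <- with_seed(seed, sample.int(n))
  part <- rep(names(fractions) %||% c("train", "validation", "test"), times = base)
  data.table::data.table(patient_id = patient_ids[perm], partition = part)[
    order(match(patient_id, patient_ids))]
}
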