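# Shared fixtures, built in code at test time.

# A small cohort configuration used where generation speed matters more
# than population size. Panels keep their full defaults.
small_config <- function(n = 300L, seed = 7L, ...) {
  cohort_config(n_admissions = n, seed = seed, ...)
}

# Hand-built toy cohort: one encounter with fully controlled segments and
# events, for window-arithmetic tests. `los` in hours; `transfers` is a
# data.table(time_hr, to).
toy_cohort <- function(los = 26, segments = NULL, events = NULL, meds = NULL) {
  cfg <- cohort_config(n_admissions = 1L, seed = 1L,
                       lab_panel = default_lab_panel(3L),
                       med_classes = default_med_classes(5L))
  admit <- as.POSIXct("2018-03-01 00:00:00", tz = "UTC")
  if (is.null(segments))
    segments <- data.table::data.table(encounter_id = 1L, location = "routine",
                                       start_hr = 0, end_hr = los)
  if (is.null(events))
    events <- data.table::data.table(encounter_id = integer(), time_hr = numeric(),
                                     kind = character(), variable_id = character(),
                                     value = numeric())
  if (is.null(meds))
    meds <- data.table::data.table(encounter_id = integer(), class_id = integer(),
                                   start_hr = numeric(), end_hr = numeric())
  structure(list(
    encounters = data.table::data.table(
      encounter_id = 1L, age_months = 24, sex = "F", race_category = "other",
      admit_time = admit, discharge_time = admit + los * 3600,
      los_hours = los, chronic_neuro = FALSE, admission_type = "routine_stable"),
    segments = segments, events = events, medications = meds,
    latent = data.table::data.table(encounter_id = integer(), hour = integer(),
                                    severity = numeric(), location = character()),
    config = cfg, seed = 1L), class = "ci_cohort")
}

# Toy trajectory exercising the transfer-cohort eligibility rules: one
# patient with `residence_hr` hours in the origin location, then a transfer.
toy_transfer_site <- function(residence_hr, post_hr = 18, new_data = TRUE,
                              origin = "routine") {
  dest <- if (origin == "routine") "ICU" else "routine"
  los <- residence_hr + post_hr
  seg <- data.table::data.table(
    encounter_id = 1L, location = c(origin, dest),
    start_hr = c(0, residence_hr), end_hr = c(residence_hr, los))
  per <- label_horizons(discretize_periods(toy_cohort(los = los, segments = seg)))
  per[, new_data_flag := new_data]
  list(meta = per, segments = seg)
}

# Brute-force oracles ------------------------------------------------------

# AUROC as the exhaustive pairwise concordance count.
auc_brute <- function(scores, outcomes) {
  sp <- scores[outcomes == 1]; sn <- scores[outcomes == 0]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# PR-AUC by explicit threshold enumeration and trapezoidal integration.
pr_auc_brute <- function(scores, outcomes) {
  thr <- sort(unique(scores), decreasing = TRUE)
  rec <- numeric(length(thr)); prec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tp <- sum(pred & outcomes == 1); fp <- sum(pred & outcomes == 0)
    rec[i] <- tp / sum(outcomes == 1)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 1
  }
  rec0 <- c(0, rec); prec0 <- c(prec[1], prec)
  sum(diff(rec0) * (head(prec0, -1) + tail(prec0, -1)) / 2)
}

# Memoised pipeline runs shared across test files (built once per session).
.fixture_env <- new.env(parent = emptyenv())

# Two-site experiment with the default practice shift, desk scale.
shared_experiment <- function() {
  if (is.null(.fixture_env$shifted)) {
    cfg <- experiment_config(
      cohort = cohort_config(n_admissions = 800L),
      protocol = ci_protocol_desk(epochs = 10L, seed = 5L),
      importance = NULL, min_interval_n = 100L, seed = 2024L)
    .fixture_env$shifted <- suppressWarnings(run_experiment(cfg))
  }
  .fixture_env$shifted
}

# Same scale with a zero practice shift: both sites share one distribution.
shared_null_experiment <- function() {
  if (is.null(.fixture_env$null)) {
    cfg <- experiment_config(
      cohort = cohort_config(n_admissions = 800L),
      shift = site_shift(),
      protocol = ci_protocol_desk(epochs = 10L, seed = 6L),
      importance = NULL, min_interval_n = 100L, seed = 4048L)
    .fixture_env$null <- suppressWarnings(run_experiment(cfg))
  }
  .fixture_env$null
}

# Exhaustive search for the largest threshold reaching a sensitivity.
threshold_sens_brute <- function(scores, outcomes, target) {
  cand <- sort(unique(c(scores - 1e-9, scores, 0)))
  best <- NULL
  for (t in cand) {
    pred <- scores > t
    sens <- sum(pred & outcomes == 1) / sum(outcomes == 1)
    if (sens >= target && (is.null(best) || t > best)) best <- t
  }
  best
}
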