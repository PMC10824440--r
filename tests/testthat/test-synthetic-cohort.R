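test_that("configuration validation names the offending field", {
  expect_error(cohort_config(p_direct_icu = 1.3), "p_direct_icu")
  expect_error(cohort_config(p_direct_icu = 0.8, p_routine_to_icu = 1.0),
               "below 1")
  expect_error(cohort_config(severity = list(theta = 0.1, vol = 0.03,
                                             icu_entry = 0.5, icu_exit = 0.6,
                                             routine_mu = 0.3, icu_mu = 0.8,
                                             deteriorate_mu = 0.88,
                                             improve_mu = 0.15, sd0 = 0.05)),
               "hysteresis")
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- small_config(n = 120L)
  a <- generate_cohort(cfg, seed = 99L)
  b <- generate_cohort(cfg, seed = 99L)
  expect_identical(a$encounters, b$encounters)
  expect_identical(a$segments, b$segments)
  expect_identical(a$events, b$events)
  expect_identical(a$medications, b$medications)
  c <- generate_cohort(cfg, seed = 100L)
  expect_false(identical(a$events, c$events))
})

test_that("realized admission-path fractions hit the configured targets", {
  co <- generate_cohort(cohort_config(n_admissions = 20000L, seed = 41L),
                        include_streams = FALSE)
  s <- cohort_summary(co)
  expect_lt(abs(s$frac_direct_icu - 0.192), 0.01)
  expect_lt(abs(s$frac_routine_to_icu - 0.030), 0.01)
  expect_lt(abs(s$frac_icu_to_routine - 0.781), 0.01)
  # downstream 6-hour discretization: ICU share of non-transition periods
  per <- discretize_periods(co)
  expect_lt(abs(icu_period_fraction(per) - 0.208), 0.02)
})

test_that("degenerate severity process yields zero transfers", {
  cfg <- cohort_config(n_admissions = 150L, p_routine_to_icu = 0,
                       p_icu_to_routine = 0,
                       coma = list(min = 3L, max = 15L, rate_routine = 0.1,
                                   rate_icu = 0.5, slope = 20, onset = 0.30,
                                   noise_sd = 1.0, p_impaired = 0,
                                   offset_max = 9),
                       severity = list(theta = 0.12, vol = 0, icu_entry = 0.65,
                                       icu_exit = 0.50, routine_mu = 0.30,
                                       icu_mu = 0.80, deteriorate_mu = 0.88,
                                       improve_mu = 0.15, sd0 = 0.05),
                       seed = 5L)
  co <- generate_cohort(cfg, include_streams = FALSE)
  expect_equal(nrow(co$segments), nrow(co$encounters))  # one segment each
})

test_that("segments are contiguous, alternating, and cover the stay", {
  co <- generate_cohort(small_config(n = 400L), include_streams = FALSE)
  seg <- co$segments
  bad <- seg[, {
    ok_cover <- abs(start_hr[1]) < 1e-9 &&
      abs(end_hr[.N] - co$encounters$los_hours[match(encounter_id[1],
          co$encounters$encounter_id)]) < 1e-9
    ok_contig <- .N == 1 || all(abs(start_hr[-1] - end_hr[-.N]) < 1e-9)
    ok_alt <- .N == 1 || all(location[-1] != location[-.N])
    .(ok = ok_cover && ok_contig && ok_alt)
  }, by = encounter_id]
  expect_true(all(bad$ok))
})

test_that("generated values respect plausible ranges and stay in-encounter", {
  co <- generate_cohort(small_config(n = 200L))
  pan <- rbind(co$config$lab_panel[, .(variable_id = name, plaus_lo, plaus_hi)],
               co$config$vital_panel[, .(variable_id = name, plaus_lo, plaus_hi)])
  ev <- merge(co$events[kind != "coma_score"], pan, by = "variable_id")
  expect_true(all(ev$value >= ev$plaus_lo & ev$value <= ev$plaus_hi))
  coma <- co$events[kind == "coma_score"]
  expect_true(all(coma$value >= 3 & coma$value <= 15))
  los <- co$encounters$los_hours[match(co$events$encounter_id,
                                       co$encounters$encounter_id)]
  expect_true(all(co$events$time_hr >= 0 & co$events$time_hr <= los))
  expect_true(all(co$medications$end_hr >= co$medications$start_hr))
})

test_that("zero shift returns two identical configurations", {
  cfg <- small_config()
  pair <- make_site_pair(cfg, site_shift())
  expect_identical(pair$reference$med_classes, pair$local$med_classes)
  expect_identical(pair$reference$coma_icu_threshold, pair$local$coma_icu_threshold)
})

test_that("physiology-touching shifts are rejected", {
  cfg <- small_config()
  expect_error(make_site_pair(cfg, site_shift(med_multipliers = c("999" = 2))),
               "unknown medication classes")
  expect_error(site_shift(med_multipliers = c("12" = -1)), "non-negative")
  expect_error(site_shift(med_multipliers = 2), "named")
})

test_that("raising ICU bronchodilator usage is detectable with Cohen's h > 0.2", {
  cfg <- cohort_config(n_admissions = 700L, seed = 61L)
  pair <- make_site_pair(cfg, site_shift(med_multipliers = c("12" = 4)))
  exposure_rate <- function(config, seed) {
    co <- generate_cohort(config, seed = seed)
    per <- discretize_periods(co)
    f <- build_features(per, co)
    icu_rows <- which(f$meta$care_label == "ICU")
    mean(f$base[["med_12__frac"]][icu_rows] > 0)
  }
  p_ref <- exposure_rate(pair$reference, 62L)
  p_loc <- exposure_rate(pair$local, 63L)
  expect_gt(p_loc, p_ref)
  expect_gt(cohens_h(p_loc, p_ref), 0.2)
})

test_that("raising the ward coma floor strictly raises the ICU period fraction", {
  cfg <- cohort_config(n_admissions = 4000L, seed = 71L)
  pair <- make_site_pair(cfg, site_shift(coma_threshold_delta = 6))
  f_ref <- icu_period_fraction(discretize_periods(
    generate_cohort(pair$reference, seed = 72L, include_streams = FALSE)))
  f_loc <- icu_period_fraction(discretize_periods(
    generate_cohort(pair$local, seed = 72L, include_streams = FALSE)))
  expect_gt(f_loc, f_ref)
})
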