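test_that("a 26-hour single-segment stay gives 4 full + 1 partial routine windows", {
  co <- toy_cohort(los = 26)
  per <- discretize_periods(co)
  expect_equal(nrow(per), 5L)
  expect_equal(per$p_end - per$p_start, c(6, 6, 6, 6, 2))
  expect_true(all(per$care_label == "routine"))
  # partial window dropped when requested
  expect_equal(nrow(discretize_periods(co, keep_partial = FALSE)), 4L)
  # 3-hour stay: one partial window
  expect_equal(nrow(discretize_periods(toy_cohort(los = 3))), 1L)
})

test_that("a mid-window transfer labels exactly the containing window transition", {
  seg <- data.table::data.table(encounter_id = 1L,
                                location = c("routine", "ICU"),
                                start_hr = c(0, 14), end_hr = c(14, 40))
  per <- discretize_periods(toy_cohort(los = 40, segments = seg))
  expect_equal(per$care_label,
               c("routine", "routine", "transition", "ICU", "ICU", "ICU", "ICU"))
  # a boundary exactly on the grid produces no transition window
  seg2 <- data.table::data.table(encounter_id = 1L,
                                 location = c("routine", "ICU"),
                                 start_hr = c(0, 12), end_hr = c(12, 40))
  per2 <- discretize_periods(toy_cohort(los = 40, segments = seg2))
  expect_false(any(per2$care_label == "transition"))
  expect_equal(per2$care_label[3], "ICU")
})

test_that("care-label counts partition the windows", {
  co <- generate_cohort(small_config(n = 250L), include_streams = FALSE)
  per <- discretize_periods(co)
  expect_equal(sum(per$care_label == "routine") + sum(per$care_label == "ICU") +
                 sum(per$care_label == "transition"), nrow(per))
})

test_that("horizon labels follow the window-offset mapping", {
  # brute-force oracle: outcome of Hj at origin k is the label of window
  # k+1+j, undefined off the end or on a transition window
  label_oracle <- function(labels, k, j) {
    t <- k + 1 + j
    if (t > length(labels)) return(NA_real_)
    if (labels[t] == "transition") return(NA_real_)
    as.numeric(labels[t] == "ICU")
  }
  # all-routine 40 h stay: origin 0 gives four routine labels
  per <- label_horizons(discretize_periods(toy_cohort(los = 40)))
  expect_equal(unlist(per[1, .(H1, H2, H3, H4)]), c(H1 = 0, H2 = 0, H3 = 0, H4 = 0))
  # origin 6 h before discharge: all horizons undefined
  last <- per[.N]
  expect_true(all(is.na(unlist(last[, .(H1, H2, H3, H4)]))))
  # transfer completing at hour 20 -> transition window [18,24):
  # H1 routine, H2 undefined (transition target), H3 onward ICU
  seg <- data.table::data.table(encounter_id = 1L,
                                location = c("routine", "ICU"),
                                start_hr = c(0, 20), end_hr = c(20, 48))
  per3 <- label_horizons(discretize_periods(toy_cohort(los = 48, segments = seg)))
  labs <- per3$care_label
  for (j in 1:4) {
    expect_equal(per3[[paste0("H", j)]][1], label_oracle(labs, 1, j))
  }
  expect_equal(per3$H1[1], 0)
  expect_true(is.na(per3$H2[1]))
  expect_equal(per3$H3[1], 1)
})

test_that("features summarize within-window events and flag lookback", {
  ev <- data.table::data.table(
    encounter_id = 1L,
    time_hr = c(1, 2, 5, 13),
    kind = "lab", variable_id = "sodium",
    value = c(140, 130, 135, 150))
  meds <- data.table::data.table(encounter_id = 1L, class_id = 3L,
                                 start_hr = 7, end_hr = 10)
  co <- toy_cohort(los = 24, events = ev, meds = meds)
  f <- build_features(discretize_periods(co), co)
  b <- f$base
  expect_equal(b[["sodium__min"]][1], 130)
  expect_equal(b[["sodium__max"]][1], 140)
  expect_equal(b[["sodium__mean"]][1], 135)
  expect_equal(b[["sodium__mean"]][3], 150)
  expect_true(is.na(b[["sodium__mean"]][2]))
  # med class 3 active hours 7-10 of window [6,12): exposure fraction 0.5
  expect_equal(b[["med_3__frac"]][2], 0.5)
  expect_equal(b[["med_3__n"]][2], 1)
  expect_equal(b[["med_3__frac"]][1], 0)
  # new-data gate: window [18,24) has no events at all
  expect_equal(f$meta$new_data_flag, c(TRUE, TRUE, TRUE, FALSE))
  # unknown variable rejected with its identifier
  ev_bad <- data.table::copy(ev); ev_bad$variable_id[1] <- "mystery"
  co_bad <- toy_cohort(los = 24, events = ev_bad)
  expect_error(build_features(discretize_periods(co_bad), co_bad), "mystery")
})

test_that("imputation carries forward, falls back to defaults, and stays leak-free", {
  ev <- data.table::data.table(
    encounter_id = 1L, time_hr = c(2, 14),
    kind = "vital", variable_id = "heart_rate", value = c(110, 150))
  co <- toy_cohort(los = 18, events = ev)
  f <- impute_features(build_features(discretize_periods(co), co))
  b <- f$base
  # window 1 observed, window 2 carried forward, window 3 observed anew
  expect_equal(b[["heart_rate__mean"]], c(110, 110, 150))
  expect_equal(unname(f$base_mask[, "heart_rate__mean"]), c(FALSE, TRUE, FALSE))
  # never-observed variable falls back to the age-band normal midpoint
  expect_equal(b[["sodium__mean"]], rep(140, 3))
  # fully observed entries are untouched
  expect_equal(b[["heart_rate__mean"]][1], 110)
})

test_that("no feature depends on events after its window (leakage check)", {
  ev <- data.table::data.table(
    encounter_id = 1L, time_hr = c(2, 8, 14, 20),
    kind = "vital", variable_id = "heart_rate", value = c(100, 120, 140, 160))
  co1 <- toy_cohort(los = 24, events = ev)
  ev2 <- data.table::copy(ev); ev2$value[4] <- 60  # perturb future event
  co2 <- toy_cohort(los = 24, events = ev2)
  m1 <- feature_matrix(impute_features(build_features(discretize_periods(co1), co1)))
  m2 <- feature_matrix(impute_features(build_features(discretize_periods(co2), co2)))
  expect_identical(m1$X[1:3, ], m2$X[1:3, ])
  expect_false(identical(m1$X[4, ], m2$X[4, ]))
})

test_that("lookback slots repeat history and flag pre-admission windows", {
  ev <- data.table::data.table(
    encounter_id = 1L, time_hr = c(1, 7, 13),
    kind = "vital", variable_id = "heart_rate", value = c(100, 120, 140))
  co <- toy_cohort(los = 18, events = ev)
  fm <- feature_matrix(impute_features(build_features(discretize_periods(co), co)))
  expect_equal(unname(fm$X[3, "heart_rate__mean__lag0"]), 140)
  expect_equal(unname(fm$X[3, "heart_rate__mean__lag1"]), 120)
  expect_equal(unname(fm$X[3, "heart_rate__mean__lag2"]), 100)
  # first window: every lookback slot flagged imputed
  lag_cols <- grep("__lag[1-4]$", colnames(fm$mask))
  expect_true(all(fm$mask[1, lag_cols]))
  expect_false(all(fm$mask[3, grep("__lag1$", colnames(fm$mask))]))
})

test_that("patient split uses largest-remainder rounding and is deterministic", {
  sp <- split_patients(1:100, seed = 8L)
  expect_equal(as.vector(table(sp$partition)[c("train", "validation", "test")]),
               c(75, 13, 12))
  expect_identical(sp, split_patients(1:100, seed = 8L))
  expect_false(identical(sp$partition, split_patients(1:100, seed = 9L)$partition))
  expect_error(split_patients(integer()), "empty")
  expect_error(split_patients(1:10, fractions = c(0.5, 0.3)), "sum to 1")
  # all periods of one patient share a partition by construction
  co <- generate_cohort(small_config(n = 80L), include_streams = FALSE)
  site <- prepare_site(co, seed = 3L)
  per_pat <- site$meta[, data.table::uniqueN(partition), by = encounter_id]$V1
  expect_true(all(per_pat == 1L))
})

test_that("dropping the new-data gate removes rows without altering features", {
  co <- generate_cohort(small_config(n = 60L))
  site <- prepare_site(co, seed = 2L)
  gated <- which(site$meta$care_label != "transition" & site$meta$new_data_flag &
                   !is.na(site$meta$H1))
  ungated <- which(site$meta$care_label != "transition" & !is.na(site$meta$H1))
  expect_true(all(gated %in% ungated))
  expect_identical(site$X[gated, ], site$X[ungated, ][match(gated, ungated), ])
})
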