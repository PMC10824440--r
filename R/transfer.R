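#' Prediction accuracy in the transfer cohort
#'
#' Evaluates how often the horizon models correctly predict the
#' post-transfer care location for patients who actually moved
#' (routine to ICU, or ICU to routine). For a transfer at time `T`, the
#' first window fully in the new location is `w`; the horizon-`j` model
#' predicts it from origin window `w - (1 + j)`. A patient is eligible for
#' horizon `j` iff that origin window exists, lies entirely within the
#' pre-transfer residence in the origin location, and carries at least one
#' new data element. So 12 hours of pre-transfer residence admit only the
#' `>6-12 h` model, and at least 30 hours (with new data throughout) admit
#' all four. Predictions use fixed thresholds (one per horizon), typically
#' chosen on the full test set at a fixed sensitivity (routine to ICU) or
#' fixed specificity (ICU to routine).
#'
#' @param scores_by_horizon Named list `H1..H4` of score vectors aligned
#'   with the rows of `meta`.
#' @param meta Period metadata (`encounter_id`, `period_index`,
#'   `care_label`, `p_start`, `p_end`, `new_data_flag`).
#' @param segments Care-location segments of the same cohort.
#' @param direction `"routine_to_icu"` or `"icu_to_routine"`.
#' @param thresholds Named numeric vector of decision thresholds, one per
#'   horizon in `scores_by_horizon`.
#' @param period_hours Window length (6).
#' @return A `data.table` with one row per horizon: eligible patients,
#'   correct predictions and percent correct. Zero transferring patients
#'   yields an empty table with a warning.
#' @export
transfer_accuracy <- function(scores_by_horizon, meta, segments, direction,
                              thresholds, period_hours = 6) {
  direction <- match.arg(direction, c("routine_to_icu", "icu_to_routine"))
  origin <- if (direction == "routine_to_icu") "routine" else "ICU"
  dest <- if (direction == "routine_to_icu") "ICU" else "routine"
  horizons <- names(scores_by_horizon)
  stopifnot(all(horizons %in% names(thresholds)))

  seg <- data.table::copy(segments)
  data.table::setorder(seg, encounter_id, start_hr)
  seg[, prev_loc := data.table::shift(location), by = encounter_id]
  tr <- seg[prev_loc == origin & location == dest & start_hr > 0,
            .SD[1], by = encounter_id]      # first qualifying transfer per patient
  if (!nrow(tr)) {
    warning(sprintf("transfer_accuracy: no %s transfers in this cohort", direction))
    return(data.table::data.table(direction = character(), horizon = character(),
                                  threshold = numeric(), n_eligible = integer(),
                                  n_correct = integer(), pct_correct = numeric()))
  }
  # residence start in the origin location before this transfer
  res <- seg[tr[, .(encounter_id, t = start_hr)], on = "encounter_id"][
    location == origin & start_hr < t, .(res_start = max(start_hr)), by = encounter_id]
  # res_start is the start of the origin segment ending at the transfer
  tr <- merge(tr[, .(encounter_id, transfer_hr = start_hr)], res, by = "encounter_id")

  m <- data.table::copy(meta)
  m[, row := .I]
  out <- vector("list", length(horizons))
  for (i in seq_along(horizons)) {
    j <- as.integer(sub("^H", "", horizons[i]))
    w_first <- ifelse(tr$transfer_hr %% period_hours == 0,
                      tr$transfer_hr / period_hours,
                      floor(tr$transfer_hr / period_hours) + 1)
    k <- as.integer(w_first) - (1L + j)
    q <- data.table::data.table(encounter_id = tr$encounter_id, period_index = k,
                                res_start = tr$res_start)
    q <- m[q, on = c("encounter_id", "period_index"), nomatch = NULL]
    elig <- q[p_start >= res_start & care_label == origin & new_data_flag == TRUE]
    s <- scores_by_horizon[[horizons[i]]][elig$row]
    pred_icu <- s > thresholds[[horizons[i]]]
    correct <- if (dest == "ICU") pred_icu else !pred_icu
    out[[i]] <- data.table::data.table(
      direction = direction, horizon = horizons[i],
      threshold = unname(thresholds[[horizons[i]]]),
      n_eligible = nrow(elig), n_correct = sum(correct),
      pct_correct = if (nrow(elig)) 100 * mean(correct) else NA_real_)
  }
  data.table::rbindlist(out)
}
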