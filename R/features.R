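#' Build period-level features from raw observation streams
#'
#' Summarizes raw events into per-window features: min/max/mean for each
#' laboratory analyte, vital sign and the coma score; exposure
#' fraction-of-time and administration count for each medication class.
#' Lookback slots repeat the same summaries for up to `lookback` preceding
#' windows (slots before admission are flagged missing). The
#' `new_data_flag` is true iff at least one raw data element — a lab,
#' vital, coma score, or medication start/stop — occurred in the window;
#' downstream, predictions are only issued for flagged windows.
#'
#' No feature of window `k` depends on any event after the end of window
#' `k`: summaries are within-window and lookback only reaches backwards.
#'
#' @param periods Output of [discretize_periods()] (optionally already
#'   through [label_horizons()]).
#' @param cohort The `ci_cohort` the periods came from.
#' @param lookback Number of preceding windows summarized (default 4, i.e.
#'   up to 24 hours of history).
#' @return An object of class `ci_features` holding the base (current
#'   window) summary table with `NA` for unobserved entries, the period
#'   metadata, and the variable universe. Pass through [impute_features()]
#'   and [feature_matrix()] to obtain a complete numeric matrix.
#' @export
build_features <- function(periods, cohort, lookback = 4L) {
  stopifnot(inherits(cohort, "ci_cohort"))
  period_hours <- max(periods[, p_end - p_start])
  per <- data.table::copy(periods)
  data.table::setkey(per, encounter_id, period_index)
  nper <- per[, .(n_per = .N), by = encounter_id]

  vars <- c(cohort$config$lab_panel$name, cohort$config$vital_panel$name, "coma_score")
  ev <- cohort$events
  unknown <- setdiff(unique(ev$variable_id), vars)
  if (length(unknown))
    stopf("build_features: unknown variable_id(s): %s", paste(unknown, collapse = ", "))

  ## per-window stats for continuous variables
  ev2 <- ev[, .(encounter_id, variable_id, value,
                period_index = pmin(as.integer(floor(time_hr / period_hours)),
                                    nper$n_per[match(encounter_id, nper$encounter_id)] - 1L))]
  st <- if (nrow(ev2))
    ev2[, .(min = min(value), max = max(value), mean = mean(value), n_events = .N),
        by = .(encounter_id, period_index, variable_id)]
  else data.table::data.table(encounter_id = integer(), period_index = integer(),
                              variable_id = character(), min = numeric(),
                              max = numeric(), mean = numeric(),
                              n_events = integer())
  base <- data.table::copy(per[, .(encounter_id, period_index)])
  for (s in c("min", "max", "mean")) {
    w <- if (nrow(st))
      data.table::dcast(st, encounter_id + period_index ~ variable_id, value.var = s)
    else data.table::data.table(encounter_id = integer(), period_index = integer())
    miss <- setdiff(vars, names(w))
    for (m in miss) w[, (m) := NA_real_]
    data.table::setcolorder(w, c("encounter_id", "period_index", vars))
    data.table::setnames(w, vars, paste0(vars, "__", s))
    base <- w[base, on = c("encounter_id", "period_index")]
  }

  ## medication exposure per window
  md <- cohort$medications
  cls <- cohort$config$med_classes$class_id
  if (nrow(md)) {
    unknown_cls <- setdiff(unique(md$class_id), cls)
    if (length(unknown_cls))
      stopf("build_features: unknown medication class(es): %s",
            paste(unknown_cls, collapse = ", "))
    np <- nper$n_per[match(md$encounter_id, nper$encounter_id)]
    first <- pmin(as.integer(floor(md$start_hr / period_hours)), np - 1L)
    last <- pmin(as.integer(floor((md$end_hr - 1e-9) / period_hours)), np - 1L)
    span <- last - first + 1L
    row <- rep(seq_len(nrow(md)), span)
    pidx <- first[row] + (sequence(span) - 1L)
    ov <- data.table::data.table(
      encounter_id = md$encounter_id[row], period_index = pidx, class_id = md$class_id[row],
      s = md$start_hr[row], e = md$end_hr[row])
    ov <- per[, .(encounter_id, period_index, p_start, p_end)][ov,
            on = c("encounter_id", "period_index")]
    ov[, overlap := pmax(pmin(e, p_end) - pmax(s, p_start), 0)]
    ov[, frac := overlap / (p_end - p_start)]
    magg <- ov[, .(frac = min(sum(frac), 1), n = .N),
               by = .(encounter_id, period_index, class_id)]
    wfrac <- data.table::dcast(magg, encounter_id + period_index ~ class_id,
                               value.var = "frac", fill = 0)
    wn <- data.table::dcast(magg, encounter_id + period_index ~ class_id,
                            value.var = "n", fill = 0)
  } else {
    wfrac <- data.table::data.table(encounter_id = integer(),
                                    period_index = integer())
    wn <- data.table::data.table(encounter_id = integer(),
                                 period_index = integer())
  }
  for (cid in setdiff(as.character(cls), names(wfrac))) {
    wfrac[, (cid) := 0]; wn[, (cid) := 0]
  }
  data.table::setcolorder(wfrac, c("encounter_id", "period_index", as.character(cls)))
  data.table::setcolorder(wn, c("encounter_id", "period_index", as.character(cls)))
  data.table::setnames(wfrac, as.character(cls), sprintf("med_%s__frac", cls))
  data.table::setnames(wn, as.character(cls), sprintf("med_%s__n", cls))
  base <- wfrac[base, on = c("encounter_id", "period_index")]
  base <- wn[base, on = c("encounter_id", "period_index")]
  medcols <- c(sprintf("med_%s__frac", cls), sprintf("med_%s__n", cls))
  for (mc in medcols) data.table::set(base, which(is.na(base[[mc]])), mc, 0)

  ## new-data flag: any raw event or medication start/stop in the window
  nd <- st[, .(n_events = sum(n_events)), by = .(encounter_id, period_index)]
  meta <- data.table::copy(per)
  meta[nd, on = c("encounter_id", "period_index"), new_data_flag := n_events > 0]
  meta[is.na(new_data_flag), new_data_flag := FALSE]
  if (nrow(md)) {
    np <- nper$n_per[match(md$encounter_id, nper$encounter_id)]
    mstart <- data.table::data.table(
      encounter_id = md$encounter_id,
      period_index = pmin(as.integer(floor(md$start_hr / period_hours)), np - 1L))
    mend <- data.table::data.table(
      encounter_id = md$encounter_id,
      period_index = pmin(as.integer(floor(md$end_hr / period_hours)), np - 1L))
    mboth <- unique(data.table::rbindlist(list(mstart, mend)))
    meta[mboth, on = c("encounter_id", "period_index"), new_data_flag := TRUE]
  }

  data.table::setkey(base, encounter_id, period_index)
  data.table::setkey(meta, encounter_id, period_index)
  structure(list(
    base = base, meta = meta, vars = vars, med_cols = medcols,
    stat_cols = paste0(rep(vars, each = 3), "__", c("min", "max", "mean")),
    lookback = as.integer(lookback), imputed = NULL,
    panels = list(lab = cohort$config$lab_panel, vital = cohort$config$vital_panel,
                  coma = cohort$config$coma)
  ), class = "ci_features")
}

#' Age-band imputation defaults for never-observed variables
#'
#' Returns the fallback value used when a laboratory/vital variable was
#' never observed in an encounter: the midpoint of the age band's normal
#' reference range (bands: `<12`, `12-59`, `>=60` months; the default
#' panels use one range across bands). The coma score defaults to the
#' normal maximum. Supplied as a named list so an alternative imputation
#' strategy can be dropped in.
#'
#' @param feats A `ci_features`.
#' @return Named numeric vector of defaults, one per variable, per band
#'   (matrix variables x bands).
#' @export
imputation_defaults <- function(feats) {
  pan <- rbind(feats$panels$lab[, .(name, normal_lo, normal_hi)],
               feats$panels$vital[, .(name, normal_lo, normal_hi)])
  mids <- c(stats::setNames((pan$normal_lo + pan$normal_hi) / 2, pan$name),
            coma_score = as.numeric(feats$panels$coma$max))
  bands <- c("age_lt_12m", "age_12_59m", "age_ge_60m")
  matrix(rep(mids, length(bands)), ncol = length(bands),
         dimnames = list(names(mids), bands))
}

#' Impute missing laboratory/vital features
#'
#' Last observation carried forward within the encounter (past information
#' only — no value ever flows backwards in time), then age-band normal
#' defaults for variables never observed in the encounter. Medication
#' exposure features are structurally zero when no administration overlaps
#' the window and are never imputed. The returned object records an
#' imputation mask alongside the completed values.
#'
#' @param feats A `ci_features` from [build_features()].
#' @param ages Optional `data.table(encounter_id, age_months)` used to pick
#'   the age band; when missing, the middle band is used.
#' @param defaults Defaults matrix as from [imputation_defaults()].
#' @return The `ci_features` with completed `base`, plus `base_mask`.
#' @export
impute_features <- function(feats, ages = NULL, defaults = imputation_defaults(feats)) {
  stopifnot(inherits(feats, "ci_features"))
  base <- data.table::copy(feats$base)
  cols <- feats$stat_cols
  enc <- base$encounter_id
  grp_start <- rep(match(unique(enc), enc), table(match(enc, unique(enc))))
  band <- rep("age_12_59m", nrow(base))
  if (!is.null(ages)) {
    a <- ages$age_months[match(enc, ages$encounter_id)]
    band <- ifelse(a < 12, "age_lt_12m", ifelse(a < 60, "age_12_59m", "age_ge_60m"))
  }
  mask <- matrix(FALSE, nrow(base), length(cols), dimnames = list(NULL, cols))
  for (j in seq_along(cols)) {
    v <- base[[cols[j]]]
    isna <- is.na(v)
    if (any(isna)) {
      filled <- locf_grouped(v, grp_start)
      still <- is.na(filled)
      if (any(still)) {
        var <- sub("__(min|max|mean)$", "", cols[j])
        filled[still] <- defaults[var, band[still]]
      }
      data.table::set(base, j = cols[j], value = filled)
      mask[, j] <- isna
    }
  }
  feats$base <- base
  feats$base_mask <- mask
  feats$imputed <- TRUE
  feats
}

# Vectorized last-observation-carried-forward that never crosses the group
# boundary given by grp_start (row index of each row's group start).
locf_grouped <- function(v, grp_start) {
  n <- length(v)
  has <- !is.na(v)
  cnt <- cumsum(has)
  src <- which(has)
  last_idx <- ifelse(cnt > 0, src[pmax(cnt, 1L)], NA_integer_)
  ok <- !is.na(last_idx) & last_idx >= grp_start
  out <- v
  fill <- which(is.na(v) & ok)
  out[fill] <- v[last_idx[fill]]
  out
}

#' Materialize the model feature matrix with lookback slots
#'
#' Expands the per-window summaries into the fixed-length model input: the
#' current window plus `lookback` preceding windows for every variable.
#' Lookback slots that precede admission repeat the admission-window value
#' and are flagged imputed. Column order and names are deterministic, so
#' two runs over the same configuration produce interchangeable schemas.
#'
#' @param feats An imputed `ci_features`.
#' @return A list: numeric matrix `X` (rows aligned with `meta`), logical
#'   `mask` of imputed entries, and the period metadata `meta`.
#' @export
feature_matrix <- function(feats) {
  stopifnot(inherits(feats, "ci_features"))
  if (!isTRUE(feats$imputed))
    stopf("feature_matrix: run impute_features() first")
  base <- feats$base
  cols <- c(feats$stat_cols, feats$med_cols)
  B <- as.matrix(base[, cols, with = FALSE])
  Bm <- matrix(FALSE, nrow(B), ncol(B), dimnames = list(NULL, cols))
  Bm[, feats$stat_cols] <- feats$base_mask[, feats$stat_cols]
  enc <- base$encounter_id
  first_row <- rep(match(unique(enc), enc), table(match(enc, unique(enc))))
  Lb <- feats$lookback
  out <- vector("list", Lb + 1L)
  msk <- vector("list", Lb + 1L)
  rows <- seq_len(nrow(B))
  for (l in 0:Lb) {
    shifted <- pmax(rows - l, first_row)
    pre_adm <- (rows - l) < first_row
    Xl <- B[shifted, , drop = FALSE]
    Ml <- Bm[shifted, , drop = FALSE]
    Ml[pre_adm, ] <- TRUE
    colnames(Xl) <- colnames(Ml) <- paste0(cols, "__lag", l)
    out[[l + 1L]] <- Xl
    msk[[l + 1L]] <- Ml
  }
  list(X = do.call(cbind, out), mask = do.call(cbind, msk), meta = feats$meta)
}
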