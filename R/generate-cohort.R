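#' Generate a synthetic inpatient cohort
#'
#' Simulates hospital admissions with a care-location trajectory (routine
#' ward / ICU segments), demographics, a latent hourly severity trace, and —
#' optionally — the observation streams (labs, vitals, coma scores,
#' medication administrations) that downstream models see. Severity follows
#' a discrete-time mean-reverting process; transfers happen when the
#' simulated trace actually crosses location-specific thresholds with
#' hysteresis (`icu_entry` on the way up, the lower `icu_exit` on the way
#' down), with per-patient drift rates calibrated so that expected crossing
#' times land on planned transfer times. All observables are functions of
#' the latent trace, current location and independent noise, so the latent
#' trace is an upper bound on what any observable-based model can recover.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param include_streams If `FALSE`, skip generation of observation and
#'   medication streams (much faster when only trajectories are needed).
#' @return An object of class `ci_cohort`: a list with `data.table`s
#'   `encounters`, `segments`, `events`, `medications`, `latent`, plus the
#'   `config` and `seed` used. Times in `segments`, `events`, `medications`
#'   and `latent` are hours since admission; `encounters` carries absolute
#'   admission timestamps.
#' @export
generate_cohort <- function(config, seed = config$seed, include_streams = TRUE) {
  stopifnot(inherits(config, "ci_cohort_config"))
  validate_cohort_config(config)
  with_seed(seed, generate_cohort_impl(config, seed, include_streams))
}

generate_cohort_impl <- function(cfg, seed, include_streams) {
  n <- cfg$n_admissions
  sv <- cfg$severity

  ## ---- admission types ------------------------------------------------
  direct <- runif(n) < cfg$p_direct_icu
  deteriorate <- !direct & (runif(n) < cfg$p_routine_to_icu)
  icu_out <- runif(n) < cfg$p_icu_to_routine  # drawn for all, used when ICU-ever

  s0 <- numeric(n)
  s0[direct] <- clamp(rnorm(sum(direct), sv$icu_mu, sv$sd0),
                      sv$icu_entry + 0.02, 0.97)
  s0[!direct] <- clamp(rnorm(sum(!direct), sv$routine_mu, sv$sd0),
                       0.03, sv$icu_exit - 0.02)

  # Persistent neurologic impairment: a patient-level coma-score offset
  # independent of systemic severity (chronic neuro disease, sedation needs).
  impaired <- runif(n) < cfg$coma$p_impaired
  coma_offset <- ifelse(impaired, runif(n, 1, cfg$coma$offset_max), 0)

  # Admission coma assessment: the ward coma floor is a practice rule that
  # forces admissions scoring below it into the ICU regardless of
  # physiology.
  s_adm <- s0 + rnorm(n, 0, 0.10)
  coma_adm <- clamp(round(cfg$coma$max - cfg$coma$slope * pmax(0, s_adm - cfg$coma$onset)
                          - coma_offset + rnorm(n, 0, cfg$coma$noise_sd)),
                    cfg$coma$min, cfg$coma$max)
  forced <- !direct & !deteriorate & (coma_adm < cfg$coma_icu_threshold)

  icu_ever_plan <- direct | deteriorate | forced

  ## ---- length of stay -------------------------------------------------
  los_days <- numeric(n)
  los_days[icu_ever_plan] <- rlnorm(sum(icu_ever_plan),
                                    cfg$los_days$icu$meanlog, cfg$los_days$icu$sdlog)
  los_days[!icu_ever_plan] <- rlnorm(sum(!icu_ever_plan),
                                     cfg$los_days$routine$meanlog, cfg$los_days$routine$sdlog)
  los_days <- clamp(los_days, cfg$los_days$min, cfg$los_days$max)
  L <- los_days * 24

  ## ---- planned transfer times and drift calibration -------------------
  # Each planned transfer is a hold-then-ramp: the patient holds at the phase
  # mean, then a short ramp (<= ramp_len hours) with a drift rate calibrated
  # to cross the relevant threshold at the planned time. The transfer itself
  # is still the emergent first crossing of the simulated trace.
  tf <- cfg$transfer_fracs
  theta0 <- sv$theta
  ramp_len <- 12
  mu <- numeric(n); th <- rep(theta0, n)
  loc <- as.integer(direct | forced)           # 1 = ICU
  tau1 <- rep(NA_real_, n)                     # planned first transfer
  tau2 <- rep(NA_real_, n)                     # planned ICU exit for returners
  sw_hr <- rep(NA_real_, n)                    # next scheduled ramp start
  sw_dir <- rep(NA_integer_, n)                # +1 ramp up to ICU, -1 ramp down

  d_out <- direct & icu_out
  d_stay <- direct & !icu_out
  mu[d_stay] <- sv$icu_mu
  mu[d_out] <- sv$icu_mu
  if (any(d_out)) {
    f <- clamp(rbeta(sum(d_out), tf$direct_icu_out[1], tf$direct_icu_out[2]), 0.15, 0.90)
    tau1[d_out] <- pmax(pmin(f * L[d_out], L[d_out] - 9), 2)
    sw_hr[d_out] <- pmax(ceiling(tau1[d_out]) - ramp_len, 1)
    sw_dir[d_out] <- -1L
  }
  # Practice-forced ICU admissions: physiology stays routine-like; the stay
  # in the ICU is rule-driven, so their transfer out (if any) is
  # time-triggered rather than severity-threshold-triggered.
  mu[forced] <- sv$routine_mu
  forced_exit <- rep(NA_real_, n)
  f_out <- forced & icu_out
  if (any(f_out)) {
    f <- clamp(rbeta(sum(f_out), tf$direct_icu_out[1], tf$direct_icu_out[2]), 0.15, 0.90)
    forced_exit[f_out] <- pmax(pmin(ceiling(f * L[f_out]), ceiling(L[f_out]) - 2), 1)
  }
  if (any(deteriorate)) {
    r <- clamp(rbeta(sum(deteriorate), tf$r2i_routine[1], tf$r2i_routine[2]), 0.05, 0.85)
    tau1[deteriorate] <- pmax(pmin(r * L[deteriorate], L[deteriorate] - 6), 2)
    mu[deteriorate] <- sv$routine_mu
    sw_hr[deteriorate] <- pmax(ceiling(tau1[deteriorate]) - ramp_len, 1)
    sw_dir[deteriorate] <- 1L
    g <- clamp(rbeta(sum(deteriorate), tf$r2i_return[1], tf$r2i_return[2]), 0.15, 0.90)
    tau2[deteriorate] <- ifelse(icu_out[deteriorate],
                                pmin(tau1[deteriorate] + g * (L[deteriorate] - tau1[deteriorate]),
                                     L[deteriorate] - 9), NA_real_)
    tau2[deteriorate] <- pmax(tau2[deteriorate], tau1[deteriorate] + 2)
  }
  stable <- !direct & !forced & !deteriorate
  mu[stable] <- sv$routine_mu

  ## ---- hourly simulation with emergent threshold crossings ------------
  H <- pmax(ceiling(L), 1L)                    # hours of trace per encounter
  Tmax <- max(H)
  S <- matrix(NA_real_, n, Tmax)
  S[, 1] <- s0
  sev <- s0
  transfers <- vector("list", 64L); n_tr <- 0L

  # Calibrate the ramp to sit slightly past the threshold at the deadline so
  # discharge censoring of planned transfers is negligible.
  ramp_theta <- function(from, level, target, hours) {
    over <- level + 0.06 * sign(target - level)
    ratio <- pmax((from - target) / (over - target), 1.05)
    clamp(log(ratio) / pmax(hours, 2), 1 / 2000, 0.95)
  }

  for (t in 2:Tmax) {
    hr <- t - 1                                # time of the new state
    # start scheduled ramps
    sw <- which(!is.na(sw_hr) & sw_hr == hr & H >= t)
    if (length(sw)) {
      up_sw <- sw[sw_dir[sw] == 1L]
      dn_sw <- sw[sw_dir[sw] == -1L]
      if (length(up_sw)) {
        mu[up_sw] <- sv$deteriorate_mu
        th[up_sw] <- ramp_theta(sev[up_sw], sv$icu_entry, sv$deteriorate_mu,
                                tau1[up_sw] - hr + 1)
      }
      if (length(dn_sw)) {
        dl <- ifelse(deteriorate[dn_sw], tau2[dn_sw], tau1[dn_sw])
        mu[dn_sw] <- sv$improve_mu
        th[dn_sw] <- ramp_theta(sev[dn_sw], sv$icu_exit, sv$improve_mu, dl - hr + 1)
      }
      sw_hr[sw] <- NA_real_
    }
    idx <- which(H >= t)
    if (!length(idx)) break
    nx <- sev[idx] + th[idx] * (mu[idx] - sev[idx]) +
      if (sv$vol > 0) rnorm(length(idx), 0, sv$vol) else 0
    nx <- clamp(nx, 0.02, 0.98)
    sev[idx] <- nx
    S[cbind(idx, t)] <- nx
    can <- idx[hr <= L[idx] - 1 & !forced[idx]] # no transfers in the final hour
    up <- can[loc[can] == 0L & sev[can] > sv$icu_entry]
    dn <- can[loc[can] == 1L & sev[can] < sv$icu_exit]
    fx <- idx[forced[idx] & !is.na(forced_exit[idx]) & forced_exit[idx] == hr]
    if (length(fx)) {
      loc[fx] <- 0L
      n_tr <- n_tr + 1L
      transfers[[n_tr]] <- data.table::data.table(encounter_id = fx, time_hr = hr,
                                                  to = "routine")
    }
    if (length(up)) {
      loc[up] <- 1L
      n_tr <- n_tr + 1L
      transfers[[n_tr]] <- data.table::data.table(encounter_id = up, time_hr = hr,
                                                  to = "ICU")
      ret <- up[deteriorate[up] & icu_out[up]]
      hold <- setdiff(up[deteriorate[up]], ret)
      other <- up[!deteriorate[up]]            # emergent crossing of a stable patient
      if (length(ret)) {
        # hold in the ICU, then schedule the ramp back down
        mu[ret] <- sv$icu_mu; th[ret] <- theta0
        sw_hr[ret] <- pmax(ceiling(tau2[ret]) - ramp_len, hr + 1)
        sw_dir[ret] <- -1L
      }
      if (length(hold)) { mu[hold] <- sv$icu_mu; th[hold] <- theta0 }
      if (length(other)) { th[other] <- theta0 }  # mean stays low; they revert
    }
    if (length(dn)) {
      loc[dn] <- 0L
      n_tr <- n_tr + 1L
      transfers[[n_tr]] <- data.table::data.table(encounter_id = dn, time_hr = hr,
                                                  to = "routine")
      mu[dn] <- sv$routine_mu; th[dn] <- theta0
      sw_hr[dn] <- NA_real_
    }
    if (n_tr >= length(transfers))
      transfers <- c(transfers, vector("list", length(transfers)))
  }

  transfers <- if (n_tr) data.table::rbindlist(transfers[seq_len(n_tr)])
  else data.table::data.table(encounter_id = integer(), time_hr = numeric(),
                              to = character())

  ## ---- segments -------------------------------------------------------
  init_loc <- ifelse(direct | forced, "ICU", "routine")
  segments <- build_segments(n, init_loc, transfers, L)

  ## ---- encounters -----------------------------------------------------
  base_time <- as.POSIXct("2018-01-01 00:00:00", tz = "UTC")
  admit <- base_time + round(runif(n, 0, 760 * 86400))
  race <- names(cfg$race_probs)[
    max.col(t(rmultinom(n, 1L, cfg$race_probs)), ties.method = "first")]
  encounters <- data.table::data.table(
    encounter_id = seq_len(n),
    age_months = clamp(rlnorm(n, cfg$age_months$meanlog, cfg$age_months$sdlog),
                       0.5, cfg$age_months$max),
    sex = ifelse(runif(n) < cfg$sex_female, "F", "M"),
    race_category = race,
    admit_time = admit,
    discharge_time = admit + round(L * 3600),
    los_hours = L,
    chronic_neuro = impaired,
    admission_type = ifelse(direct, "direct_icu",
                            ifelse(forced, "coma_forced_icu",
                                   ifelse(deteriorate, "routine_deteriorate",
                                          "routine_stable")))
  )

  ## ---- latent trace (oracle only) -------------------------------------
  hr_idx <- sequence(H) - 1L
  enc_idx <- rep(seq_len(n), H)
  latent <- data.table::data.table(
    encounter_id = enc_idx, hour = hr_idx,
    severity = S[cbind(enc_idx, hr_idx + 1L)]
  )
  latent[, location := lookup_location(segments, encounter_id, hour + 1e-9)]

  events <- data.table::data.table(encounter_id = integer(), time_hr = numeric(),
                                   kind = character(), variable_id = character(),
                                   value = numeric())
  medications <- data.table::data.table(encounter_id = integer(), class_id = integer(),
                                        start_hr = numeric(), end_hr = numeric())
  if (include_streams) {
    streams <- generate_streams(cfg, latent, segments, L, coma_offset)
    events <- streams$events
    medications <- streams$medications
  }

  structure(list(encounters = encounters, segments = segments, events = events,
                 medications = medications, latent = latent,
                 config = cfg, seed = seed),
            class = "ci_cohort")
}

# Assemble alternating location segments from initial locations and the
# recorded transfer times. Segments are half-open [start_hr, end_hr) and
# cover [0, los_hours) exactly.
build_segments <- function(n, init_loc, transfers, L) {
  if (nrow(transfers)) {
    data.table::setorder(transfers, encounter_id, time_hr)
    tr_by_enc <- split(transfers, by = "encounter_id")
  } else tr_by_enc <- list()
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- tr_by_enc[[as.character(i)]]
    if (is.null(tr)) {
      segs[[i]] <- data.table::data.table(encounter_id = i, location = init_loc[i],
                                          start_hr = 0, end_hr = L[i])
    } else {
      starts <- c(0, tr$time_hr)
      ends <- c(tr$time_hr, L[i])
      locs <- c(init_loc[i], tr$to)
      keep <- ends > starts
      segs[[i]] <- data.table::data.table(encounter_id = i, location = locs[keep],
                                          start_hr = starts[keep], end_hr = ends[keep])
    }
  }
  out <- data.table::rbindlist(segs)
  data.table::setorder(out, encounter_id, start_hr)
  out
}

# Vectorized location lookup at given times (hours since admission).
lookup_location <- function(segments, enc, time_hr) {
  q <- data.table::data.table(encounter_id = enc, t = time_hr,
                              ord = seq_along(enc))
  s <- segments[, .(encounter_id, start_hr, location)]
  data.table::setkey(s, encounter_id, start_hr)
  q[, start_hr := t]
  res <- s[q, on = c("encounter_id", "start_hr"), roll = TRUE]
  res[order(res$ord)]$location
}

generate_streams <- function(cfg, latent, segments, L, coma_offset = NULL) {
  if (is.null(coma_offset)) coma_offset <- numeric(length(L))
  sv <- cfg$severity
  n <- length(L)
  hourly <- latent
  is_icu <- hourly$location == "ICU"
  n_h <- nrow(hourly)
  # event timestamps stay inside the encounter, including partial last hours
  hrs_per_enc <- hourly[, .N, by = encounter_id]$N
  max_in_hour <- pmin(1, rep(L, hrs_per_enc) - hourly$hour)

  # Observations arrive in rounds: one draw decides whether the panel is
  # sampled in that hour (a vitals set, a lab draw); labs then include each
  # analyte with probability `p_within` (not every draw is the full panel).
  sample_panel <- function(panel, kind, p_within = 1) {
    rate <- ifelse(is_icu, panel$rate_icu[1], panel$rate_routine[1])
    round_rows <- which(runif(n_h) < rate)
    out <- vector("list", nrow(panel))
    for (j in seq_len(nrow(panel))) {
      p <- panel[j]
      pick <- if (p_within < 1)
        round_rows[runif(length(round_rows)) < p_within] else round_rows
      if (!length(pick)) { out[[j]] <- NULL; next }
      span <- p$normal_hi - p$normal_lo
      mid <- (p$normal_hi + p$normal_lo) / 2
      val <- mid + p$direction * span * 0.9 * (hourly$severity[pick] - 0.35) +
        rnorm(length(pick), 0, p$noise_frac * span)
      out[[j]] <- data.table::data.table(
        encounter_id = hourly$encounter_id[pick],
        time_hr = hourly$hour[pick] + runif(length(pick)) * max_in_hour[pick],
        kind = kind, variable_id = p$name,
        value = clamp(val, p$plaus_lo, p$plaus_hi))
    }
    data.table::rbindlist(out)
  }

  labs <- sample_panel(cfg$lab_panel, "lab", p_within = 0.7)
  vitals <- sample_panel(cfg$vital_panel, "vital")

  cm <- cfg$coma
  rate <- ifelse(is_icu, cm$rate_icu, cm$rate_routine)
  pick <- which(runif(n_h) < rate)
  coma <- data.table::data.table(
    encounter_id = hourly$encounter_id[pick],
    time_hr = hourly$hour[pick] + runif(length(pick)) * max_in_hour[pick],
    kind = "coma_score", variable_id = "coma_score",
    value = clamp(round(cm$max - cm$slope * pmax(0, hourly$severity[pick] - cm$onset)
                        - coma_offset[hourly$encounter_id[pick]]
                        + rnorm(length(pick), 0, cm$noise_sd)), cm$min, cm$max))

  events <- data.table::rbindlist(list(labs, vitals, coma))
  data.table::setorder(events, encounter_id, time_hr)

  ## medication administrations: Poisson starts per (segment x class)
  seg <- data.table::copy(segments)
  seg[, `:=`(seg_id = .I, dur = end_hr - start_hr)]
  sev_mean <- latent[, .(mean_sev = mean(severity)), by = encounter_id]
  seg <- merge(seg, sev_mean, by = "encounter_id", sort = FALSE)
  md <- cfg$med_classes
  n_cls <- nrow(md)
  reps <- rep(seq_len(nrow(seg)), each = n_cls)
  grid_rate <- ifelse(rep(seg$location == "ICU", each = n_cls),
                      md$rate_icu[rep(seq_len(n_cls), nrow(seg))],
                      md$rate_routine[rep(seq_len(n_cls), nrow(seg))])
  gain <- md$severity_gain[rep(seq_len(n_cls), nrow(seg))]
  lam <- grid_rate * (1 + gain * seg$mean_sev[reps]) * seg$dur[reps]
  n_adm <- rpois(length(lam), lam)
  has <- which(n_adm > 0L)
  if (length(has)) {
    tot <- n_adm[has]
    row <- rep(has, tot)
    seg_row <- reps[row]
    cls <- rep(seq_len(n_cls), nrow(seg))[row]
    start <- seg$start_hr[seg_row] + runif(length(row)) * seg$dur[seg_row]
    dur <- rlnorm(length(row), md$dur_meanlog[cls], md$dur_sdlog[cls])
    medications <- data.table::data.table(
      encounter_id = seg$encounter_id[seg_row],
      class_id = md$class_id[cls],
      start_hr = start,
      end_hr = pmin(start + dur, L[seg$encounter_id[seg_row]]))
    medications <- medications[end_hr > start_hr]
    data.table::setorder(medications, encounter_id, class_id, start_hr)
  } else {
    medications <- data.table::data.table(encounter_id = integer(),
                                          class_id = integer(),
                                          start_hr = numeric(), end_hr = numeric())
  }
  list(events = events, medications = medications)
}

#' @export
print.ci_cohort <- function(x, ...) {
  cat("<ci_cohort>\n")
  cat(sprintf("  %d encounters, %d segments, %d observation events, %d medication administrations\n",
              nrow(x$encounters), nrow(x$segments), nrow(x$events), nrow(x$medications)))
  s <- cohort_summary(x)
  cat(sprintf("  direct ICU %.1f%% | routine->ICU %.1f%% | ICU->routine %.1f%% of ICU admissions\n",
              100 * s$frac_direct_icu, 100 * s$frac_routine_to_icu,
              100 * s$frac_icu_to_routine))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Realized admission-path fractions of a cohort
#'
#' @param cohort A `ci_cohort`.
#' @return A list with the realized fraction of direct-to-ICU admissions,
#'   the fraction of routine admissions later transferred to the ICU, and
#'   the fraction of ICU admissions later transferred to routine care.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "ci_cohort"))
  seg <- cohort$segments
  first <- seg[, .SD[1], by = encounter_id]
  direct <- first$location == "ICU"
  icu_ever <- seg[, any(location == "ICU"), by = encounter_id]$V1
  r2i <- seg[, any(location == "ICU" & start_hr > 0 &
                     data.table::shift(location) == "routine", na.rm = TRUE),
             by = encounter_id]$V1
  i2r <- seg[, any(location == "routine" & start_hr > 0 &
                     data.table::shift(location) == "ICU", na.rm = TRUE),
             by = encounter_id]$V1
  list(
    n = nrow(first),
    frac_direct_icu = mean(direct),
    frac_routine_to_icu = mean(r2i[!direct]),
    frac_icu_to_routine = mean(i2r[icu_ever]),
    frac_icu_ever = mean(icu_ever)
  )
}
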