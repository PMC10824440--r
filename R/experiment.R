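#' Prepare a cohort for modeling
#'
#' Runs the full episode-processing chain: 6-hour discretization, horizon
#' labeling, feature building with lookback, leakage-free imputation, and
#' a patient-level train/validation/test split.
#'
#' @param cohort A `ci_cohort`.
#' @param lookback Lookback windows (default 4).
#' @param fractions Split fractions (default 75/13/12).
#' @param seed Split seed.
#' @return An object of class `ci_site_data`: feature matrix `X`, period
#'   metadata `meta` (care label, horizon outcomes `H1..H4`,
#'   `new_data_flag`, `partition`), imputation `mask`, and the `cohort`.
#' @export
prepare_site <- function(cohort, lookback = 4L,
                         fractions = c(train = 0.75, validation = 0.13, test = 0.12),
                         seed = 1L) {
  per <- label_horizons(discretize_periods(cohort))
  f <- build_features(per, cohort, lookback = lookback)
  f <- impute_features(f, ages = cohort$encounters[, .(encounter_id, age_months)])
  fm <- feature_matrix(f)
  sp <- split_patients(cohort$encounters$encounter_id, fractions, seed = seed)
  fm$meta[, partition := sp$partition[match(encounter_id, sp$patient_id)]]
  structure(list(X = fm$X, mask = fm$mask, meta = fm$meta, cohort = cohort),
            class = "ci_site_data")
}

#' @export
print.ci_site_data <- function(x, ...) {
  cat(sprintf("<ci_site_data> %d periods x %d features (%d encounters)\n",
              nrow(x$X), ncol(x$X), length(unique(x$meta$encounter_id))))
  print(table(x$meta$partition))
  invisible(x)
}

# Rows usable for modeling a horizon: non-transition, gated on new data,
# defined outcome.
model_rows <- function(site, horizon, partition = NULL) {
  hcol <- paste0("H", horizon)
  keep <- site$meta$care_label != "transition" & site$meta$new_data_flag &
    !is.na(site$meta[[hcol]])
  if (!is.null(partition)) keep <- keep & site$meta$partition %in% partition
  which(keep)
}

#' Train calibrated models for all four horizons at one site
#'
#' For each horizon: trains the classifier under the growth protocol on
#' the training partition, then fits the B-spline logistic calibration map
#' on the validation partition's raw scores.
#'
#' @param site A `ci_site_data`.
#' @param protocol A [ci_protocol()].
#' @param horizons Horizon indices (default 1:4).
#' @return An object of class `ci_model_set`: per-horizon
#'   `ci_horizon_model`s and `ci_calibration_map`s.
#' @export
train_site_models <- function(site, protocol = ci_protocol(), horizons = 1:4) {
  models <- list(); maps <- list()
  for (j in horizons) {
    hcol <- paste0("H", j)
    tr <- model_rows(site, j, "train")
    va <- model_rows(site, j, "validation")
    pj <- protocol; pj$seed <- child_seed(protocol$seed, paste0("H", j))
    m <- train_horizon_model(site$X[tr, , drop = FALSE], site$meta[[hcol]][tr],
                             site$X[va, , drop = FALSE], site$meta[[hcol]][va],
                             pj, horizon = j)
    raw_val <- predict_raw(m, site$X[va, , drop = FALSE])
    maps[[paste0("H", j)]] <- fit_calibration(raw_val, site$meta[[hcol]][va])
    models[[paste0("H", j)]] <- m
  }
  structure(list(models = models, maps = maps, horizons = horizons),
            class = "ci_model_set")
}

#' @export
print.ci_model_set <- function(x, ...) {
  cat(sprintf("<ci_model_set> horizons: %s\n",
              paste(names(x$models), collapse = ", ")))
  for (nm in names(x$models))
    cat(sprintf("  %s: hidden %s, val MCC %.3f\n", nm,
                paste(x$models[[nm]]$hidden, collapse = "-"),
                x$models[[nm]]$val_mcc))
  invisible(x)
}

#' Evaluate a model set on a site's partition
#'
#' The full evaluation suite on (by default) the test partition:
#' AUROC/AUPRC with confidence intervals, the threshold-0.5 operating
#' point, fixed-sensitivity operating points (0.85/0.90/0.95/0.99) with
#' NNE, a calibration audit on calibrated risks (when enough records), and
#' transfer-cohort accuracy in both directions at fixed sensitivity
#' (routine to ICU) and fixed specificity (ICU to routine).
#'
#' @param model_set A `ci_model_set` (possibly trained at another site).
#' @param site The `ci_site_data` to evaluate on.
#' @param partition Partition name(s), default `"test"`.
#' @param sens_targets Fixed sensitivities for the threshold analysis.
#' @param transfer_sens,transfer_spec Operating targets for the transfer
#'   cohort (default 0.95 each).
#' @param min_interval_n Calibration-audit interval size (default 200).
#' @return An object of class `ci_evaluation`.
#' @export
evaluate_models <- function(model_set, site, partition = "test",
                            sens_targets = c(0.85, 0.90, 0.95, 0.99),
                            transfer_sens = 0.95, transfer_spec = 0.95,
                            min_interval_n = 200L) {
  stopifnot(inherits(model_set, "ci_model_set"), inherits(site, "ci_site_data"))
  res <- list(); disc <- list(); ops <- list(); audits <- list()
  scores_all <- list(); risks_all <- list()
  thr_sens <- c(); thr_spec <- c()
  for (j in model_set$horizons) {
    hn <- paste0("H", j)
    rows <- model_rows(site, j, partition)
    y <- site$meta[[hn]][rows]
    raw <- predict_raw(model_set$models[[hn]], site$X[rows, , drop = FALSE])
    risk <- calibrate_scores(model_set$maps[[hn]], raw)
    roc <- roc_auc(risk, y)
    pr <- pr_auc(risk, y)
    disc[[hn]] <- data.table::data.table(
      horizon = hn, n = length(y), prevalence = mean(y),
      auroc = roc$auc, auroc_lo = roc$ci[1], auroc_hi = roc$ci[2],
      auprc = pr$area, auprc_lo = pr$ci[1], auprc_hi = pr$ci[2])
    op5 <- metrics_at_threshold(risk, y, 0.5)
    tab <- lapply(sens_targets, function(tg) {
      op <- threshold_for_sensitivity(risk, y, tg)
      data.table::data.table(horizon = hn, target_sensitivity = tg,
                             threshold = op$threshold,
                             sensitivity = op$sensitivity, precision = op$precision,
                             accuracy = op$accuracy, specificity = op$specificity,
                             npv = op$npv, f1 = op$f1, nne = op$nne)
    })
    ops[[hn]] <- data.table::rbindlist(tab)
    audits[[hn]] <- if (length(y) >= 2L * min_interval_n)
      audit_calibration(risk, y, min_interval_n) else NULL
    # per-period-row score vectors for the transfer analysis
    sc <- rep(NA_real_, nrow(site$X))
    rk <- rep(NA_real_, nrow(site$X))
    sc[rows] <- raw; rk[rows] <- risk
    scores_all[[hn]] <- rk
    thr_sens[hn] <- threshold_for_sensitivity(risk, y, transfer_sens)$threshold
    thr_spec[hn] <- threshold_for_specificity(risk, y, transfer_spec)$threshold
    res[[hn]] <- list(op_05 = op5)
  }
  # align score vectors with pmeta rows
  sel <- which(site$meta[["partition"]] %in% partition)
  pmeta <- site$meta[sel]
  scores_part <- lapply(scores_all, function(v) v[sel])
  tacc_r2i <- suppressWarnings(transfer_accuracy(
    scores_part, pmeta, site$cohort$segments[encounter_id %in% pmeta$encounter_id],
    "routine_to_icu", thr_sens))
  tacc_i2r <- suppressWarnings(transfer_accuracy(
    scores_part, pmeta, site$cohort$segments[encounter_id %in% pmeta$encounter_id],
    "icu_to_routine", thr_spec))
  structure(list(
    discrimination = data.table::rbindlist(disc),
    operating_points_05 = lapply(res, `[[`, "op_05"),
    threshold_table = data.table::rbindlist(ops),
    audits = audits,
    transfer = data.table::rbindlist(list(tacc_r2i, tacc_i2r)),
    partition = partition
  ), class = "ci_evaluation")
}

#' @export
print.ci_evaluation <- function(x, ...) {
  cat(sprintf("<ci_evaluation> partition: %s\n", paste(x$partition, collapse = "+")))
  print(x$discrimination[, .(horizon, n, auroc = round(auroc, 3),
                             auprc = round(auprc, 3))])
  invisible(x)
}

#' Configuration of the two-site experiment
#'
#' @param cohort Reference-site [cohort_config()].
#' @param shift A [site_shift()] applied to the local site.
#' @param protocol Training [ci_protocol()].
#' @param lookback Lookback windows.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param importance Local-importance settings: `horizons`, `risk_band`,
#'   `top_k`, `n_perturbations`, `max_cases`, or `NULL` to skip.
#' @param min_interval_n Calibration audit interval size.
#' @return A list of class `ci_experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(n_admissions = 2000L),
                              shift = default_site_shift(cohort$med_classes),
                              protocol = ci_protocol_desk(),
                              lookback = 4L, seed = 1L,
                              importance = list(horizons = 1L,
                                                risk_band = c(0.245, 0.255),
                                                top_k = 30L,
                                                n_perturbations = 300L,
                                                max_cases = 40L),
                              min_interval_n = 200L) {
  structure(list(cohort = cohort, shift = shift, protocol = protocol,
                 lookback = as.integer(lookback), seed = as.integer(seed),
                 importance = importance, min_interval_n = min_interval_n),
            class = "ci_experiment_config")
}

#' Run the two-site experiment
#'
#' The package's headline pipeline: generate a reference site and a
#' practice-shifted local site, prepare both, train a model set on each,
#' apply the reference models to the local test data (the transported-model
#' arm), train and evaluate local models on the same test data (the
#' locally-redeveloped arm), audit calibration, and compare local covariate
#' importance between the two model sets inside a fixed risk band. With a
#' zero shift the two sites are draws from the same distribution and the
#' two arms should perform indistinguishably.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, metric tables and a run
#'   manifest (with file digests and seeds) are written there.
#' @return An object of class `ci_experiment` with both evaluations, the
#'   model sets, the importance comparison and the manifest.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "ci_experiment_config"))
  pair <- make_site_pair(config$cohort, config$shift)
  seed_ref <- child_seed(config$seed, "reference-cohort")
  seed_loc <- child_seed(config$seed, "local-cohort")
  ref_cohort <- generate_cohort(pair$reference, seed = seed_ref)
  loc_cohort <- generate_cohort(pair$local, seed = seed_loc)
  ref_site <- prepare_site(ref_cohort, lookback = config$lookback,
                           seed = child_seed(config$seed, "split-ref"))
  loc_site <- prepare_site(loc_cohort, lookback = config$lookback,
                           seed = child_seed(config$seed, "split-loc"))
  p_ref <- config$protocol; p_ref$seed <- child_seed(config$seed, "train-ref")
  p_loc <- config$protocol; p_loc$seed <- child_seed(config$seed, "train-loc")
  ref_models <- train_site_models(ref_site, p_ref)
  loc_models <- train_site_models(loc_site, p_loc)
  eval_ref_on_local <- evaluate_models(ref_models, loc_site,
                                       min_interval_n = config$min_interval_n)
  eval_local <- evaluate_models(loc_models, loc_site,
                                min_interval_n = config$min_interval_n)

  importance <- NULL
  if (!is.null(config$importance)) {
    imp <- config$importance
    importance <- list()
    for (j in imp$horizons) {
      hn <- paste0("H", j)
      rows <- model_rows(loc_site, j, "test")
      Xt <- loc_site$X[rows, , drop = FALSE]
      fsd <- apply(loc_site$X[model_rows(loc_site, j, "train"), , drop = FALSE], 2L, sd)
      risks_of <- function(ms)
        calibrate_scores(ms$maps[[hn]], predict_raw(ms$models[[hn]], Xt))
      rk_ref <- risks_of(ref_models); rk_loc <- risks_of(loc_models)
      # the published band is narrow; at desk scale the risk distribution can
      # leave it unpopulated, so widen symmetrically until both model sets
      # have enough cases, and record the band actually used
      ctr <- mean(imp$risk_band); hw <- diff(imp$risk_band) / 2
      band <- imp$risk_band
      repeat {
        band <- c(max(0, ctr - hw), min(1, ctr + hw))
        n_in <- min(sum(rk_ref >= band[1] & rk_ref <= band[2]),
                    sum(rk_loc >= band[1] & rk_loc <= band[2]))
        if (n_in >= min(10L, imp$max_cases) || hw >= 0.25) break
        hw <- hw * 2
      }
      # covariates = variable x summary, pooled over lookback slots
      cov_groups <- stats::setNames(sub("__lag\\d+$", "", colnames(Xt)),
                                    colnames(Xt))
      prof <- function(ms, rk) {
        importance_frequency(
          function(M) calibrate_scores(ms$maps[[hn]], predict_raw(ms$models[[hn]], M)),
          Xt, rk, fsd, risk_band = band, top_k = imp$top_k,
          n_perturbations = imp$n_perturbations,
          seed = child_seed(config$seed, paste0("lime", j)),
          max_cases = imp$max_cases, groups = cov_groups)
      }
      pr_ref <- try(prof(ref_models, rk_ref), silent = TRUE)
      pr_loc <- try(prof(loc_models, rk_loc), silent = TRUE)
      importance[[hn]] <- if (inherits(pr_ref, "try-error") ||
                              inherits(pr_loc, "try-error"))
        list(error = "no records in risk band")
      else c(compare_profiles(pr_ref, pr_loc),
             list(profile_reference = pr_ref, profile_local = pr_loc,
                  risk_band_used = band))
    }
  }

  manifest <- list(seed = config$seed,
                   seeds = list(reference_cohort = seed_ref, local_cohort = seed_loc),
                   n_admissions_per_site = config$cohort$n_admissions,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  result <- structure(list(
    reference_on_local = eval_ref_on_local,
    local_on_local = eval_local,
    reference_models = ref_models, local_models = loc_models,
    importance = importance,
    sites = list(reference = ref_site, local = loc_site),
    manifest = manifest, config = config
  ), class = "ci_experiment")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(eval_ref_on_local$discrimination,
                       file.path(out_dir, "discrimination_reference_on_local.csv"))
    data.table::fwrite(eval_local$discrimination,
                       file.path(out_dir, "discrimination_local.csv"))
    data.table::fwrite(eval_local$threshold_table,
                       file.path(out_dir, "threshold_table_local.csv"))
    data.table::fwrite(eval_local$transfer,
                       file.path(out_dir, "transfer_accuracy_local.csv"))
    for (hn in names(eval_local$audits)) if (!is.null(eval_local$audits[[hn]]))
      data.table::fwrite(eval_local$audits[[hn]]$intervals,
                         file.path(out_dir, sprintf("calibration_intervals_%s.csv", hn)))
    if (!is.null(importance)) for (hn in names(importance))
      if (!is.null(importance[[hn]]$table))
        data.table::fwrite(importance[[hn]]$table,
                           file.path(out_dir, sprintf("importance_comparison_%s.csv", hn)))
    files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$files <- as.list(stats::setNames(unname(tools::md5sum(files)),
                                              basename(files)))
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
    result$manifest <- manifest
  }
  result
}

#' @export
print.ci_experiment <- function(x, ...) {
  cat("<ci_experiment>\n")
  a <- x$reference_on_local$discrimination
  b <- x$local_on_local$discrimination
  cmp <- merge(a[, .(horizon, auroc_reference = auroc)],
               b[, .(horizon, auroc_local = auroc)], by = "horizon")
  print(cmp[, lapply(.SD, function(v) if (is.numeric(v)) round(v, 3) else v)])
  invisible(x)
}
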