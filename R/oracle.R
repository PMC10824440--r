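#' Latent-severity oracle scores for a horizon
#'
#' A predictor with direct access to the generator's latent severity trace
#' (which is never exposed to models): a logistic fit of the horizon
#' outcome on the period-mean latent severity and the current care
#' location. Because every observable is generated from the latent trace,
#' current location and independent noise, this oracle's discrimination
#' upper-bounds (up to sampling noise) what any observable-based model can
#' achieve — a data-processing check used in tests.
#'
#' @param cohort The `ci_cohort` (must retain `latent`).
#' @param periods Labeled periods from [label_horizons()].
#' @param horizon Horizon index 1..4.
#' @return A list with `scores`, `outcomes` and the row filter used
#'   (non-transition periods with a defined outcome).
#' @export
latent_oracle_scores <- function(cohort, periods, horizon = 1L) {
  stopifnot(inherits(cohort, "ci_cohort"), nrow(cohort$latent) > 0)
  hcol <- paste0("H", horizon)
  if (!hcol %in% names(periods))
    stopf("latent_oracle_scores: periods lack column %s; run label_horizons()", hcol)
  sev <- cohort$latent[, .(sev_mean = mean(severity)),
                       by = .(encounter_id, period_index = as.integer(floor(hour / 6)))]
  per <- merge(periods, sev, by = c("encounter_id", "period_index"), all.x = TRUE)
  keep <- per$care_label != "transition" & !is.na(per[[hcol]]) & !is.na(per$sev_mean)
  d <- per[keep]
  y <- d[[hcol]]
  fit <- glm(y ~ sev_mean + I(care_label == "ICU"), data = d, family = binomial())
  list(scores = unname(predict(fit, type = "response")), outcomes = y, keep = keep)
}
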