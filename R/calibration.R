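#' Fit a B-spline logistic calibration map
#'
#' Maps raw classifier scores to calibrated ICU risk by logistic regression
#' on a cubic B-spline basis of the raw score. Interior knots sit at
#' empirical quantiles of the fitting scores (5 knots by default); raw
#' scores outside the fitting range are clamped to the boundary knots, so
#' the map is defined on all of (0, 1). The map is not constrained to be
#' monotone; with enough data and a well-ordered score it is in practice.
#' Fit this on the validation partition only — never on test outcomes.
#'
#' @param raw_scores Raw scores in (0, 1) (validation partition).
#' @param outcomes 0/1 outcomes aligned with `raw_scores`.
#' @param knots Number of interior knots (default 5).
#' @param degree Spline degree (default 3, cubic).
#' @return An object of class `ci_calibration_map`.
#' @export
fit_calibration <- function(raw_scores, outcomes, knots = 5L, degree = 3L) {
  if (length(unique(outcomes)) < 2L)
    stopf("fit_calibration: both outcome classes required")
  rng <- range(raw_scores)
  if (diff(rng) < 1e-8)
    stopf("fit_calibration: raw scores are (near-)constant; nothing to calibrate")
  kq <- unique(quantile(raw_scores, probs = seq_len(knots) / (knots + 1), names = FALSE))
  kq <- kq[kq > rng[1] & kq < rng[2]]
  basis <- splines::bs(raw_scores, knots = kq, degree = degree,
                       Boundary.knots = rng)
  df <- data.frame(y = outcomes, basis)
  fit <- glm(y ~ ., data = df, family = binomial())
  structure(list(knots = kq, degree = degree, boundary = rng,
                 coef = coef(fit), converged = fit$converged),
            class = "ci_calibration_map")
}

#' Apply a calibration map to raw scores
#'
#' @param map A `ci_calibration_map`.
#' @param raw_scores Raw scores; values outside the fitted range are
#'   clamped to the boundary knots.
#' @return Calibrated risks in `[0, 1]`.
#' @export
calibrate_scores <- function(map, raw_scores) {
  stopifnot(inherits(map, "ci_calibration_map"))
  x <- clamp(raw_scores, map$boundary[1], map$boundary[2])
  basis <- splines::bs(x, knots = map$knots, degree = map$degree,
                       Boundary.knots = map$boundary)
  eta <- drop(cbind(1, basis) %*% map$coef)
  plogis(eta)
}

#' @export
print.ci_calibration_map <- function(x, ...) {
  cat(sprintf("<ci_calibration_map> degree %d, %d interior knots on [%.3f, %.3f]\n",
              x$degree, length(x$knots), x$boundary[1], x$boundary[2]))
  invisible(x)
}

#' Cohen's h effect size for two proportions
#'
#' `h = |2 asin(sqrt(p1)) - 2 asin(sqrt(p2))|`. Values below 0.2 are
#' conventionally negligible ("small") differences.
#'
#' @param p1,p2 Proportions in `[0, 1]` (vectorized).
#' @return Non-negative effect size(s); `h(1, 0) = pi`.
#' @export
cohens_h <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stopf("cohens_h: proportions must lie in [0, 1]")
  abs(2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2)))
}

#' Audit calibration over ordered risk intervals
#'
#' Sorts records by calibrated risk and forms equal-count intervals of
#' exactly `min_interval_n` records (the last interval absorbs the
#' remainder). Per interval: expected proportion = mean calibrated risk,
#' observed proportion = outcome rate, a two-proportion comparison (exact
#' binomial test of the observed count against the expected proportion)
#' and Cohen's h. The summary regresses expected on observed proportions;
#' optimal calibration has intercept 0, slope 1, R-squared 1, at most 5 %
#' of intervals significant at p < 0.05, and h < 0.2 throughout.
#'
#' @param calibrated_risks Calibrated risks in `[0, 1]`.
#' @param outcomes 0/1 outcomes.
#' @param min_interval_n Minimum records per risk interval (default 200).
#' @return An object of class `ci_calibration_audit`: interval table plus
#'   summary statistics.
#' @export
audit_calibration <- function(calibrated_risks, outcomes, min_interval_n = 200L) {
  n <- length(calibrated_risks)
  if (n < 2L * min_interval_n)
    stopf("audit_calibration: need at least %d records (2 x min_interval_n), got %d",
          2L * min_interval_n, n)
  o <- order(calibrated_risks)
  r <- calibrated_risks[o]; y <- outcomes[o]
  n_int <- n %/% min_interval_n
  sizes <- rep(min_interval_n, n_int)
  sizes[n_int] <- sizes[n_int] + n %% min_interval_n
  idx <- rep(seq_len(n_int), sizes)
  tab <- data.table::data.table(interval = idx, risk = r, y = y)[
    , .(n = .N, expected = mean(risk), observed = mean(y), events = sum(y)),
    by = interval]
  tab[, p_value := mapply(function(x, n, p) {
    p <- clamp(p, 1e-12, 1 - 1e-12)
    binom.test(x, n, p)$p.value
  }, events, n, expected)]
  tab[, cohens_h := cohens_h(observed, expected)]
  fit <- lm(expected ~ observed, data = tab)
  structure(list(
    intervals = tab[],
    n = n, n_intervals = n_int,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    pct_h_lt_0.2 = 100 * mean(tab$cohens_h < 0.2),
    pct_significant = 100 * mean(tab$p_value < 0.05)
  ), class = "ci_calibration_audit")
}

#' @export
print.ci_calibration_audit <- function(x, ...) {
  cat(sprintf("<ci_calibration_audit> %d records in %d intervals\n",
              x$n, x$n_intervals))
  cat(sprintf("  slope %.3f | intercept %.4f | R^2 %.3f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  %.1f%% of intervals with Cohen's h < 0.2; %.1f%% significant at p < 0.05\n",
              x$pct_h_lt_0.2, x$pct_significant))
  invisible(x)
}

#' Calibration plot (observed vs expected by risk interval)
#'
#' @param x A `ci_calibration_audit`.
#' @param ... Passed to `plot()`.
#' @export
plot.ci_calibration_audit <- function(x, ...) {
  tab <- x$intervals
  plot(tab$observed, tab$expected, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Observed proportion of ICU periods",
       ylab = "Expected proportion (mean calibrated risk)",
       pch = 1, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}
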