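#' Confusion counts at a threshold
#'
#' Scores strictly above the threshold are called positive (ICU).
#'
#' @param scores Numeric scores.
#' @param outcomes 0/1 outcomes (1 = ICU).
#' @param threshold Decision threshold.
#' @return List with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(scores, outcomes, threshold) {
  pred <- scores > threshold
  pos <- outcomes == 1
  list(TP = sum(pred & pos), FP = sum(pred & !pos),
       TN = sum(!pred & !pos), FN = sum(!pred & pos))
}

wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Operating point with the full metric set
#'
#' Computes sensitivity, specificity, precision (PPV), NPV, accuracy, F1
#' (harmonic mean of precision and sensitivity), MCC and the number needed
#' to evaluate (NNE = 1/precision) at a threshold, with Wilson 95 %
#' intervals for the proportion-type metrics. The algebraic identities
#' `accuracy = sens * prev + spec * (1 - prev)`, `F1 = 2 p s / (p + s)` and
#' `NNE = 1 / precision` hold exactly by construction.
#'
#' @param scores,outcomes Scores and 0/1 outcomes.
#' @param threshold Decision threshold in (0, 1).
#' @return An object of class `ci_operating_point`.
#' @export
metrics_at_threshold <- function(scores, outcomes, threshold = 0.5) {
  if (!length(scores)) stopf("metrics_at_threshold: empty input")
  if (threshold <= 0 || threshold >= 1)
    stopf("metrics_at_threshold: threshold must be in (0, 1)")
  cc <- confusion_counts(scores, outcomes, threshold)
  operating_point(cc, threshold)
}

operating_point <- function(cc, threshold) {
  with(cc, {
    n <- TP + FP + TN + FN
    sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
    npv <- if (TN + FN > 0) TN / (TN + FN) else NA_real_
    acc <- (TP + TN) / n
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else NA_real_
    m <- {
      den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
      if (den == 0) 0 else (TP * TN - FP * FN) / den
    }
    structure(list(
      threshold = threshold, counts = cc, n = n,
      sensitivity = sens, specificity = spec, precision = prec, npv = npv,
      accuracy = acc, f1 = f1, mcc = m,
      nne = if (!is.na(prec) && prec > 0) 1 / prec else NA_real_,
      ci = list(sensitivity = wilson_ci(TP, TP + FN),
                specificity = wilson_ci(TN, TN + FP),
                precision = wilson_ci(TP, TP + FP),
                npv = wilson_ci(TN, TN + FN),
                accuracy = wilson_ci(TP + TN, n))
    ), class = "ci_operating_point")
  })
}

#' @export
print.ci_operating_point <- function(x, ...) {
  cat(sprintf("<ci_operating_point> threshold %.3f (n=%d)\n", x$threshold, x$n))
  cat(sprintf("  sens %.3f | spec %.3f | prec %.3f | npv %.3f | acc %.3f\n",
              x$sensitivity, x$specificity, x$precision, x$npv, x$accuracy))
  cat(sprintf("  F1 %.3f | MCC %.3f | NNE %.1f\n", x$f1, x$mcc, x$nne))
  invisible(x)
}

#' Accuracy from sensitivity, specificity and prevalence
#'
#' The identity `accuracy = sensitivity * prevalence +
#' specificity * (1 - prevalence)`, used to check published operating
#' points for internal consistency.
#'
#' @param sensitivity,specificity,prevalence Rates in `[0, 1]`.
#' @return Accuracy.
#' @export
accuracy_from_rates <- function(sensitivity, specificity, prevalence) {
  sensitivity * prevalence + specificity * (1 - prevalence)
}

#' F1 score as the harmonic mean of precision and sensitivity
#' @param precision,sensitivity Rates in `[0, 1]`.
#' @return F1 score.
#' @export
f1_score <- function(precision, sensitivity) {
  2 * precision * sensitivity / (precision + sensitivity)
}

#' Number needed to evaluate
#' @param precision Positive predictive value.
#' @return `1 / precision`: alerted patients reviewed per true positive.
#' @export
nne <- function(precision) 1 / precision

#' Area under the ROC curve with DeLong confidence interval
#'
#' The area equals the pairwise concordance probability (ties counted 1/2),
#' computed by the rank-sum formulation; the confidence interval uses the
#' DeLong large-sample variance of placement values.
#'
#' @param scores,outcomes Scores and 0/1 outcomes (both classes required).
#' @param conf Confidence level.
#' @return List with `auc`, `ci` (length-2), `se`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, outcomes, conf = 0.95) {
  pos <- outcomes == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("roc_auc: both outcome classes required")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # placement values (DeLong): V10_i = P(score_neg < s_i) + .5 P(=)
  r1 <- rank(scores[pos], ties.method = "average")
  r0 <- rank(scores[!pos], ties.method = "average")
  v10 <- (r[pos] - r1) / n0
  v01 <- 1 - (r[!pos] - r0) / n1
  se <- sqrt(var(v10) / n1 + var(v01) / n0)
  z <- qnorm(1 - (1 - conf) / 2)
  list(auc = auc, ci = c(max(0, auc - z * se), min(1, auc + z * se)),
       se = se, n_pos = n1, n_neg = n0)
}

#' Area under the precision-recall curve with logit-scale interval
#'
#' Trapezoidal integration of precision over recall across all distinct
#' score thresholds. The interval is a normal interval on the logit scale
#' with a binomial-type standard error `sqrt(A (1 - A) / n_pos)`.
#'
#' @param scores,outcomes Scores and 0/1 outcomes (>= 1 positive required).
#' @param conf Confidence level.
#' @return List with `area`, `ci`, `n_pos`, and the curve coordinates.
#' @export
pr_auc <- function(scores, outcomes, conf = 0.95) {
  n1 <- sum(outcomes == 1)
  if (n1 == 0) stopf("pr_auc: at least one positive outcome required")
  o <- order(scores, decreasing = TRUE)
  y <- outcomes[o]; s <- scores[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(s[-length(s)] != s[-1], TRUE)   # last index of each distinct score
  tp <- tp[keep]; fp <- fp[keep]
  recall <- tp / n1
  prec <- tp / (tp + fp)
  rec0 <- c(0, recall)
  prec0 <- c(prec[1], prec)                  # extend flat to recall 0
  area <- sum(diff(rec0) * (head(prec0, -1) + tail(prec0, -1)) / 2)
  se <- sqrt(max(area * (1 - area), 1e-12) / n1)
  z <- qnorm(1 - (1 - conf) / 2)
  lo <- plogis(qlogis(clamp(area, 1e-12, 1 - 1e-12)) -
                 z * se / max(area * (1 - area), 1e-12))
  hi <- plogis(qlogis(clamp(area, 1e-12, 1 - 1e-12)) +
                 z * se / max(area * (1 - area), 1e-12))
  list(area = area, ci = c(lo, hi), n_pos = n1,
       curve = data.table::data.table(recall = recall, precision = prec))
}

#' Operating point achieving a target sensitivity
#'
#' Returns the largest threshold whose sensitivity is at least `target`
#' (ties resolved toward the larger threshold, maximizing specificity).
#' Reported sensitivity can exceed the target because of score ties.
#'
#' @param scores,outcomes Scores and 0/1 outcomes.
#' @param target Required sensitivity (e.g. 0.85, 0.90, 0.95, 0.99).
#' @return A `ci_operating_point` with an extra `target` element.
#' @export
threshold_for_sensitivity <- function(scores, outcomes, target = 0.95) {
  pos <- outcomes == 1
  if (!any(pos) || all(pos))
    stopf("threshold_for_sensitivity: both outcome classes required")
  # candidate thresholds: just below each distinct positive score (strict >)
  sp <- sort(unique(scores[pos]), decreasing = TRUE)
  sens <- cumsum(table(factor(scores[pos], levels = sp)))[as.character(sp)] / sum(pos)
  # threshold t in [sp[k+1], sp[k]) achieves sensitivity of >= sp[k]
  feasible <- which(sens >= target)
  if (!length(feasible))
    stopf("threshold_for_sensitivity: target %.3f unreachable", target)
  k <- feasible[1]
  thr <- next_lower_threshold(scores, sp[k])
  op <- operating_point(confusion_counts(scores, outcomes, thr), thr)
  op$target <- c(sensitivity = target)
  op
}

#' Operating point achieving a target specificity
#'
#' Mirror of [threshold_for_sensitivity()] with the class roles swapped:
#' the smallest threshold whose specificity is at least `target` (ties
#' toward the smaller threshold, maximizing sensitivity).
#'
#' @param scores,outcomes Scores and 0/1 outcomes.
#' @param target Required specificity.
#' @return A `ci_operating_point` with an extra `target` element.
#' @export
threshold_for_specificity <- function(scores, outcomes, target = 0.95) {
  neg <- outcomes == 0
  if (!any(neg) || all(neg))
    stopf("threshold_for_specificity: both outcome classes required")
  sn <- sort(unique(scores[neg]))            # ascending
  # classifying routine requires score <= t; spec(t) = P(neg score <= t)
  spec_at <- cumsum(table(factor(scores[neg], levels = sn)))[as.character(sn)] / sum(neg)
  feasible <- which(spec_at >= target)
  if (!length(feasible))
    stopf("threshold_for_specificity: target %.3f unreachable", target)
  thr <- sn[feasible[1]]
  op <- operating_point(confusion_counts(scores, outcomes, thr), thr)
  op$target <- c(specificity = target)
  op
}

# A threshold strictly below `value` but above the next lower distinct
# score, so `score > threshold` includes `value`.
next_lower_threshold <- function(scores, value) {
  lower <- scores[scores < value]
  if (!length(lower)) return(value - max(1e-6, abs(value) * 1e-6))
  (value + max(lower)) / 2
}
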