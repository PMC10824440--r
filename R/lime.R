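#' Local linear surrogate explanation for one prediction
#'
#' LIME-style explanation: perturb the record's features (Gaussian jitter
#' scaled by per-feature training standard deviations; Bernoulli flips for
#' binary features), score the perturbations with the model, weight them by
#' an exponential proximity kernel on standardized distance, and fit a
#' weighted ridge surrogate. The absolute surrogate coefficients rank the
#' covariates by local importance; rank ties break by feature name for
#' determinism.
#'
#' @param predict_fun Function mapping a feature matrix to scores (e.g.
#'   `function(X) predict_raw(model, X)`).
#' @param record Named numeric vector: the instance to explain.
#' @param feature_sd Named per-feature scales (training standard
#'   deviations); features with `sd = 0` are held fixed.
#' @param binary Optional character vector of features perturbed by
#'   Bernoulli flip (0/1) instead of jitter.
#' @param n_perturbations Perturbation sample size (default 1000).
#' @param kernel_width Proximity kernel width on standardized distance;
#'   default `0.75 * sqrt(d)`.
#' @param ridge Ridge penalty of the surrogate (default 1e-3).
#' @param seed Integer seed; identical seeds give identical explanations.
#' @return An object of class `ci_local_explanation`: `data.table` with
#'   `feature`, `weight`, `rank` (1 = most important).
#' @export
explain_local <- function(predict_fun, record, feature_sd,
                          binary = character(), n_perturbations = 1000L,
                          kernel_width = NULL, ridge = 1e-3, seed = 1L) {
  d <- length(record)
  if (is.null(names(record)) || is.null(names(feature_sd)))
    stopf("explain_local: record and feature_sd must be named")
  feature_sd <- feature_sd[names(record)]
  if (anyNA(feature_sd)) stopf("explain_local: feature_sd missing some features")
  active <- feature_sd > 0
  if (!any(active)) stopf("explain_local: all perturbation scales are zero")
  kw <- kernel_width %||% (0.75 * sqrt(d))
  with_seed(seed, {
    Z <- matrix(rep(record, each = n_perturbations), n_perturbations, d,
                dimnames = list(NULL, names(record)))
    cont <- names(record)[active & !(names(record) %in% binary)]
    if (length(cont)) {
      J <- matrix(rnorm(n_perturbations * length(cont)), n_perturbations)
      Z[, cont] <- Z[, cont] + sweep(J, 2L, feature_sd[cont], "*")
    }
    bin <- intersect(binary, names(record)[active])
    for (bcol in bin) Z[, bcol] <- rbinom(n_perturbations, 1L, 0.5)
    y <- predict_fun(Z)
    # standardized distance to the record
    Dz <- sweep(Z, 2L, record)
    Dz[, active] <- sweep(Dz[, active, drop = FALSE], 2L,
                          feature_sd[active], "/")
    dist <- sqrt(rowSums(Dz^2))
    w <- exp(-dist^2 / (2 * kw^2))
    # weighted ridge on standardized perturbations
    Xs <- Dz[, active, drop = FALSE]
    if (all(apply(Xs, 2L, var) < 1e-14))
      stopf("explain_local: zero-variance perturbations")
    xbar <- colSums(Xs * w) / sum(w)
    Xw <- sweep(Xs, 2L, xbar) * sqrt(w)        # weighted centering = intercept
    yw <- (y - sum(w * y) / sum(w)) * sqrt(w)
    beta <- if (ncol(Xw) <= nrow(Xw)) {
      A <- crossprod(Xw) + diag(ridge, ncol(Xw))
      solve(A, crossprod(Xw, yw))[, 1L]
    } else {
      # dual form: cheaper when features outnumber perturbations
      G <- tcrossprod(Xw) + diag(ridge, nrow(Xw))
      drop(crossprod(Xw, solve(G, yw)))
    }
    weights <- stats::setNames(numeric(d), names(record))
    weights[names(beta)] <- beta
    tab <- data.table::data.table(feature = names(record), weight = unname(weights))
    tab[, abs_w := abs(weight)]
    data.table::setorder(tab, -abs_w, feature)
    tab[, rank := .I]
    tab[, abs_w := NULL]
    structure(list(weights = tab[order(match(feature, names(record)))],
                   n_perturbations = n_perturbations, kernel_width = kw,
                   seed = seed),
              class = "ci_local_explanation")
  })
}

#' @export
print.ci_local_explanation <- function(x, ...) {
  cat("<ci_local_explanation>\n")
  top <- x$weights[order(rank)][1:min(10, nrow(x$weights))]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %2d. %-32s %+.4f\n", top$rank[i], top$feature[i], top$weight[i]))
  invisible(x)
}

#' Covariate importance frequency within a risk band
#'
#' Explains every record whose calibrated risk lies inside the band
#' (default 0.245-0.255) and reports, per covariate, the percentage of
#' explained cases in which it ranked among the `top_k` (default 30) most
#' important features. Duplicated records are counted once per appearance.
#'
#' @param predict_fun Model scoring function (see [explain_local()]).
#' @param X Feature matrix for candidate records.
#' @param risks Calibrated risks aligned with rows of `X`.
#' @param feature_sd Per-feature perturbation scales.
#' @param risk_band Inclusive bounds of the risk band.
#' @param top_k Rank cutoff counted as "important".
#' @param n_perturbations,seed Passed to [explain_local()].
#' @param max_cases Optional cap on explained cases (first `max_cases` in
#'   row order) to bound run time.
#' @param groups Optional named character vector mapping each column of `X`
#'   to a covariate name. When supplied, the local importance of a
#'   covariate is the sum of absolute surrogate weights over its columns
#'   (e.g. collapsing lookback slots of one variable), and ranking/top-`k`
#'   membership operates at the covariate level.
#' @return An object of class `ci_importance_profile`.
#' @export
importance_frequency <- function(predict_fun, X, risks, feature_sd,
                                 risk_band = c(0.245, 0.255), top_k = 30L,
                                 n_perturbations = 500L, seed = 1L,
                                 max_cases = Inf, groups = NULL) {
  in_band <- which(risks >= risk_band[1] & risks <= risk_band[2])
  if (!length(in_band))
    stopf("importance_frequency: no records with risk in [%.3f, %.3f]; widen the band",
          risk_band[1], risk_band[2])
  if (length(in_band) > max_cases) in_band <- in_band[seq_len(max_cases)]
  if (!is.null(groups)) {
    if (!all(colnames(X) %in% names(groups)))
      stopf("importance_frequency: groups must cover every column of X")
    covariates <- sort(unique(unname(groups[colnames(X)])))
  } else covariates <- colnames(X)
  hits <- stats::setNames(numeric(length(covariates)), covariates)
  for (i in seq_along(in_band)) {
    ex <- explain_local(predict_fun, X[in_band[i], ], feature_sd,
                        n_perturbations = n_perturbations,
                        seed = child_seed(seed, paste0("case", in_band[i])))
    w <- ex$weights
    if (!is.null(groups)) {
      w <- w[, .(weight = sum(abs(weight))),
             by = .(feature = unname(groups[feature]))]
      data.table::setorder(w, -weight, feature)
      top <- w$feature[seq_len(min(top_k, nrow(w)))]
    } else top <- w[rank <= top_k, feature]
    hits[top] <- hits[top] + 1
  }
  structure(list(
    frequency = 100 * hits / length(in_band),
    n_cases = length(in_band), risk_band = risk_band, top_k = top_k,
    grouped = !is.null(groups)
  ), class = "ci_importance_profile")
}

#' @export
print.ci_importance_profile <- function(x, ...) {
  cat(sprintf("<ci_importance_profile> %d cases in risk band [%.3f, %.3f], top %d\n",
              x$n_cases, x$risk_band[1], x$risk_band[2], x$top_k))
  top <- sort(x$frequency, decreasing = TRUE)[1:min(10, length(x$frequency))]
  for (i in seq_along(top))
    cat(sprintf("  %-32s %5.1f%%\n", names(top)[i], top[i]))
  invisible(x)
}

#' Compare two covariate-importance profiles
#'
#' Per covariate: the frequency difference, 95 % Wilson intervals for both
#' frequencies, Cohen's h of the two proportions, and a practical-
#' difference flag set iff the intervals do not overlap AND h > 0.2. Also
#' reports the top-`k` set non-overlap: the share of one profile's top-`k`
#' covariates absent from the other's.
#'
#' @param profile_a,profile_b `ci_importance_profile`s over the same
#'   covariate universe.
#' @return A list with the per-covariate `table` and the two non-overlap
#'   shares (`pct_a_not_in_b`, `pct_b_not_in_a`).
#' @export
compare_profiles <- function(profile_a, profile_b) {
  fa <- profile_a$frequency; fb <- profile_b$frequency
  if (!setequal(names(fa), names(fb)))
    stopf("compare_profiles: covariate universes differ (%s)",
          paste(head(c(setdiff(names(fa), names(fb)),
                       setdiff(names(fb), names(fa))), 8L), collapse = ", "))
  fb <- fb[names(fa)]
  pa <- fa / 100; pb <- fb / 100
  na <- profile_a$n_cases; nb <- profile_b$n_cases
  cia <- t(vapply(pa, function(p) wilson_ci(round(p * na), na), c(0, 0)))
  cib <- t(vapply(pb, function(p) wilson_ci(round(p * nb), nb), c(0, 0)))
  h <- cohens_h(pa, pb)
  no_overlap <- cia[, 1] > cib[, 2] | cib[, 1] > cia[, 2]
  tab <- data.table::data.table(
    feature = names(fa), freq_a = fa, freq_b = fb, diff = fa - fb,
    ci_a_lo = 100 * cia[, 1], ci_a_hi = 100 * cia[, 2],
    ci_b_lo = 100 * cib[, 1], ci_b_hi = 100 * cib[, 2],
    cohens_h = h, practical_difference = no_overlap & h > 0.2)
  k <- profile_a$top_k
  top_a <- names(fa)[order(-fa, names(fa))][seq_len(min(k, length(fa)))]
  top_b <- names(fb)[order(-fb, names(fb))][seq_len(min(k, length(fb)))]
  list(table = tab,
       pct_a_not_in_b = 100 * mean(!top_a %in% top_b),
       pct_b_not_in_a = 100 * mean(!top_b %in% top_a))
}
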