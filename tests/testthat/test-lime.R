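test_that("the surrogate recovers the coefficient ranking of a linear model", {
  beta <- c(f1 = 3, f2 = -2, f3 = 1, f4 = 0.5, f5 = 0)
  predict_fun <- function(X) plogis(X %*% beta)[, 1]
  record <- c(f1 = 0.2, f2 = -0.1, f3 = 0.3, f4 = 0, f5 = 0.1)
  fsd <- setNames(rep(1, 5), names(record))
  ex <- explain_local(predict_fun, record, fsd, seed = 4L)
  got <- ex$weights[order(rank)]$feature
  expect_equal(got, c("f1", "f2", "f3", "f4", "f5"))
  expect_true(all(sort(ex$weights$rank) == 1:5))
})

test_that("a feature the model ignores stays below the noise floor", {
  set.seed(9)
  beta <- c(rep(1, 4), 0)
  names(beta) <- paste0("f", 1:5)
  predict_fun <- function(X) plogis(X %*% beta)[, 1]
  fsd <- setNames(rep(1, 5), names(beta))
  hits <- 0L
  for (i in 1:40) {
    record <- setNames(rnorm(5), names(beta))
    ex <- explain_local(predict_fun, record, fsd, seed = 100L + i)
    w <- ex$weights
    null_w <- abs(w[feature == "f5"]$weight)
    active_med <- stats::median(abs(w[feature != "f5"]$weight))
    if (null_w < 0.2 * active_med) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("explanations are seeded and invariant to feature order", {
  beta <- c(f1 = 2, f2 = -1, f3 = 0.5)
  predict_fun <- function(X) plogis(X[, c("f1", "f2", "f3")] %*% beta)[, 1]
  record <- c(f1 = 0.1, f2 = 0.2, f3 = -0.3)
  fsd <- setNames(rep(1, 3), names(record))
  e1 <- explain_local(predict_fun, record, fsd, seed = 7L)
  e2 <- explain_local(predict_fun, record, fsd, seed = 7L)
  expect_identical(e1$weights, e2$weights)
  perm <- c("f3", "f1", "f2")
  e3 <- explain_local(predict_fun, record[perm], fsd[perm], seed = 7L)
  w1 <- setNames(e1$weights$weight, e1$weights$feature)
  w3 <- setNames(e3$weights$weight, e3$weights$feature)
  expect_equal(w1[names(w3)], w3, tolerance = 0.2)
  expect_equal(e3$weights[order(rank)]$feature[1], "f1")
})

test_that("importance frequency counts top-k membership inside the risk band", {
  beta <- c(f1 = 5, f2 = 0, f3 = 0, f4 = 0)
  predict_fun <- function(X) plogis(X %*% beta / 4)[, 1]
  set.seed(31)
  X <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, names(beta)))
  risks <- predict_fun(X)
  fsd <- setNames(rep(1, 4), names(beta))
  # band covering everything with top_k = all features: every frequency 100
  prof <- importance_frequency(predict_fun, X, risks, fsd,
                               risk_band = c(0, 1), top_k = 4L,
                               n_perturbations = 200L, seed = 5L,
                               max_cases = 25L)
  expect_true(all(prof$frequency == 100))
  # dominant feature always top-1
  prof1 <- importance_frequency(predict_fun, X, risks, fsd,
                                risk_band = c(0, 1), top_k = 1L,
                                n_perturbations = 200L, seed = 5L,
                                max_cases = 25L)
  expect_equal(unname(prof1$frequency["f1"]), 100)
  expect_true(all(prof1$frequency[c("f2", "f3", "f4")] < 25))
  expect_error(importance_frequency(predict_fun, X, risks, fsd,
                                    risk_band = c(0.9999, 1)), "widen")
})

test_that("an injected usage shift flags the shifted covariates preferentially", {
  # two linear scorers over 40 features; the "local" model leans on a known
  # subset the "reference" model ignores (an injected practice shift)
  set.seed(77)
  d <- 40L
  feats <- sprintf("f%02d", 1:d)
  shifted <- feats[1:8]
  beta_ref <- setNames(c(rep(0.05, 8), rep(2, 8), rep(0.05, 24)), feats)
  beta_loc <- setNames(c(rep(2, 8), rep(2, 8), rep(0.05, 24)), feats)
  fsd <- setNames(rep(1, d), feats)
  X <- matrix(rnorm(400 * d), 400, d, dimnames = list(NULL, feats))
  mk_prof <- function(beta) {
    pf <- function(M) plogis(M %*% beta / 8)[, 1]
    importance_frequency(pf, X, pf(X), fsd, risk_band = c(0, 1), top_k = 10L,
                         n_perturbations = 250L, seed = 3L, max_cases = 40L)
  }
  cmp <- compare_profiles(mk_prof(beta_ref), mk_prof(beta_loc))
  tab <- cmp$table
  flag_shifted <- mean(tab[feature %in% shifted]$practical_difference)
  flag_other <- mean(tab[!feature %in% shifted]$practical_difference)
  expect_gt(flag_shifted, flag_other)
  expect_gte(flag_shifted, 0.9)
  # and the top-10 sets disagree more than two same-model profiles do
  expect_gt(cmp$pct_b_not_in_a, 0)
})

test_that("profile comparison flags require CI separation and h > 0.2", {
  mk <- function(freqs, n) structure(list(frequency = freqs, n_cases = n,
                                          risk_band = c(0.245, 0.255),
                                          top_k = 2L),
                                     class = "ci_importance_profile")
  a <- mk(c(x = 50, y = 40, z = 10), 200L)
  cmp_same <- compare_profiles(a, a)
  expect_false(any(cmp_same$table$practical_difference))
  expect_equal(cmp_same$pct_a_not_in_b, 0)
  # 50% vs 40% at n = 200: h just over 0.2 but intervals overlap -> no flag
  b <- mk(c(x = 40, y = 40, z = 10), 200L)
  row_x <- compare_profiles(a, b)$table[feature == "x"]
  expect_equal(row_x$cohens_h, cohens_h(0.5, 0.4), tolerance = 1e-9)
  expect_false(row_x$practical_difference)
  # large separation at big n flags
  c2 <- mk(c(x = 5, y = 40, z = 60), 2000L)
  a2 <- mk(c(x = 50, y = 40, z = 10), 2000L)
  tab <- compare_profiles(a2, c2)$table
  expect_true(tab[feature == "x"]$practical_difference)
  expect_true(tab[feature == "z"]$practical_difference)
  expect_false(tab[feature == "y"]$practical_difference)
  d <- mk(c(q = 10, y = 20, z = 30), 200L)
  expect_error(compare_profiles(a, d), "universes")
})
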