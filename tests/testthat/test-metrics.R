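test_that("operating-point identities hold exactly on computed confusions", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(50:300, 1)
    scores <- runif(n)
    outcomes <- rbinom(n, 1, 0.3)
    if (length(unique(outcomes)) < 2) next
    op <- metrics_at_threshold(scores, outcomes, runif(1, 0.1, 0.9))
    prev <- mean(outcomes)
    expect_equal(op$accuracy,
                 op$sensitivity * prev + op$specificity * (1 - prev),
                 tolerance = 1e-12)
    expect_equal(op$f1, 2 * op$precision * op$sensitivity /
                   (op$precision + op$sensitivity), tolerance = 1e-12)
    expect_equal(op$nne, 1 / op$precision, tolerance = 1e-12)
    expect_true(op$nne >= 1)
  }
})

test_that("perfect and degenerate classifiers give the expected corners", {
  op <- metrics_at_threshold(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_equal(op$mcc, 1)
  expect_equal(op$f1, 1)
  expect_error(metrics_at_threshold(numeric(), numeric(), 0.5), "empty")
  expect_error(metrics_at_threshold(0.5, 1, 1.5), "threshold")
})

test_that("roc_auc equals brute-force concordance and rank-sum on random toys", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), sample(1:3, 1))  # induce ties
    outcomes <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(outcomes)) < 2) next
    a <- roc_auc(scores, outcomes)$auc
    expect_equal(a, auc_brute(scores, outcomes), tolerance = 1e-12)
    w <- suppressWarnings(wilcox.test(scores[outcomes == 1],
                                      scores[outcomes == 0]))$statistic
    expect_equal(a, unname(w) / (sum(outcomes == 1) * sum(outcomes == 0)),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc corners: perfect separation 1.0, null near 0.5", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  set.seed(2)
  n <- 10000
  a <- roc_auc(runif(n), rbinom(n, 1, 0.5))$auc
  expect_lt(abs(a - 0.5), 0.02)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both")
})

test_that("pr_auc equals exhaustive threshold enumeration on random toys", {
  set.seed(13)
  for (i in 1:300) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), sample(1:3, 1))
    outcomes <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(outcomes) == 0) next
    expect_equal(pr_auc(scores, outcomes)$area,
                 pr_auc_brute(scores, outcomes), tolerance = 1e-12)
  }
})

test_that("pr_auc corners: perfect 1.0, random near prevalence", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$area, 1)
  set.seed(3)
  n <- 10000
  y <- rbinom(n, 1, 0.2)
  expect_lt(abs(pr_auc(runif(n), y)$area - 0.2), 0.02)
  expect_error(pr_auc(runif(5), rep(0, 5)), "positive")
})

test_that("fixed-sensitivity threshold search matches brute force", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    scores <- round(runif(n), 2)
    outcomes <- rbinom(n, 1, 0.4)
    if (length(unique(outcomes)) < 2) next
    for (target in c(0.85, 0.95)) {
      op <- threshold_for_sensitivity(scores, outcomes, target)
      expect_gte(op$sensitivity, target)
      bf <- threshold_sens_brute(scores, outcomes, target)
      # same achieved confusion as the brute-force threshold
      expect_identical(confusion_counts(scores, outcomes, op$threshold),
                       confusion_counts(scores, outcomes, bf))
    }
  }
})

test_that("sensitivity/specificity trade-off is monotone in the target", {
  set.seed(19)
  scores <- runif(500); outcomes <- rbinom(500, 1, 0.3)
  ops <- lapply(c(0.85, 0.90, 0.95, 0.99),
                function(t) threshold_for_sensitivity(scores, outcomes, t))
  specs <- vapply(ops, `[[`, 0, "specificity")
  expect_true(all(diff(specs) <= 1e-12))
  spo <- lapply(c(0.85, 0.90, 0.95, 0.99),
                function(t) threshold_for_specificity(scores, outcomes, t))
  senss <- vapply(spo, `[[`, 0, "sensitivity")
  expect_true(all(diff(senss) <= 1e-12))
})

test_that("fixed-specificity search mirrors the sensitivity search", {
  scores <- c(0.1, 0.2, 0.3, 0.6, 0.7, 0.9)
  outcomes <- c(0, 0, 0, 1, 1, 1)
  op <- threshold_for_specificity(scores, outcomes, 0.95)
  expect_equal(op$specificity, 1)
  expect_equal(op$sensitivity, 1)  # perfect scores: both ends achievable
})

test_that("sensitivity non-increasing and specificity non-decreasing in threshold", {
  set.seed(23)
  scores <- runif(300); outcomes <- rbinom(300, 1, 0.4)
  grid <- sort(unique(scores))
  sens <- vapply(grid, function(t) {
    cc <- confusion_counts(scores, outcomes, t); cc$TP / (cc$TP + cc$FN)
  }, 0)
  spec <- vapply(grid, function(t) {
    cc <- confusion_counts(scores, outcomes, t); cc$TN / (cc$TN + cc$FP)
  }, 0)
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("published-row identities reproduce printed values", {
  # accuracy from sensitivity/specificity/prevalence at the 0.5 threshold
  expect_lt(abs(accuracy_from_rates(0.718, 0.943, 0.208) - 0.896), 1e-3)
  # F1 as the harmonic mean of precision and sensitivity
  expect_lt(abs(f1_score(0.663, 0.850) - 0.745), 1e-3)
  expect_lt(abs(f1_score(0.428, 0.008) - 0.016), 1e-3)
  # number needed to evaluate
  expect_equal(nne(0.505), 2.0, tolerance = 0.05)
  expect_equal(nne(0.383), 2.6, tolerance = 0.05)
})
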