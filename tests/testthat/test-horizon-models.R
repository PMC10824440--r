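make_linear_toy <- function(n = 4000L, seed = 1L, noise = 0) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- as.integer(X[, 1] + X[, 2] + noise * rnorm(n) > 0)
    list(X = X, y = y, train = seq_len(0.75 * n),
         val = seq(0.75 * n + 1, n))
  })
}

test_that("growth training matches a logistic oracle on separable data", {
  d <- make_linear_toy()
  # oracle: logistic regression achieves MCC >= 0.9 here
  g <- suppressWarnings(glm(d$y[d$train] ~ d$X[d$train, ], family = binomial))
  po <- plogis(cbind(1, d$X[d$val, ]) %*% coef(g))[, 1]
  expect_gte(mcc(as.integer(po > 0.5), d$y[d$val]), 0.9)
  m <- train_horizon_model(d$X[d$train, ], d$y[d$train],
                           d$X[d$val, ], d$y[d$val],
                           ci_protocol_desk(seed = 2L), horizon = 1L)
  expect_gte(m$val_mcc, 0.9)
  expect_false(m$overfit_fallback)
})

test_that("shuffled labels give chance-level discrimination", {
  d <- make_linear_toy(n = 20000L, seed = 3L)
  y_perm <- withr::with_seed(4L, sample(d$y))
  m <- suppressWarnings(train_horizon_model(
    d$X[d$train, ], y_perm[d$train], d$X[d$val, ], y_perm[d$val],
    ci_protocol(max_hidden_layers = 1L, node_schedule = 8L, epochs = 8L,
                learning_rate = 3e-3, drift_tolerance = 1, seed = 5L),
    horizon = 1L))
  s <- predict_raw(m, d$X[d$val, ])
  expect_lt(abs(roc_auc(s, y_perm[d$val])$auc - 0.5), 0.05)
})

test_that("single-class partitions are rejected", {
  d <- make_linear_toy(n = 200L)
  expect_error(train_horizon_model(d$X, rep(1L, 200), d$X, d$y,
                                   ci_protocol_desk()), "single class")
  expect_error(train_horizon_model(d$X, d$y, d$X, rep(0L, 200),
                                   ci_protocol_desk()), "single class")
})

test_that("training is reproducible and selection is MCC-optimal", {
  d <- make_linear_toy(n = 1500L, seed = 6L, noise = 0.5)
  p <- ci_protocol_desk(seed = 11L, epochs = 8L)
  m1 <- suppressWarnings(train_horizon_model(d$X[d$train, ], d$y[d$train],
                                             d$X[d$val, ], d$y[d$val], p, 1L))
  m2 <- suppressWarnings(train_horizon_model(d$X[d$train, ], d$y[d$train],
                                             d$X[d$val, ], d$y[d$val], p, 1L))
  expect_identical(m1$hidden, m2$hidden)
  expect_equal(m1$val_mcc, m2$val_mcc, tolerance = 1e-12)
  expect_identical(m1$net$W, m2$net$W)
  # the selected model dominates every retained non-overfit candidate
  if (!m1$overfit_fallback)
    expect_gte(m1$val_mcc + 1e-9, max(m1$history[overfit == FALSE]$val_mcc))
})

test_that("predict_raw is deterministic, order-equivariant, schema-strict", {
  d <- make_linear_toy(n = 800L, seed = 7L)
  m <- suppressWarnings(train_horizon_model(d$X[d$train, ], d$y[d$train],
                                            d$X[d$val, ], d$y[d$val],
                                            ci_protocol_desk(seed = 3L, epochs = 5L), 1L))
  s1 <- predict_raw(m, d$X[d$val, ])
  expect_identical(s1, predict_raw(m, d$X[d$val, ]))
  expect_true(all(s1 > 0 & s1 < 1))
  # duplicated row scores identically; permutation permutes scores
  dup <- d$X[c(1, 1), ]
  expect_equal(predict_raw(m, dup)[1], predict_raw(m, dup)[2])
  perm <- rev(seq_along(s1))
  expect_equal(predict_raw(m, d$X[d$val, ][perm, ]), s1[perm])
  Xbad <- d$X[d$val, 1:4]
  expect_error(predict_raw(m, Xbad), "schema")
})

test_that("classify applies the strict-inequality cut point convention", {
  expect_equal(classify(c(0.2, 0.6), 0.5), c(0L, 1L))
  expect_equal(classify(0.5, 0.5), 0L)  # score equal to cut point -> routine
  s <- runif(100)
  expect_gte(sum(classify(s, 0.15)), sum(classify(s, 0.9)))
  expect_error(classify(0.5, 0), "cutpoint")
})

test_that("mcc handles degenerate confusion matrices by convention", {
  expect_equal(mcc(rep(1, 10), rep(1, 10)), 0)
  expect_equal(mcc(rep(0, 10), rbinom(10, 1, 0.5)), 0)
  expect_equal(mcc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(mcc(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1)
})
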