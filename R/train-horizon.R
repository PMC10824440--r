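#' Training protocol configuration
#'
#' Parameters of the architecture-growth training protocol. Training starts
#' with a single hidden layer and grows the node count along
#' `node_schedule`, monitoring MCC (plus sensitivity/specificity/precision/
#' NPV) at cut points 0.15/0.5/0.9 on training and validation data. When
#' the validation MCC drifts below the training MCC by more than
#' `drift_tolerance` (overfitting), L1/L2 and dropout are added along
#' `reg_ladder` and the fit is retried. When wider layers stop helping, a
#' hidden layer is added; growth stops when regularization no longer
#' rescues overfitting, and the best non-overfit validation-MCC model wins.
#'
#' Full-scale defaults follow the published protocol (Glorot-uniform
#' initialization, RMSprop with initial learning rate 2e-4, minibatches of
#' 10,000 rows, up to five hidden layers). `minibatch = NULL` shrinks the
#' minibatch to `min(10000, ceiling(n/10))` so small cohorts still take
#' several steps per epoch; small-data runs should also raise the learning
#' rate (see `ci_protocol_desk()`).
#'
#' @param max_hidden_layers Maximum depth explored (default 5).
#' @param node_schedule Widths tried at each depth (default 8-128).
#' @param epochs,patience Epoch budget and early-stopping patience.
#' @param learning_rate RMSprop initial learning rate (default 2e-4).
#' @param minibatch Minibatch rows, or `NULL` for the desk-scale shrink.
#' @param cutpoints Monitoring cut points (default 0.15/0.5/0.9).
#' @param drift_tolerance Max allowed training-minus-validation MCC gap at
#'   cut point 0.5 before a fit counts as overfit (default 0.02).
#' @param min_delta Minimum validation-MCC gain to count as an improvement.
#' @param reg_ladder List of `list(l1=, l2=, dropout=)` levels tried, in
#'   order, when a fit overfits.
#' @param seed Integer seed making the whole protocol reproducible.
#' @return An object of class `ci_protocol`.
#' @export
ci_protocol <- function(max_hidden_layers = 5L,
                        node_schedule = c(8L, 16L, 32L, 64L, 128L),
                        epochs = 60L, patience = 8L,
                        learning_rate = 2e-4, minibatch = NULL,
                        cutpoints = c(0.15, 0.5, 0.9),
                        drift_tolerance = 0.02, min_delta = 0.002,
                        reg_ladder = list(
                          list(l1 = 0, l2 = 0, dropout = 0),
                          list(l1 = 1e-6, l2 = 1e-4, dropout = 0.1),
                          list(l1 = 1e-5, l2 = 1e-3, dropout = 0.25),
                          list(l1 = 1e-5, l2 = 1e-2, dropout = 0.4)),
                        seed = 1L) {
  if (!is.null(minibatch) && minibatch < 1) stopf("ci_protocol: minibatch must be >= 1")
  if (any(cutpoints <= 0 | cutpoints >= 1))
    stopf("ci_protocol: cutpoints must lie in (0, 1)")
  if (drift_tolerance < 0) stopf("ci_protocol: drift_tolerance must be >= 0")
  if (!any(cutpoints == 0.5)) cutpoints <- sort(c(cutpoints, 0.5))
  structure(list(max_hidden_layers = as.integer(max_hidden_layers),
                 node_schedule = as.integer(node_schedule),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 learning_rate = learning_rate, minibatch = minibatch,
                 cutpoints = cutpoints, drift_tolerance = drift_tolerance,
                 min_delta = min_delta, reg_ladder = reg_ladder,
                 seed = as.integer(seed)),
            class = "ci_protocol")
}

#' Desk-scale training protocol
#'
#' A reduced growth schedule for cohorts of a few thousand admissions:
#' fewer candidate widths/depths, fewer epochs, and a learning rate raised
#' so RMSprop converges within the small step budget. The drift tolerance
#' is relaxed to 0.12 because at a few thousand training rows a
#' generalization gap of that order is irreducible (no amount of L1/L2/
#' dropout removes it) and the validation MCC itself carries sampling
#' noise of a few hundredths.
#'
#' @param seed Integer seed.
#' @param epochs Epoch budget.
#' @return A `ci_protocol`.
#' @export
ci_protocol_desk <- function(seed = 1L, epochs = 15L) {
  ci_protocol(max_hidden_layers = 2L, node_schedule = c(8L, 16L),
              epochs = epochs, patience = 5L, learning_rate = 3e-3,
              drift_tolerance = 0.12, min_delta = 0.005,
              reg_ladder = list(
                list(l1 = 0, l2 = 0, dropout = 0),
                list(l1 = 1e-6, l2 = 1e-3, dropout = 0.2),
                list(l1 = 1e-5, l2 = 5e-2, dropout = 0.5)),
              seed = seed)
}

#' Train one prediction-horizon classifier under the growth protocol
#'
#' @param X_train,y_train Training feature matrix and 0/1 outcome.
#' @param X_val,y_val Validation partition (used for model selection and
#'   overfit monitoring only).
#' @param protocol A [ci_protocol()].
#' @param horizon Integer horizon index carried in the model object.
#' @return An object of class `ci_horizon_model` with the fitted network,
#'   the feature schema, standardization constants, the per-candidate
#'   training history, and the selected architecture.
#' @export
train_horizon_model <- function(X_train, y_train, X_val, y_val,
                                protocol = ci_protocol(), horizon = NA_integer_) {
  stopifnot(inherits(protocol, "ci_protocol"))
  if (length(unique(y_train)) < 2L)
    stopf("train_horizon_model: training outcomes contain a single class")
  if (length(unique(y_val)) < 2L)
    stopf("train_horizon_model: validation outcomes contain a single class")
  n <- nrow(X_train)
  mb <- protocol$minibatch %||% min(10000L, max(64L, ceiling(n / 10)))

  ctr <- colMeans(X_train)
  scl <- apply(X_train, 2L, sd); scl[scl < 1e-8] <- 1
  Xt <- sweep(sweep(X_train, 2L, ctr), 2L, scl, "/")
  Xv <- sweep(sweep(X_val, 2L, ctr), 2L, scl, "/")

  cand <- list(); ci <- 0L
  best <- NULL
  fit_one <- function(hidden, reg, seed) {
    mlp_fit(Xt, y_train, Xv, y_val, hidden = hidden,
            epochs = protocol$epochs, lr = protocol$learning_rate,
            minibatch = mb, l1 = reg$l1, l2 = reg$l2, dropout = reg$dropout,
            patience = protocol$patience, cutpoints = protocol$cutpoints,
            seed = seed)
  }

  fallback <- NULL                             # least-drift candidate, any reg
  overfit_fallback <- FALSE
  depth <- 1L
  repeat {
    depth_gain <- FALSE
    for (width in protocol$node_schedule) {
      hidden <- rep(width, depth)
      fit <- NULL
      for (ri in seq_along(protocol$reg_ladder)) {
        reg <- protocol$reg_ladder[[ri]]
        f <- fit_one(hidden, reg, child_seed(protocol$seed,
                                             sprintf("d%dw%dr%d", depth, width, ri)))
        drift <- f$train_mcc - f$val_mcc
        overfit <- drift > protocol$drift_tolerance
        ci <- ci + 1L
        cand[[ci]] <- data.table::data.table(
          depth = depth, width = width, l1 = reg$l1, l2 = reg$l2,
          dropout = reg$dropout, epochs_run = f$epoch,
          train_mcc = f$train_mcc, val_mcc = f$val_mcc, overfit = overfit)
        if (is.null(fallback) || drift < fallback$drift)
          fallback <- c(f, list(hidden = hidden, drift = drift))
        if (!overfit) { fit <- f; break }
      }
      if (is.null(fit)) {
        # regularization could not rescue overfitting: stop growing
        depth <- protocol$max_hidden_layers + 1L
        break
      }
      if (is.null(best) || fit$val_mcc > best$val_mcc + protocol$min_delta) {
        best <- c(fit, list(hidden = hidden))
        depth_gain <- TRUE
      } else break  # wider stopped helping at this depth
    }
    depth <- depth + 1L
    if (depth > protocol$max_hidden_layers || !depth_gain) break
  }
  if (is.null(best)) {
    # every candidate overfit beyond tolerance: keep the least-drift one and
    # say so, rather than failing the whole pipeline on a small cohort
    warning(sprintf(paste0("train_horizon_model: no candidate met the drift ",
                           "tolerance %.3f; keeping the least-drift model ",
                           "(drift %.3f)"),
                    protocol$drift_tolerance, fallback$drift))
    best <- fallback
    overfit_fallback <- TRUE
  }

  structure(list(
    horizon = horizon, net = best$net, hidden = best$hidden,
    center = ctr, scale = scl, features = colnames(X_train),
    val_mcc = best$val_mcc, train_mcc = best$train_mcc,
    selected_epoch = best$epoch, overfit_fallback = overfit_fallback,
    history = data.table::rbindlist(cand),
    protocol = protocol
  ), class = "ci_horizon_model")
}

#' @export
print.ci_horizon_model <- function(x, ...) {
  cat("<ci_horizon_model>\n")
  cat(sprintf("  horizon: %s | hidden layers: %s | validation MCC at 0.5: %.3f\n",
              if (is.na(x$horizon)) "?" else paste0("H", x$horizon),
              paste(x$hidden, collapse = "-"), x$val_mcc))
  cat(sprintf("  %d features, %d candidates explored\n",
              length(x$features), nrow(x$history)))
  invisible(x)
}

#' Raw model scores for new rows
#'
#' Deterministic given the fitted weights; row order only permutes the
#' output. The feature schema must match the training schema exactly.
#'
#' @param model A `ci_horizon_model`.
#' @param X Feature matrix with the training columns.
#' @return Scores in (0, 1).
#' @export
predict_raw <- function(model, X) {
  stopifnot(inherits(model, "ci_horizon_model"))
  if (is.null(colnames(X)))
    stopf("predict_raw: feature matrix lacks column names")
  missing <- setdiff(model$features, colnames(X))
  extra <- setdiff(colnames(X), model$features)
  if (length(missing) || length(extra))
    stopf("predict_raw: schema mismatch (missing: %s; extra: %s)",
          paste(head(missing, 5L), collapse = ", ") %||% "",
          paste(head(extra, 5L), collapse = ", ") %||% "")
  X <- X[, model$features, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  mlp_predict(model$net, Xs)
}

#' Convert scores to binary care-location labels
#'
#' A score strictly above the cut point is classified ICU; a score equal to
#' the cut point is classified routine (strict-inequality convention).
#'
#' @param scores Numeric scores.
#' @param cutpoint Decision threshold in (0, 1).
#' @return Integer vector, 1 = ICU, 0 = routine.
#' @export
classify <- function(scores, cutpoint = 0.5) {
  if (cutpoint <= 0 || cutpoint >= 1) stopf("classify: cutpoint must be in (0, 1)")
  as.integer(scores > cutpoint)
}
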