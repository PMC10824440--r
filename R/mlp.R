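# Minimal fully connected feed-forward network for binary classification.
# ReLU hidden layers, single logistic output, binary cross-entropy loss,
# Glorot-uniform initialization, RMSprop updates, optional L1/L2 penalties
# and inverted dropout. Matrix algebra only; sized for desk-scale cohorts.

mlp_init <- function(n_in, hidden) {
  sizes <- c(n_in, hidden, 1L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b, hidden = hidden)
}

mlp_forward <- function(net, X, dropout = 0, train = FALSE) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  masks <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], "+")
    if (l < L) {
      Z[Z < 0] <- 0
      if (train && dropout > 0) {
        m <- matrix(runif(length(Z)) >= dropout, nrow(Z), ncol(Z)) / (1 - dropout)
        Z <- Z * m
        masks[[l]] <- m
      }
    } else {
      Z <- plogis(Z)
    }
    A[[l + 1L]] <- Z
  }
  list(A = A, masks = masks)
}

mlp_predict <- function(net, X) {
  p <- mlp_forward(net, X)$A[[length(net$W) + 1L]][, 1L]
  clamp(p, 1e-7, 1 - 1e-7)
}

# One RMSprop minibatch step; returns updated net and caches.
mlp_step <- function(net, cache, X, y, lr, l1, l2, dropout, rho = 0.9, eps = 1e-8) {
  L <- length(net$W)
  fw <- mlp_forward(net, X, dropout = dropout, train = TRUE)
  A <- fw$A
  n <- nrow(X)
  delta <- (A[[L + 1L]] - y) / n          # dBCE/dz for logistic output
  for (l in rev(seq_len(L))) {
    gW <- crossprod(A[[l]], delta) + l2 * net$W[[l]] + l1 * sign(net$W[[l]])
    gb <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$W[[l]])
      delta[A[[l]] <= 0] <- 0
      if (!is.null(fw$masks[[l - 1L]])) delta <- delta * fw$masks[[l - 1L]]
    }
    cache$W[[l]] <- rho * cache$W[[l]] + (1 - rho) * gW^2
    cache$b[[l]] <- rho * cache$b[[l]] + (1 - rho) * gb^2
    net$W[[l]] <- net$W[[l]] - lr * gW / (sqrt(cache$W[[l]]) + eps)
    net$b[[l]] <- net$b[[l]] - lr * gb / (sqrt(cache$b[[l]]) + eps)
  }
  list(net = net, cache = cache)
}

mlp_fit <- function(X, y, Xval, yval, hidden, epochs, lr, minibatch,
                    l1 = 0, l2 = 0, dropout = 0, patience = 6L,
                    cutpoints = c(0.15, 0.5, 0.9), seed = NULL) {
  with_seed(seed, {
    net <- mlp_init(ncol(X), hidden)
    cache <- list(W = lapply(net$W, function(w) w * 0),
                  b = lapply(net$b, function(b) b * 0))
    n <- nrow(X)
    best <- list(mcc = -Inf, net = net, epoch = 0L)
    hist <- vector("list", epochs)
    stale <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = minibatch)
      for (s in starts) {
        rows <- ord[s:min(s + minibatch - 1L, n)]
        st <- mlp_step(net, cache, X[rows, , drop = FALSE], y[rows],
                       lr, l1, l2, dropout)
        net <- st$net; cache <- st$cache
      }
      pt <- mlp_predict(net, X)
      pv <- mlp_predict(net, Xval)
      loss <- -mean(y * log(pt) + (1 - y) * log(1 - pt))
      if (!is.finite(loss))
        stopf("mlp_fit: non-finite training loss at epoch %d", ep)
      tr_m <- vapply(cutpoints, function(ct) mcc(as.integer(pt > ct), y), 0)
      va_m <- vapply(cutpoints, function(ct) mcc(as.integer(pv > ct), yval), 0)
      i5 <- which(cutpoints == 0.5)[1]
      hist[[ep]] <- data.table::data.table(
        epoch = ep, loss = loss,
        cutpoint = cutpoints, train_mcc = tr_m, val_mcc = va_m)
      if (va_m[i5] > best$mcc + 1e-6) {
        best <- list(mcc = va_m[i5], net = net, epoch = ep, train_mcc = tr_m[i5])
        stale <- 0L
      } else stale <- stale + 1L
      if (stale >= patience) break
    }
    list(net = best$net, val_mcc = best$mcc, train_mcc = best$train_mcc,
         epoch = best$epoch,
         history = data.table::rbindlist(hist[!vapply(hist, is.null, TRUE)]))
  })
}

#' Matthews correlation coefficient
#'
#' MCC of a binary prediction against binary truth. For a degenerate
#' confusion matrix (any zero marginal) the value is defined as 0.
#'
#' @param pred,truth Vectors coded 0/1.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}
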