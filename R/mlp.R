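# Multilayer perceptron for binary sequence classification.
#
# Architecture: dense layers of 128, 64 and 32 units, each followed by
# batch normalization, ReLU activation and 20% dropout, then a single
# sigmoid output unit; binary cross-entropy loss minimised with Adam.
# Implemented directly on R matrices: the input width (4L one-hot
# columns, 140 for the 35-nt core) and layer sizes are small enough
# that BLAS-backed matrix products train in seconds.

.mlp_init <- function(n_in, hidden, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- c(n_in, hidden)
  layers <- vector("list", length(hidden))
  for (i in seq_along(hidden)) {
    fan_in <- sizes[i]
    # He initialisation for ReLU layers
    layers[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * hidden[i], 0, sqrt(2 / fan_in)),
                 fan_in, hidden[i]),
      gamma = rep(1, hidden[i]),
      beta = rep(0, hidden[i]),
      run_mean = rep(0, hidden[i]),
      run_var = rep(1, hidden[i]))
  }
  out <- list(W = matrix(stats::rnorm(hidden[length(hidden)], 0,
                                      sqrt(1 / hidden[length(hidden)])),
                         hidden[length(hidden)], 1L),
              b = 0)
  list(layers = layers, out = out)
}

.adam_new <- function(par) {
  lapply(par, function(p) list(m = p * 0, v = p * 0))
}

.adam_step <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-7) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

.mlp_forward <- function(net, X, training = FALSE, dropout = 0.2,
                         bn_eps = 1e-3, bn_momentum = 0.99) {
  cache <- list()
  A <- X
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    Z <- A %*% ly$W
    if (training) {
      mu <- colMeans(Z)
      va <- colMeans(sweep(Z, 2L, mu)^2)
      ly$run_mean <- bn_momentum * ly$run_mean + (1 - bn_momentum) * mu
      ly$run_var <- bn_momentum * ly$run_var + (1 - bn_momentum) * va
      net$layers[[i]] <- ly
    } else {
      mu <- ly$run_mean
      va <- ly$run_var
    }
    inv_sd <- 1 / sqrt(va + bn_eps)
    Zc <- sweep(Z, 2L, mu)
    Zhat <- sweep(Zc, 2L, inv_sd, "*")
    BN <- sweep(sweep(Zhat, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
    H <- pmax(BN, 0)
    if (training && dropout > 0) {
      mask <- matrix(stats::runif(length(H)) >= dropout, nrow(H)) /
        (1 - dropout)
      H <- H * mask
    } else {
      mask <- NULL
    }
    cache[[i]] <- list(A_in = A, Z = Z, Zc = Zc, Zhat = Zhat, BN = BN,
                       inv_sd = inv_sd, mask = mask)
    A <- H
  }
  logits <- A %*% net$out$W + net$out$b
  p <- 1 / (1 + exp(-logits))
  list(net = net, p = as.numeric(p), A_last = A, cache = cache)
}

.mlp_backward <- function(net, fw, y, dropout = 0.2) {
  n <- length(y)
  grads <- list(layers = vector("list", length(net$layers)), out = NULL)
  dlogits <- matrix((fw$p - y) / n, ncol = 1L)
  grads$out <- list(W = crossprod(fw$A_last, dlogits),
                    b = sum(dlogits))
  dA <- dlogits %*% t(net$out$W)
  for (i in rev(seq_along(net$layers))) {
    cc <- fw$cache[[i]]
    ly <- net$layers[[i]]
    if (!is.null(cc$mask)) dA <- dA * cc$mask
    dBN <- dA * (cc$BN > 0)
    dgamma <- colSums(dBN * cc$Zhat)
    dbeta <- colSums(dBN)
    dZhat <- sweep(dBN, 2L, ly$gamma, "*")
    m <- nrow(dZhat)
    # batch-norm backward (population statistics over the batch)
    dvar <- colSums(dZhat * cc$Zc) * (-0.5) * cc$inv_sd^3
    dmu <- colSums(sweep(dZhat, 2L, -cc$inv_sd, "*")) +
      dvar * colMeans(-2 * cc$Zc)
    dZ <- sweep(dZhat, 2L, cc$inv_sd, "*") +
      sweep(cc$Zc, 2L, 2 * dvar / m, "*") +
      matrix(dmu / m, m, length(dmu), byrow = TRUE)
    grads$layers[[i]] <- list(W = crossprod(cc$A_in, dZ),
                              gamma = dgamma, beta = dbeta)
    dA <- dZ %*% t(ly$W)
  }
  grads
}

#' Train the multilayer perceptron
#'
#' @param x Numeric matrix of one-hot features (rows = sequences).
#' @param y Numeric/integer vector of labels (1 = neutral,
#'   0 = deleterious).
#' @param hidden Hidden-layer widths.
#' @param dropout Dropout rate after every hidden layer.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed Seed for weight initialisation, shuffling, and dropout.
#' @return Object of class `mlp` holding the fitted weights and batch
#'   statistics.
#' @export
mlp_train <- function(x, y, hidden = c(128L, 64L, 32L), dropout = 0.2,
                      lr = 0.005, epochs = 100L, batch_size = 1024L,
                      seed = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  net <- .mlp_init(ncol(x), hidden, seed = seed)
  flat <- function(net) {
    c(unlist(lapply(net$layers, function(l) list(l$W, l$gamma, l$beta)),
             recursive = FALSE),
      list(net$out$W, net$out$b))
  }
  adam <- .adam_new(flat(net))
  t <- 0L
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      if (length(idx) < 2L) next  # batch norm needs a batch
      fw <- .mlp_forward(net, x[idx, , drop = FALSE], training = TRUE,
                         dropout = dropout)
      net <- fw$net
      gr <- .mlp_backward(net, fw, y[idx], dropout = dropout)
      t <- t + 1L
      k <- 0L
      for (i in seq_along(net$layers)) {
        for (fld in c("W", "gamma", "beta")) {
          k <- k + 1L
          upd <- .adam_step(net$layers[[i]][[fld]], gr$layers[[i]][[fld]],
                            adam[[k]], lr, t)
          net$layers[[i]][[fld]] <- upd$p
          adam[[k]] <- upd$st
        }
      }
      k <- k + 1L
      upd <- .adam_step(net$out$W, gr$out$W, adam[[k]], lr, t)
      net$out$W <- upd$p
      adam[[k]] <- upd$st
      k <- k + 1L
      upd <- .adam_step(net$out$b, gr$out$b, adam[[k]], lr, t)
      net$out$b <- upd$p
      adam[[k]] <- upd$st
    }
  }
  structure(list(net = net, hidden = hidden, n_in = ncol(x),
                 dropout = dropout, lr = lr, epochs = epochs,
                 batch_size = batch_size),
            class = "mlp")
}

#' Predict class probabilities from a fitted MLP
#'
#' @param object A fitted [mlp_train()] model.
#' @param x One-hot feature matrix.
#' @param ... Unused.
#' @return Numeric vector of neutral-class probabilities.
#' @export
predict.mlp <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$n_in) {
    stop("feature width ", ncol(x), " does not match the model (",
         object$n_in, ")")
  }
  .mlp_forward(object$net, x, training = FALSE)$p
}
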