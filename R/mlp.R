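# Seeded multilayer perceptron with ReLU hidden layers, inverted dropout,
# L2 weight decay, Adam, mini-batches and validation-loss early stopping.
# Written in base matrix algebra: deterministic in single-threaded mode under
# a fixed seed, which the cross-validation protocol relies on.

mlp_init <- function(widths) {
  n <- length(widths) - 1L
  W <- vector("list", n)
  b <- vector("list", n)
  for (l in seq_len(n)) {
    # He initialization for ReLU layers
    W[[l]] <- matrix(rnorm(widths[l] * widths[l + 1], sd = sqrt(2 / widths[l])),
                     widths[l], widths[l + 1])
    b[[l]] <- numeric(widths[l + 1])
  }
  list(W = W, b = b, widths = widths)
}

mlp_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass; when training, applies inverted dropout after each hidden
# activation and returns the cached activations and masks for backprop.
mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  n_layers <- length(net$W)
  A <- list(X)
  masks <- vector("list", n_layers - 1L)
  for (l in seq_len(n_layers)) {
    Z <- A[[l]] %*% net$W[[l]] + matrix(net$b[[l]], nrow(A[[l]]),
                                        length(net$b[[l]]), byrow = TRUE)
    if (l < n_layers) {
      H <- pmax(Z, 0)
      if (training && dropout > 0) {
        m <- matrix(runif(length(H)) >= dropout, nrow(H), ncol(H)) / (1 - dropout)
        H <- H * m
        masks[[l]] <- m
      }
      A[[l + 1L]] <- H
    } else {
      A[[l + 1L]] <- mlp_softmax(Z)
    }
  }
  list(A = A, masks = masks)
}

# Mean cross-entropy plus the L2 penalty on weights (not biases).
mlp_loss <- function(net, probs, Y, l2) {
  ce <- -mean(log(pmax(rowSums(probs * Y), 1e-12)))
  if (l2 > 0) ce <- ce + l2 / 2 * sum(vapply(net$W, function(w) sum(w^2),
                                             numeric(1)))
  ce
}

mlp_backward <- function(net, cache, Y, dropout, l2) {
  n_layers <- length(net$W)
  n <- nrow(Y)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  delta <- (cache$A[[n_layers + 1L]] - Y) / n  # softmax + CE gradient
  for (l in n_layers:1) {
    gW[[l]] <- crossprod(cache$A[[l]], delta) + l2 * net$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(net$W[[l]])
      if (dropout > 0 && !is.null(cache$masks[[l - 1L]])) {
        delta <- delta * cache$masks[[l - 1L]]
      }
      delta <- delta * (cache$A[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

adam_state <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0), vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0), vb = lapply(net$b, function(b) b * 0),
       t = 0L)
}

adam_step <- function(net, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * grads$W[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grads$b[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, st = st)
}

# Train the MLP.  X standardized n x d matrix, y integer class index 1..K.
# Returns the best-validation-loss weights.
mlp_train <- function(X, y, widths, lr = 0.01, batch_size = 32L,
                      epochs = 50L, dropout = 0.3, l2 = 0.001,
                      patience = 10L, val_frac = 0.2, seed = 1L) {
  K <- widths[length(widths)]
  withr::with_seed(seed, {
    # stratified inner train/validation split
    val_idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
      n_val <- max(1L, round(length(ix) * val_frac))
      if (length(ix) < 2) stop("fewer than 2 samples in a class for the ",
                               "inner train/validation split")
      sample(ix, n_val)
    }), use.names = FALSE)
    tr_idx <- setdiff(seq_along(y), val_idx)
    onehot <- function(yy) {
      Y <- matrix(0, length(yy), K)
      Y[cbind(seq_along(yy), yy)] <- 1
      Y
    }
    Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- onehot(y[tr_idx])
    Xva <- X[val_idx, , drop = FALSE]; Yva <- onehot(y[val_idx])
    net <- mlp_init(widths)
    st <- adam_state(net)
    best <- list(loss = Inf, net = net, epoch = 0L)
    stall <- 0L
    history <- numeric(0)
    for (ep in seq_len(epochs)) {
      ord <- sample(nrow(Xtr))
      for (start in seq(1, nrow(Xtr), by = batch_size)) {
        ix <- ord[start:min(start + batch_size - 1L, nrow(Xtr))]
        cache <- mlp_forward(net, Xtr[ix, , drop = FALSE], dropout,
                             training = TRUE)
        grads <- mlp_backward(net, cache, Ytr[ix, , drop = FALSE], dropout, l2)
        upd <- adam_step(net, grads, st, lr)
        net <- upd$net; st <- upd$st
      }
      probs <- mlp_forward(net, Xva)$A[[length(net$W) + 1L]]
      vloss <- mlp_loss(net, probs, Yva, l2 = 0)
      history <- c(history, vloss)
      if (vloss < best$loss - 1e-9) {
        best <- list(loss = vloss, net = net, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    list(net = best$net, val_loss = best$loss, best_epoch = best$epoch,
         epochs_run = length(history), history = history)
  })
}

mlp_predict_prob <- function(net, X) {
  mlp_forward(net, X)$A[[length(net$W) + 1L]]
}
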