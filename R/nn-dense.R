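# Compact fully-connected neural-network engine.
#
# A minimal multilayer perceptron for binary classification: rectified
# hidden layers, a single sigmoid output, weighted binary cross-entropy,
# Adam or RMSprop updates, and early stopping on the training loss with
# best-weight restoration. Everything runs on base-R matrix algebra (BLAS),
# which is ample at the scale of an 8-feature PROM model or a 2-input
# fusion head. Used by `fit_tabular(kind = "mlp")` and the `shallow_net`
# fusion head; the convolutional engine lives in nn-conv.R.

nn_dense_init <- function(sizes, seed) {
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1), function(l) {
      fan_in <- sizes[l]
      list(W = matrix(rnorm(fan_in * sizes[l + 1], 0, sqrt(2 / fan_in)),
                      fan_in, sizes[l + 1]),
           b = rep(0, sizes[l + 1]))
    })
  })
}

nn_dense_forward <- function(layers, X) {
  L <- length(layers)
  a <- vector("list", L + 1)
  z <- vector("list", L)
  a[[1]] <- X
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    a[[l + 1]] <- if (l < L) relu(z[[l]]) else sigmoid(z[[l]])
  }
  list(a = a, z = z, p = as.vector(a[[L + 1]]))
}

nn_dense_loss <- function(p, y, w) {
  eps <- 1e-12
  -mean(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
}

# One optimizer step; state holds first/second moment caches per tensor.
nn_opt_step <- function(theta, grad, state, key, optimizer, lr, t) {
  g <- grad
  zero <- g * 0
  if (optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    m <- b1 * (state[[key]]$m %||% zero) + (1 - b1) * g
    v <- b2 * (state[[key]]$v %||% zero) + (1 - b2) * g^2
    state[[key]] <- list(m = m, v = v)
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    theta <- theta - lr * mh / (sqrt(vh) + eps)
  } else {  # rmsprop
    rho <- 0.9; eps <- 1e-8
    v <- rho * (state[[key]]$v %||% zero) + (1 - rho) * g^2
    state[[key]] <- list(v = v)
    theta <- theta - lr * g / (sqrt(v) + eps)
  }
  list(theta = theta, state = state)
}

nn_dense_fit <- function(X, y, hidden = c(16, 8), epochs = 200,
                         batch_size = 32, lr = 1e-3,
                         optimizer = c("adam", "rmsprop"),
                         class_weights = NULL, patience = 10,
                         min_delta = 1e-5, weight_decay = 0.03, seed = 1) {
  optimizer <- match.arg(optimizer)
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class; cannot fit a classifier",
         call. = FALSE)
  }
  if (is.null(class_weights)) class_weights <- c(1, 1)
  w <- class_weights[y + 1]
  w <- w / mean(w)

  sizes <- c(ncol(X), hidden, 1)
  layers <- nn_dense_init(sizes, derive_seed(seed, 1))
  L <- length(layers)
  state <- list()
  step <- 0L
  trace <- numeric(0)
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  wait <- 0L

  with_seed(derive_seed(seed, 2), {
    n <- nrow(X)
    for (epoch in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        rows <- idx[start:min(start + batch_size - 1, n)]
        nb <- length(rows)
        fw <- nn_dense_forward(layers, X[rows, , drop = FALSE])
        delta <- matrix((fw$p - y[rows]) * w[rows] / nb, ncol = 1)
        step <- step + 1L
        for (l in rev(seq_len(L))) {
          # L2 decay on weights (not biases) tempers memorisation of rare
          # feature patterns under heavy class weighting
          gW <- crossprod(fw$a[[l]], delta) + weight_decay * layers[[l]]$W
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(layers[[l]]$W)) * (fw$z[[l - 1]] > 0)
          }
          up <- nn_opt_step(layers[[l]]$W, gW, state, paste0("W", l),
                            optimizer, lr, step)
          layers[[l]]$W <- up$theta; state <- up$state
          up <- nn_opt_step(layers[[l]]$b, gb, state, paste0("b", l),
                            optimizer, lr, step)
          layers[[l]]$b <- up$theta; state <- up$state
        }
      }
      loss <- nn_dense_loss(nn_dense_forward(layers, X)$p, y, w)
      trace <- c(trace, loss)
      if (loss < best$loss - min_delta) {
        best <- list(loss = loss, layers = layers, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })

  structure(list(
    layers = best$layers, sizes = sizes,
    training_meta = list(loss_trace = trace, best_epoch = best$epoch,
                         best_loss = best$loss, epochs_run = length(trace),
                         optimizer = optimizer, lr = lr,
                         batch_size = batch_size,
                         class_weights = class_weights,
                         weight_decay = weight_decay, seed = seed)
  ), class = "dense_net")
}

nn_dense_predict <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != net$sizes[1]) {
    stop(sprintf("feature count mismatch: model expects %d columns, got %d",
                 net$sizes[1], ncol(X)), call. = FALSE)
  }
  nn_dense_forward(net$layers, X)$p
}
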