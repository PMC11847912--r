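# Compact convolutional network engine.
#
# A small image classifier built on base-R matrix algebra: an average-pool
# stem that brings the standardised 256 x 256 input down to the working
# resolution, a stack of 3x3 same-padded convolution blocks (ReLU, optional
# 2x2 max-pool), global average pooling and a single sigmoid unit.
# Convolutions are evaluated as patch-matrix products (im2col) with cached
# index maps, so each layer is one BLAS call per image. RMSprop updates,
# weighted binary cross-entropy, early stopping on the training loss
# evaluated every `eval_every` optimisation steps with best-weight restore.

# Index map gathering 3x3 zero-padded patches of an (H, W, C) array into an
# (H*W) x (9*C) matrix; rows follow column-major output order.
conv_idx <- function(H, W, C) {
  Hp <- H + 2L
  Wp <- W + 2L
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L * C)
  col <- 0L
  for (c in seq_len(C)) for (dj in -1:1) for (di in -1:1) {
    col <- col + 1L
    idx[, col] <- (c - 1L) * Hp * Wp + (j + dj) * Hp + (i + di + 1L)
  }
  idx
}

pad1 <- function(x) {
  d <- dim(x)
  xp <- array(0, d + c(2L, 2L, 0L))
  xp[2:(d[1] + 1), 2:(d[2] + 1), ] <- x
  xp
}

avg_pool <- function(x, f) {
  if (f == 1L) return(x)
  d <- dim(x)
  out <- 0
  for (a in seq_len(f)) for (b in seq_len(f)) {
    out <- out + x[seq(a, d[1], f), seq(b, d[2], f), , drop = FALSE]
  }
  out / f^2
}

maxpool_fwd <- function(A) {
  d <- dim(A)
  o1 <- seq(1, d[1], 2); e1 <- seq(2, d[1], 2)
  o2 <- seq(1, d[2], 2); e2 <- seq(2, d[2], 2)
  s <- list(A[o1, o2, , drop = FALSE], A[e1, o2, , drop = FALSE],
            A[o1, e2, , drop = FALSE], A[e1, e2, , drop = FALSE])
  M <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- array(FALSE, dim(M))
  masks <- vector("list", 4)
  for (q in 1:4) {
    masks[[q]] <- (s[[q]] == M) & !taken
    taken <- taken | masks[[q]]
  }
  list(M = M, masks = masks, in_dim = d)
}

maxpool_bwd <- function(pool, dM) {
  d <- pool$in_dim
  dA <- array(0, d)
  o1 <- seq(1, d[1], 2); e1 <- seq(2, d[1], 2)
  o2 <- seq(1, d[2], 2); e2 <- seq(2, d[2], 2)
  dA[o1, o2, ] <- dM * pool$masks[[1]]
  dA[e1, o2, ] <- dM * pool$masks[[2]]
  dA[o1, e2, ] <- dM * pool$masks[[3]]
  dA[e1, e2, ] <- dM * pool$masks[[4]]
  dA
}

cnn_architecture <- function(input_size = 256, stem_pool = 4,
                             filters = c(8, 16, 16, 32),
                             pool = c(TRUE, TRUE, TRUE, FALSE)) {
  stopifnot(length(filters) == length(pool),
            input_size %% stem_pool == 0)
  s <- input_size / stem_pool
  dims <- list()
  C <- 3L
  for (l in seq_along(filters)) {
    dims[[l]] <- c(H = s, W = s, C = C)
    C <- filters[l]
    if (pool[l]) s <- s / 2
  }
  stopifnot(s >= 4)  # feature map must retain spatial extent for heatmaps
  list(input_size = input_size, stem_pool = stem_pool, filters = filters,
       pool = pool, layer_dims = dims, map_size = s, n_features = C)
}

cnn_init <- function(arch, seed) {
  with_seed(seed, {
    conv <- lapply(seq_along(arch$filters), function(l) {
      d <- arch$layer_dims[[l]]
      fan_in <- 9 * d[["C"]]
      list(W = matrix(rnorm(fan_in * arch$filters[l], 0, sqrt(2 / fan_in)),
                      fan_in, arch$filters[l]),
           b = rep(0, arch$filters[l]))
    })
    dense <- list(w = rnorm(arch$n_features, 0, sqrt(1 / arch$n_features)),
                  b = 0)
    idx <- lapply(arch$layer_dims, function(d)
      conv_idx(d[["H"]], d[["W"]], d[["C"]]))
    list(arch = arch, conv = conv, dense = dense, idx = idx)
  })
}

# Forward pass for one stem-pooled image; keep = TRUE retains patch
# matrices and pool masks for backprop.
cnn_forward <- function(net, x, keep = FALSE) {
  arch <- net$arch
  cache <- list()
  A <- x
  for (l in seq_along(net$conv)) {
    d <- dim(A)
    P <- matrix(pad1(A)[net$idx[[l]]], nrow = d[1] * d[2])
    Z <- P %*% net$conv[[l]]$W
    Z <- sweep(Z, 2, net$conv[[l]]$b, `+`)
    Anew <- array(relu(Z), c(d[1], d[2], ncol(Z)))
    pool <- NULL
    if (arch$pool[l]) {
      pool <- maxpool_fwd(Anew)
      Aout <- pool$M
    } else {
      Aout <- Anew
    }
    if (keep) cache[[l]] <- list(P = P, Z = Z, pool = pool, in_dim = d)
    A <- Aout
  }
  dmap <- dim(A)
  g <- colMeans(matrix(A, dmap[1] * dmap[2], dmap[3]))
  z <- sum(g * net$dense$w) + net$dense$b
  list(p = sigmoid(z), g = g, maps = A, cache = cache)
}

# Backward pass; returns gradients in the same shapes as the parameters.
cnn_backward <- function(net, fw, y, weight = 1) {
  arch <- net$arch
  dmap <- dim(fw$maps)
  dz <- (fw$p - y) * weight
  gw <- dz * fw$g
  gb <- dz
  dg <- dz * net$dense$w
  dA <- array(rep(dg / (dmap[1] * dmap[2]), each = dmap[1] * dmap[2]), dmap)
  gconv <- vector("list", length(net$conv))
  for (l in rev(seq_along(net$conv))) {
    cc <- fw$cache[[l]]
    if (arch$pool[l]) dA <- maxpool_bwd(cc$pool, dA)
    d <- cc$in_dim
    dZ <- matrix(dA, d[1] * d[2]) * (cc$Z > 0)
    gconv[[l]] <- list(W = crossprod(cc$P, dZ), b = colSums(dZ))
    if (l > 1) {
      dP <- dZ %*% t(net$conv[[l]]$W)
      acc <- rowsum(as.vector(dP), group = as.vector(net$idx[[l]]))
      dxp <- numeric((d[1] + 2) * (d[2] + 2) * d[3])
      dxp[as.integer(rownames(acc))] <- acc
      dA <- array(dxp, c(d[1] + 2, d[2] + 2, d[3]))[2:(d[1] + 1),
                                                    2:(d[2] + 1), ,
                                                    drop = FALSE]
    }
  }
  list(conv = gconv, dense = list(w = gw, b = gb))
}

cnn_loss <- function(p, y, w) {
  eps <- 1e-12
  -mean(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
}

cnn_predict_pooled <- function(net, pooled) {
  vapply(pooled, function(x) cnn_forward(net, x)$p, numeric(1))
}

cnn_training_loss <- function(net, pooled, y, w) {
  cnn_loss(cnn_predict_pooled(net, pooled), y, w)
}
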