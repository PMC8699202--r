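# Minimal BLAS-backed neural-network engine for the two-branch CCS network:
# valid 1D convolutions implemented as im2col + matrix product, pair
# max/average pooling, dense layers, ReLU, He initialization, Adam, MAE loss.
# All tensors use the layout (batch, position, channel).

.im2col <- function(X, K) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; C <- d[3L]
  P <- L - K + 1L
  out <- matrix(0, B * P, K * C)
  for (k in seq_len(K)) {
    Xk <- X[, k:(k + P - 1L), , drop = FALSE]
    dim(Xk) <- c(B * P, C)
    out[, ((k - 1L) * C + 1L):(k * C)] <- Xk
  }
  out
}

.col2im <- function(dcol, B, L, C, K) {
  P <- L - K + 1L
  dX <- array(0, c(B, L, C))
  for (k in seq_len(K)) {
    dk <- dcol[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
    dim(dk) <- c(B, P, C)
    dX[, k:(k + P - 1L), ] <- dX[, k:(k + P - 1L), , drop = FALSE] + dk
  }
  dX
}

.conv_forward <- function(X, W, b, relu = TRUE) {
  d <- dim(X); B <- d[1L]; K <- nrow(W) / d[3L]
  P <- d[2L] - K + 1L
  col <- .im2col(X, K)
  Z <- col %*% W
  Z <- Z + rep(b, each = nrow(Z))
  mask <- NULL
  if (relu) { mask <- Z > 0; Z <- Z * mask }
  A <- Z
  dim(A) <- c(B, P, ncol(W))
  list(out = A, col = col, mask = mask, in_dim = d)
}

.conv_backward <- function(dA, cache, W) {
  d <- dim(dA); B <- d[1L]
  dZ <- dA
  dim(dZ) <- c(B * d[2L], d[3L])
  if (!is.null(cache$mask)) dZ <- dZ * cache$mask
  dW <- crossprod(cache$col, dZ)
  db <- colSums(dZ)
  dcol <- tcrossprod(dZ, W)
  K <- nrow(W) / cache$in_dim[3L]
  dX <- .col2im(dcol, B, cache$in_dim[2L], cache$in_dim[3L], K)
  list(dX = dX, dW = dW, db = db)
}

.pool_forward <- function(X, type = "max") {
  d <- dim(X); P <- d[2L]; Pp <- P %/% 2L
  i1 <- seq(1L, 2L * Pp, by = 2L); i2 <- i1 + 1L
  X1 <- X[, i1, , drop = FALSE]; X2 <- X[, i2, , drop = FALSE]
  if (type == "max") {
    mask <- X1 >= X2
    list(out = pmax(X1, X2), mask = mask, in_dim = d)
  } else {
    list(out = (X1 + X2) / 2, mask = NULL, in_dim = d)
  }
}

.pool_backward <- function(dY, cache) {
  d <- cache$in_dim; Pp <- dim(dY)[2L]
  dX <- array(0, d)
  i1 <- seq(1L, 2L * Pp, by = 2L); i2 <- i1 + 1L
  if (!is.null(cache$mask)) {
    dX[, i1, ] <- dY * cache$mask
    dX[, i2, ] <- dY * !cache$mask
  } else {
    dX[, i1, ] <- dY / 2
    dX[, i2, ] <- dY / 2
  }
  dX
}

.dense_forward <- function(X, W, b, relu = TRUE) {
  Z <- X %*% W
  Z <- Z + rep(b, each = nrow(Z))
  mask <- NULL
  if (relu) { mask <- Z > 0; Z <- Z * mask }
  list(out = Z, X = X, mask = mask)
}

.dense_backward <- function(dY, cache, W) {
  dZ <- if (is.null(cache$mask)) dY else dY * cache$mask
  list(dX = tcrossprod(dZ, W), dW = crossprod(cache$X, dZ), db = colSums(dZ))
}

.he_matrix <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

# Initialize all parameters of a network config with He (ReLU-oriented) init.
.init_params <- function(cfg) {
  params <- list()
  cin <- cfg$in_channels
  for (l in seq_along(cfg$conv_channels)) {
    cout <- cfg$conv_channels[l]
    params[[paste0("conv", l, "_W")]] <- .he_matrix(cfg$kernel * cin, cout)
    params[[paste0("conv", l, "_b")]] <- numeric(cout)
    cin <- cout
  }
  if (cfg$variant == "full") {
    nin <- cfg$global_length
    for (l in seq_along(cfg$dense_branch)) {
      nout <- cfg$dense_branch[l]
      params[[paste0("dense", l, "_W")]] <- .he_matrix(nin, nout)
      params[[paste0("dense", l, "_b")]] <- numeric(nout)
      nin <- nout
    }
  }
  params$head1_W <- .he_matrix(cfg$merge_length, cfg$head)
  params$head1_b <- numeric(cfg$head)
  params$head2_W <- .he_matrix(cfg$head, 1L)
  params$head2_b <- numeric(1L)
  params
}

# Full forward pass. X: (B, L, 323) array; G: (B, G) matrix.
# Returns predictions on the scaled target scale plus caches when training.
.net_forward <- function(params, cfg, X, G, training = FALSE) {
  caches <- if (training) list() else NULL
  if (!is.null(cfg$inv_spatial_scale)) {
    d <- dim(X)
    X <- X * rep(cfg$inv_spatial_scale, each = d[1L] * d[2L])
    G <- G * rep(cfg$inv_global_scale, each = nrow(G))
  }
  A <- X
  for (l in seq_along(cfg$conv_channels)) {
    cf <- .conv_forward(A, params[[paste0("conv", l, "_W")]],
                        params[[paste0("conv", l, "_b")]])
    A <- cf$out
    if (training) caches[[paste0("conv", l)]] <- cf[c("col", "mask", "in_dim")]
    if (l == cfg$pool_after) {
      pf <- .pool_forward(A, cfg$pool_type)
      A <- pf$out
      if (training) caches$pool <- pf[c("mask", "in_dim")]
    }
  }
  flat_dim <- dim(A)
  dim(A) <- c(flat_dim[1L], flat_dim[2L] * flat_dim[3L])
  if (cfg$variant == "full") {
    D <- G
    for (l in seq_along(cfg$dense_branch)) {
      df <- .dense_forward(D, params[[paste0("dense", l, "_W")]],
                           params[[paste0("dense", l, "_b")]])
      D <- df$out
      if (training) caches[[paste0("dense", l)]] <- df[c("X", "mask")]
    }
    branch <- D
  } else {
    branch <- G   # six global scalars merged directly with the flatten output
  }
  M <- cbind(A, branch)
  h1 <- .dense_forward(M, params$head1_W, params$head1_b)
  h2 <- .dense_forward(h1$out, params$head2_W, params$head2_b, relu = FALSE)
  if (training) {
    caches$head1 <- h1[c("X", "mask")]
    caches$head2 <- h2[c("X", "mask")]
    caches$flat_dim <- flat_dim
  }
  list(pred = as.numeric(h2$out), caches = caches)
}

# Backward pass from d(pred); returns gradient list matching params.
.net_backward <- function(params, cfg, caches, dpred) {
  grads <- list()
  d2 <- .dense_backward(matrix(dpred, ncol = 1L), caches$head2, params$head2_W)
  grads$head2_W <- d2$dW; grads$head2_b <- d2$db
  d1 <- .dense_backward(d2$dX, caches$head1, params$head1_W)
  grads$head1_W <- d1$dW; grads$head1_b <- d1$db
  fd <- caches$flat_dim
  flat_len <- fd[2L] * fd[3L]
  dFlat <- d1$dX[, seq_len(flat_len), drop = FALSE]
  dBranch <- d1$dX[, (flat_len + 1L):ncol(d1$dX), drop = FALSE]
  if (cfg$variant == "full") {
    for (l in rev(seq_along(cfg$dense_branch))) {
      db <- .dense_backward(dBranch, caches[[paste0("dense", l)]],
                            params[[paste0("dense", l, "_W")]])
      grads[[paste0("dense", l, "_W")]] <- db$dW
      grads[[paste0("dense", l, "_b")]] <- db$db
      dBranch <- db$dX
    }
  }
  dA <- dFlat
  dim(dA) <- fd
  for (l in rev(seq_along(cfg$conv_channels))) {
    if (l == cfg$pool_after) dA <- .pool_backward(dA, caches$pool)
    cb <- .conv_backward(dA, caches[[paste0("conv", l)]],
                         params[[paste0("conv", l, "_W")]])
    grads[[paste0("conv", l, "_W")]] <- cb$dW
    grads[[paste0("conv", l, "_b")]] <- cb$db
    dA <- cb$dX
  }
  grads
}

# One Adam update in place; state holds m, v and the step counter.
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
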