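# Internal neural-network engine: dense and 1-D convolutional layers with
# ReLU, max-pooling and global average pooling, softmax cross-entropy loss,
# exact backpropagation, and an Adam trainer.  Convolutions are computed as
# im2col + matrix multiply so the heavy lifting is BLAS GEMM.
#
# Layout conventions (load-bearing for the reshapes below):
#  - a batch activation is an array c(B, P, C): sample, position, channel;
#  - the im2col matrix has B*P_out rows (sample index fastest) and k*C
#    columns, column (ch-1)*k + dj holding offset dj of channel ch;
#  - conv weights W are (k*C) x filters in the same row order, so a conv is
#    cross-correlation: out[i] = f(sum_{dj,ch} W[dj,ch] * x[i+dj-1,ch] + b).

new_dense_layer <- function(in_dim, out_dim, activation = "relu",
                            init = "he") {
  stopifnot(activation %in% c("relu", "none", "softmax"))
  W <- if (init == "zero") {
    matrix(0, in_dim, out_dim)
  } else {
    matrix(rnorm(in_dim * out_dim, sd = sqrt(2 / in_dim)), in_dim, out_dim)
  }
  list(W = W, b = numeric(out_dim), activation = activation)
}

new_conv_layer <- function(in_ch, filters, k, pool = 1L, init = "he") {
  W <- if (init == "zero") {
    matrix(0, k * in_ch, filters)
  } else {
    matrix(rnorm(k * in_ch * filters, sd = sqrt(2 / (k * in_ch))),
           k * in_ch, filters)
  }
  list(W = W, b = numeric(filters), k = as.integer(k),
       in_ch = as.integer(in_ch), filters = as.integer(filters),
       pool = as.integer(pool))
}

dense_forward <- function(X, layer) {
  Z <- X %*% layer$W
  Z <- Z + rep(layer$b, each = nrow(Z))
  if (layer$activation == "relu") {
    mask <- Z > 0
    Z[!mask] <- 0
    list(out = Z, mask = mask, X = X)
  } else {
    list(out = Z, mask = NULL, X = X)
  }
}

dense_backward <- function(dOut, layer, cache) {
  dZ <- if (is.null(cache$mask)) dOut else dOut * cache$mask
  list(dW = crossprod(cache$X, dZ), db = colSums(dZ),
       dX = tcrossprod(dZ, layer$W))
}

im2col <- function(A, k) {
  d <- dim(A)
  B <- d[1]; P <- d[2]; C <- d[3]
  P_out <- P - k + 1L
  if (P_out < 1L) {
    abort(sprintf("sequence length %d too short for kernel size %d", P, k),
          class = "mirimmune_shape_error")
  }
  Xc <- matrix(0, B * P_out, k * C)
  for (dj in seq_len(k)) {
    block <- A[, dj:(dj + P_out - 1L), , drop = FALSE]
    dim(block) <- c(B * P_out, C)
    Xc[, (seq_len(C) - 1L) * k + dj] <- block
  }
  Xc
}

conv_forward <- function(A, layer) {
  d <- dim(A)
  B <- d[1]; P <- d[2]; C <- d[3]
  k <- layer$k
  P_out <- P - k + 1L
  Xc <- im2col(A, k)
  Z <- Xc %*% layer$W
  Z <- Z + rep(layer$b, each = nrow(Z))
  mask <- Z > 0
  Z[!mask] <- 0
  nf <- layer$filters
  m <- min(layer$pool, P_out)
  if (m > 1L) {
    Pg <- P_out %/% m
    P_use <- m * Pg
    arr <- Z
    dim(arr) <- c(B, P_out, nf)
    sub <- arr[, seq_len(P_use), , drop = FALSE]
    dim(sub) <- c(B, m, Pg, nf)
    cur <- array(sub[, 1L, , ], c(B, Pg, nf))
    am <- array(1L, c(B, Pg, nf))
    for (j in 2:m) {
      s <- array(sub[, j, , ], c(B, Pg, nf))
      upd <- s > cur
      cur[upd] <- s[upd]
      am[upd] <- j
    }
    out <- cur
  } else {
    out <- Z
    dim(out) <- c(B, P_out, nf)
    am <- NULL
    Pg <- P_out
    P_use <- P_out
  }
  list(out = out,
       cache = list(Xc = Xc, mask = mask, am = am, B = B, P = P, C = C,
                    P_out = P_out, m = m, Pg = Pg, P_use = P_use))
}

conv_backward <- function(dOut, layer, cache) {
  B <- cache$B; P <- cache$P; C <- cache$C
  k <- layer$k; nf <- layer$filters
  P_out <- cache$P_out
  if (cache$m > 1L) {
    darr4 <- array(0, c(B, cache$m, cache$Pg, nf))
    zero <- array(0, c(B, cache$Pg, nf))
    for (j in seq_len(cache$m)) {
      sl <- zero
      hit <- cache$am == j
      sl[hit] <- dOut[hit]
      darr4[, j, , ] <- sl
    }
    dim(darr4) <- c(B, cache$P_use, nf)
    dAct <- array(0, c(B, P_out, nf))
    dAct[, seq_len(cache$P_use), ] <- darr4
  } else {
    dAct <- dOut
  }
  dim(dAct) <- c(B * P_out, nf)
  dZ <- dAct * cache$mask
  dW <- crossprod(cache$Xc, dZ)
  db <- colSums(dZ)
  dXc <- tcrossprod(dZ, layer$W)
  dA <- array(0, c(B, P, C))
  for (dj in seq_len(k)) {
    block <- dXc[, (seq_len(C) - 1L) * k + dj, drop = FALSE]
    dim(block) <- c(B, P_out, C)
    dA[, dj:(dj + P_out - 1L), ] <-
      dA[, dj:(dj + P_out - 1L), , drop = FALSE] + block
  }
  list(dW = dW, db = db, dX = dA)
}

global_avg_pool <- function(A) {
  d <- dim(A)
  colSums(aperm(A, c(2L, 1L, 3L))) / d[2]
}

# Full forward pass for a two-branch (or dense-only) network; returns class
# probabilities and, optionally, all layer caches for backprop.
nn_forward <- function(params, X, keep = FALSE) {
  B <- nrow(X)
  mlp_caches <- vector("list", length(params$mlp))
  A <- X
  for (i in seq_along(params$mlp)) {
    fc <- dense_forward(A, params$mlp[[i]])
    A <- fc$out
    if (keep) mlp_caches[[i]] <- fc[c("mask", "X")]
  }
  mlp_out <- A
  cnn_caches <- NULL
  if (!is.null(params$cnn)) {
    Ac <- array(X, c(B, ncol(X), 1L))
    cnn_caches <- vector("list", length(params$cnn))
    for (i in seq_along(params$cnn)) {
      fc <- conv_forward(Ac, params$cnn[[i]])
      Ac <- fc$out
      if (keep) cnn_caches[[i]] <- fc$cache
    }
    gap <- global_avg_pool(Ac)
    gap_P <- dim(Ac)[2]
    H <- cbind(mlp_out, gap)
  } else {
    gap_P <- NULL
    H <- mlp_out
  }
  head_caches <- vector("list", length(params$head))
  A <- H
  logits <- NULL
  for (i in seq_along(params$head)) {
    fc <- dense_forward(A, params$head[[i]])
    if (keep) head_caches[[i]] <- fc[c("mask", "X")]
    A <- fc$out
  }
  logits <- A
  # numerically stable softmax
  zmax <- apply(logits, 1L, max)
  ez <- exp(logits - zmax)
  probs <- ez / rowSums(ez)
  list(probs = probs, logits = logits, zmax = zmax,
       mlp_caches = mlp_caches, cnn_caches = cnn_caches,
       head_caches = head_caches, mlp_dim = ncol(mlp_out), gap_P = gap_P)
}

# Weighted softmax cross-entropy loss and exact gradients for every
# parameter.  `y` is 0/1; `w` is one nonnegative weight per sample.
nn_loss_grad <- function(params, X, y, w = NULL) {
  B <- nrow(X)
  if (is.null(w)) w <- rep(1, B)
  fw <- nn_forward(params, X, keep = TRUE)
  lse <- fw$zmax + log(rowSums(exp(fw$logits - fw$zmax)))
  picked <- fw$logits[cbind(seq_len(B), y + 1L)]
  loss <- -sum(w * (picked - lse)) / sum(w)
  Y <- matrix(0, B, 2L)
  Y[cbind(seq_len(B), y + 1L)] <- 1
  dLogits <- (fw$probs - Y) * (w / sum(w))
  grads <- list(mlp = vector("list", length(params$mlp)),
                cnn = if (!is.null(params$cnn)) vector("list", length(params$cnn)),
                head = vector("list", length(params$head)))
  dA <- dLogits
  for (i in rev(seq_along(params$head))) {
    bk <- dense_backward(dA, params$head[[i]], fw$head_caches[[i]])
    grads$head[[i]] <- list(W = bk$dW, b = bk$db)
    dA <- bk$dX
  }
  dMLP <- dA[, seq_len(fw$mlp_dim), drop = FALSE]
  if (!is.null(params$cnn)) {
    dGap <- dA[, fw$mlp_dim + seq_len(ncol(dA) - fw$mlp_dim), drop = FALSE]
    P <- fw$gap_P
    dAc <- aperm(array(t(dGap) / P, c(ncol(dGap), nrow(dGap), P)),
                 c(2L, 3L, 1L))
    for (i in rev(seq_along(params$cnn))) {
      bk <- conv_backward(dAc, params$cnn[[i]], fw$cnn_caches[[i]])
      grads$cnn[[i]] <- list(W = bk$dW, b = bk$db)
      dAc <- bk$dX
    }
  }
  dA <- dMLP
  for (i in rev(seq_along(params$mlp))) {
    bk <- dense_backward(dA, params$mlp[[i]], fw$mlp_caches[[i]])
    grads$mlp[[i]] <- list(W = bk$dW, b = bk$db)
    dA <- bk$dX
  }
  list(loss = loss, grads = grads)
}

# Apply f(param_block, grad_block, state_block) over every W/b in the net.
nn_param_names <- function(params) {
  out <- list()
  for (branch in c("mlp", "cnn", "head")) {
    if (is.null(params[[branch]])) next
    for (i in seq_along(params[[branch]])) {
      out[[length(out) + 1L]] <- c(branch, i)
    }
  }
  out
}

nn_zero_like <- function(params) {
  st <- list()
  for (loc in nn_param_names(params)) {
    lay <- params[[loc[1]]][[as.integer(loc[2])]]
    st[[paste(loc, collapse = "_")]] <-
      list(W = array(0, dim(lay$W)), b = numeric(length(lay$b)))
  }
  st
}

# Adam update, in place on the params list; returns updated params + state.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (loc in nn_param_names(params)) {
    key <- paste(loc, collapse = "_")
    br <- loc[1]; i <- as.integer(loc[2])
    g <- grads[[br]][[i]]
    for (slot in c("W", "b")) {
      state$m[[key]][[slot]] <- beta1 * state$m[[key]][[slot]] +
        (1 - beta1) * g[[slot]]
      state$v[[key]][[slot]] <- beta2 * state$v[[key]][[slot]] +
        (1 - beta2) * g[[slot]]^2
      mh <- state$m[[key]][[slot]] / bc1
      vh <- state$v[[key]][[slot]] / bc2
      params[[br]][[i]][[slot]] <- params[[br]][[i]][[slot]] -
        lr * mh / (sqrt(vh) + eps)
    }
  }
  list(params = params, state = state)
}

# Engine dispatch: the compiled backend and the pure-R reference implement
# the same math with the same layouts; the reference is kept for gradient
# verification and the compiled path is used for fitting.
nn_loss_grad_engine <- function(params, X, y, w, engine = "cpp") {
  if (engine == "cpp") {
    cpp_nn_loss_grad(X, as.integer(y), as.numeric(w), unclass(params))
  } else {
    nn_loss_grad(params, X, y, w)
  }
}

# Mini-batch trainer.  Deterministic under cfg$seed (shuffling uses a local
# RNG stream); loss history records the weighted cross-entropy per epoch.
nn_train <- function(params, X, y, cfg, engine = "cpp") {
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    abort("training labels contain a single class; need both positives and negatives",
          class = "mirimmune_validation_error")
  }
  if (any(table(y) < 2L)) {
    abort("need at least 2 examples of each class",
          class = "mirimmune_validation_error")
  }
  n <- nrow(X)
  w <- rep(1, n)
  if (cfg$class_weighting == "inverse_frequency") {
    tab <- table(factor(y, levels = c(0L, 1L)))
    cw <- n / (2 * as.numeric(tab))
    w <- cw[y + 1L]
  }
  state <- list(t = 0L, m = nn_zero_like(params), v = nn_zero_like(params))
  history <- numeric(cfg$epochs)
  best <- Inf
  stall <- 0L
  n_epochs_run <- 0L
  with_seed(substream_seed(cfg$seed, "nn_train"), {
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0
      ep_wsum <- 0
      for (s in starts) {
        b_idx <- idx[s:min(s + cfg$batch_size - 1L, n)]
        lg <- nn_loss_grad_engine(params, X[b_idx, , drop = FALSE],
                                  y[b_idx], w[b_idx], engine)
        upd <- adam_step(params, lg$grads, state, lr = cfg$learning_rate)
        params <- upd$params
        state <- upd$state
        bw <- sum(w[b_idx])
        ep_loss <- ep_loss + lg$loss * bw
        ep_wsum <- ep_wsum + bw
      }
      history[ep] <- ep_loss / ep_wsum
      n_epochs_run <- ep
      if (!is.null(cfg$early_stop_patience)) {
        if (history[ep] < best - 1e-6) {
          best <- history[ep]
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= cfg$early_stop_patience) break
        }
      }
    }
  })
  list(params = params, history = history[seq_len(n_epochs_run)])
}

# Batched probability prediction; chunked to bound the im2col workspace.
nn_predict_prob <- function(params, X, chunk = 64L, engine = "cpp") {
  n <- nrow(X)
  out <- matrix(NA_real_, n, 2L)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    Xb <- X[idx, , drop = FALSE]
    out[idx, ] <- if (engine == "cpp") {
      cpp_nn_forward(Xb, unclass(params))
    } else {
      nn_forward(params, Xb)$probs
    }
  }
  out
}
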