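# Independent reference implementations used as oracles.  These are written
# as directly as possible (scalar loops, exhaustive enumeration, generic
# optimizers) and share no code with the package internals they check.

# nested-loop 1-D conv stack: layers as produced by new_conv_layer();
# x is a single feature vector; returns list of per-layer outputs
# (positions x filters matrices, after ReLU and max-pooling)
brute_conv_stack <- function(x, layers) {
  A <- matrix(x, ncol = 1)
  outs <- list()
  for (lay in layers) {
    k <- lay$k; C <- ncol(A); F_ <- lay$filters
    P_out <- nrow(A) - k + 1
    Z <- matrix(0, P_out, F_)
    for (f in seq_len(F_)) {
      for (i in seq_len(P_out)) {
        acc <- lay$b[f]
        for (c in seq_len(C)) {
          for (dj in seq_len(k)) {
            acc <- acc + lay$W[(c - 1) * k + dj, f] * A[i + dj - 1, c]
          }
        }
        Z[i, f] <- max(0, acc)
      }
    }
    m <- min(lay$pool, P_out)
    if (m > 1) {
      Pg <- P_out %/% m
      Zp <- matrix(0, Pg, F_)
      for (f in seq_len(F_)) {
        for (g in seq_len(Pg)) {
          Zp[g, f] <- max(Z[((g - 1) * m + 1):(g * m), f])
        }
      }
      Z <- Zp
    }
    A <- Z
    outs[[length(outs) + 1]] <- Z
  }
  outs
}

# AUC by exhaustive positive-negative pair enumeration, ties half credit
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# AUPR by an exhaustive threshold sweep over all distinct score values
aupr_sweep_oracle <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  rec <- prec <- numeric(length(th))
  for (i in seq_along(th)) {
    call_pos <- scores >= th[i]
    tp <- sum(call_pos & labels == 1)
    rec[i] <- tp / n_pos
    prec[i] <- tp / sum(call_pos)
  }
  sum(diff(c(0, rec)) * prec)
}

# Breslow negative log partial likelihood, for a generic-optimizer Cox fit
cox_nll_oracle <- function(beta, X, time, event) {
  lp <- drop(X %*% beta)
  nll <- 0
  for (t in unique(time[event == 1])) {
    d <- which(event == 1 & time == t)
    risk <- which(time >= t)
    nll <- nll - sum(lp[d]) + length(d) * log(sum(exp(lp[risk])))
  }
  nll
}

# hypergeometric upper tail by explicit pmf summation from log-binomials
hyper_pmf_sum_oracle <- function(N, K, n, x) {
  js <- x:min(K, n)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# small planted-signal association config used across tests
small_assoc_cfg <- function(seed = 1, signal_boost = 5) {
  synth_config(n_mirna = 180, n_gene = 600, n_positive = 40, n_negative = 80,
               disease_module_size = 40, immune_set_size = 60,
               signal_boost = signal_boost, seed = seed)
}
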