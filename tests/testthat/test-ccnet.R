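test_that("zero-parameter network is maximally uncertain", {
  p <- ccnet_params(600, init = "zero")
  out <- ccnet_forward(p, rbinom(600, 1, 0.1))
  expect_equal(unname(out), c(0.5, 0.5))
  X <- matrix(rbinom(5 * 600, 1, 0.1), 5)
  expect_equal(predict_scores(p, X), rep(0.5, 5))
})

test_that("branch dimensions follow the fixed architecture", {
  p <- ccnet_params(600, seed = 3)
  expect_length(p$mlp, 3)
  expect_identical(vapply(p$mlp, function(l) ncol(l$W), integer(1)),
                   c(256L, 64L, 128L))
  expect_length(p$cnn, 4)
  expect_identical(vapply(p$cnn, function(l) l$filters, integer(1)),
                   c(256L, 64L, 128L, 128L))
  expect_identical(vapply(p$cnn, function(l) l$k, integer(1)),
                   c(5L, 3L, 3L, 3L))
  expect_identical(ncol(p$head[[2]]$W), 2L)
  # softmax output: probability pair summing to 1
  out <- ccnet_forward(p, rnorm(600))
  expect_true(all(out >= 0))
  expect_lt(abs(sum(out) - 1), 1e-6)
  expect_error(ccnet_forward(p, rnorm(10)), class = "mirimmune_shape_error")
})

test_that("convolution matches the brute-force sliding-sum oracle", {
  # the worked toy: input (1,2,3), kernel (1,0,-1) -> raw -2, ReLU -> 0
  lay <- mirimmune:::new_conv_layer(1, 1, 3, pool = 1, init = "zero")
  lay$W[, 1] <- c(1, 0, -1)
  fc <- mirimmune:::conv_forward(array(c(1, 2, 3), c(1, 3, 1)), lay)
  expect_equal(as.numeric(fc$out), 0)
  lay$W[, 1] <- c(-1, 0, 1)  # raw response +2 survives the ReLU
  fc <- mirimmune:::conv_forward(array(c(1, 2, 3), c(1, 3, 1)), lay)
  expect_equal(as.numeric(fc$out), 2)

  # random small stacks (<= 32 features, <= 2 layers) against nested loops,
  # for both the reference and the compiled engine
  set.seed(42)
  for (rep in 1:25) {
    n_in <- sample(8:32, 1)
    k1 <- sample(2:5, 1)
    f1 <- sample(1:4, 1)
    pool1 <- sample(1:3, 1)
    layers <- list(mirimmune:::new_conv_layer(1, f1, k1, pool = pool1))
    if (rep %% 2 == 0) {
      layers[[2]] <- mirimmune:::new_conv_layer(f1, sample(1:3, 1),
                                                sample(2:3, 1),
                                                pool = sample(1:2, 1))
    }
    x <- rnorm(n_in)
    ref <- tryCatch(brute_conv_stack(x, layers), error = function(e) NULL)
    if (is.null(ref)) next
    A <- array(x, c(1, n_in, 1))
    for (li in seq_along(layers)) {
      fc <- mirimmune:::conv_forward(A, layers[[li]])
      expect_lt(max(abs(matrix(fc$out, dim(fc$out)[2], dim(fc$out)[3]) -
                          ref[[li]])), 1e-5)
      A <- fc$out
    }
  }
})

test_that("compiled engine agrees with the reference engine exactly", {
  set.seed(9)
  params <- ccnet_params(600, seed = 4)
  X <- matrix(rbinom(8 * 600, 1, 0.05), 8)
  storage.mode(X) <- "double"
  y <- rep(c(0L, 1L), 4)
  w <- runif(8, 0.5, 2)
  a <- mirimmune:::nn_loss_grad(params, X, y, w)
  b <- mirimmune:::nn_loss_grad_engine(params, X, y, w, "cpp")
  expect_equal(a$loss, b$loss, tolerance = 1e-12)
  for (br in c("mlp", "cnn", "head")) {
    for (i in seq_along(params[[br]])) {
      expect_equal(a$grads[[br]][[i]]$W, b$grads[[br]][[i]]$W,
                   tolerance = 1e-10, ignore_attr = TRUE)
      expect_equal(a$grads[[br]][[i]]$b, b$grads[[br]][[i]]$b,
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
  expect_equal(mirimmune:::nn_forward(params, X)$probs,
               mirimmune:::cpp_nn_forward(X, unclass(params)),
               tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(31)
  params <- structure(list(
    input_dim = 14L,
    mlp = list(mirimmune:::new_dense_layer(14, 5),
               mirimmune:::new_dense_layer(5, 4)),
    cnn = list(mirimmune:::new_conv_layer(1, 3, 3, pool = 2),
               mirimmune:::new_conv_layer(3, 2, 2, pool = 1)),
    head = list(mirimmune:::new_dense_layer(6, 3),
                mirimmune:::new_dense_layer(3, 2, "none"))
  ), class = "ccnet_params")
  X <- matrix(rnorm(6 * 14), 6)
  y <- rep(c(0L, 1L), 3)
  w <- runif(6, 0.5, 2)
  lg <- mirimmune:::nn_loss_grad(params, X, y, w)
  base <- lg$loss
  eps <- 1e-5
  checked <- 0L
  for (br in c("mlp", "cnn", "head")) {
    for (i in seq_along(params[[br]])) {
      for (slot in c("W", "b")) {
        P <- params[[br]][[i]][[slot]]
        G <- lg$grads[[br]][[i]][[slot]]
        idx <- sample(length(P), min(6, length(P)))
        for (j in idx) {
          p2 <- params
          p2[[br]][[i]][[slot]][j] <- P[j] + eps
          up <- mirimmune:::nn_loss_grad(p2, X, y, w)$loss
          p2[[br]][[i]][[slot]][j] <- P[j] - eps
          dn <- mirimmune:::nn_loss_grad(p2, X, y, w)$loss
          # the loss is piecewise smooth (ReLU / max-pool kinks); only
          # differentiable points admit a central-difference comparison
          kink <- abs(up + dn - 2 * base) >
            1e-3 * (abs(up - base) + abs(dn - base) + 1e-12)
          if (kink) next
          fd <- (up - dn) / (2 * eps)
          expect_lt(abs(fd - G[j]) / max(1e-8, abs(fd) + abs(G[j])), 1e-4)
          checked <- checked + 1L
        }
      }
    }
  }
  expect_gt(checked, 40)
})

test_that("training is reproducible and refuses degenerate labels", {
  cfg <- small_assoc_cfg(seed = 3)
  sim <- generate_associations(cfg)
  ids <- c(sim$positive_ids, sim$negative_ids)
  X <- sim$matrix[ids, ]
  y <- rep(c(1L, 0L), c(40, 80))
  tc <- train_config(epochs = 3, batch_size = 64, seed = 5)
  f1 <- ccnet_train(X, y, tc)
  f2 <- ccnet_train(X, y, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_error(ccnet_train(X, rep(1L, nrow(X)), tc),
               class = "mirimmune_validation_error")
})

test_that("a separable toy problem is learned to perfect training accuracy", {
  # 20 points, two informative features embedded in a 12-feature vector
  set.seed(77)
  n <- 20
  X <- cbind(matrix(rnorm(2 * n), n), matrix(0, n, 10))
  y <- as.integer(X[, 1] - X[, 2] > 0)
  y[1:2] <- c(0L, 1L)  # ensure both classes even under sign flips
  X[1, 1:2] <- c(-2, 2); X[2, 1:2] <- c(2, -2)
  fit <- ccnet_train(X, y, train_config(epochs = 200, batch_size = 10,
                                        seed = 1),
                     pool_widths = c(1L, 1L, 1L))
  acc <- mean((predict_scores(fit, X) > 0.5) == (y == 1))
  expect_equal(acc, 1)
})

test_that("batch prediction equals per-row forward and is order-equivariant", {
  p <- ccnet_params(600, seed = 12)
  X <- matrix(rbinom(7 * 600, 1, 0.08), 7)
  sc <- predict_scores(p, X)
  one_by_one <- vapply(seq_len(nrow(X)), function(i) {
    unname(ccnet_forward(p, X[i, ])[2])
  }, numeric(1))
  expect_equal(sc, one_by_one, tolerance = 1e-6)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  expect_equal(predict_scores(p, X[perm, ]), sc[perm], tolerance = 1e-12)
})

test_that("parameter archives round-trip bit-exactly", {
  p <- ccnet_params(600, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  save_ccnet(p, path)
  q <- load_ccnet(path)
  expect_identical(unclass(p)$mlp, unclass(q)$mlp)
  expect_identical(unclass(p)$cnn, unclass(q)$cnn)
  expect_identical(unclass(p)$head, unclass(q)$head)
  X <- matrix(rbinom(3 * 600, 1, 0.05), 3)
  expect_identical(predict_scores(p, X), predict_scores(q, X))
})

test_that("held-out AUC responds monotonically to the planted signal", {
  boosts <- c(1, 2, 5)
  means <- vapply(boosts, function(bst) {
    res <- benchmark_models(small_assoc_cfg(signal_boost = bst),
                            models = "ccnet", seeds = 1:10,
                            train_cfg = train_config(epochs = 4,
                                                     batch_size = 64))
    mean(res$auc)
  }, numeric(1))
  expect_lt(abs(means[1] - 0.5), 0.1)  # boost 1 is chance
  expect_gt(means[2], means[1] - 0.02)
  expect_gt(means[3], means[2] - 0.02)
  expect_gt(means[3], 0.6)
})
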