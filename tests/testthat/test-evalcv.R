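test_that("folds partition the data with balanced class counts", {
  labels <- rep(c(1L, 0L), c(133, 500))
  folds <- make_folds(labels, k = 10, seed = 1)
  expect_setequal(folds$index, seq_along(labels))
  per_fold_pos <- tapply(folds$label, folds$fold, sum)
  expect_true(all(per_fold_pos %in% c(13, 14)))
  per_fold_n <- table(folds$fold)
  expect_lte(max(per_fold_n) - min(per_fold_n), 2)
  expect_identical(folds, make_folds(labels, k = 10, seed = 1))
  expect_false(identical(folds$fold, make_folds(labels, 10, seed = 2)$fold))
  expect_error(make_folds(labels, k = 1000), "exceeds")
  expect_warning(make_folds(rep(c(1L, 0L), c(3, 50)), k = 5), "fewer")
})

test_that("auc equals exhaustive pair concordance", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.9, 0.2, 0.8, 0.3), c(1, 0, 0, 1)), 0.75)
  expect_equal(auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), class = "mirimmune_validation_error")
  set.seed(10)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc(sc, y), auc_pairs_oracle(sc, y), tolerance = 1e-12)
  }
})

test_that("aupr equals the exhaustive threshold-sweep integral", {
  expect_equal(aupr(c(0.9, 0.8, 0.7), c(1, 0, 1)), 5 / 6)
  expect_equal(aupr(c(3, 2, 1), c(1, 1, 1)), 1)   # perfect ranking
  expect_error(aupr(1:3, c(0, 0, 0)), class = "mirimmune_validation_error")
  set.seed(11)
  for (i in 1:40) {
    n <- sample(10:150, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0) next
    expect_equal(aupr(sc, y), aupr_sweep_oracle(sc, y), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under strictly monotone score transforms", {
  set.seed(12)
  sc <- runif(80)
  y <- rbinom(80, 1, 0.3)
  for (f in list(function(x) 2 * x + 1, exp, function(x) x^3)) {
    expect_equal(auc(f(sc), y), auc(sc, y), tolerance = 1e-12)
    expect_equal(aupr(f(sc), y), aupr(sc, y), tolerance = 1e-12)
  }
})

test_that("random scores yield aupr near the prevalence", {
  set.seed(13)
  pi0 <- 0.3
  vals <- replicate(200, {
    y <- rbinom(100, 1, pi0)
    if (sum(y) == 0) return(NA_real_)
    aupr(runif(100), y)
  })
  expect_lt(abs(mean(vals, na.rm = TRUE) - pi0), 0.05)
})

test_that("cross-validation honours fixtures with known behaviour", {
  set.seed(14)
  n <- 120
  y <- rep(c(1L, 0L), c(40, 80))
  X <- matrix(rnorm(n * 4), n)
  folds <- make_folds(y, k = 4, seed = 2)

  # an oracle-leak fixture: the first covariate IS the label, and the model
  # scores it directly; plus a constant-score model
  Xleak <- cbind(as.numeric(y), X)
  leak_spec <- list(fit = function(X, y) list(),
                    predict = function(model, X) X[, 1])
  res <- cross_validate(leak_spec, Xleak, y, folds)
  expect_true(all(res$per_fold$auc == 1))
  expect_equal(res$mean_auc, 1)

  const_spec <- list(fit = function(X, y) list(),
                     predict = function(model, X) rep(0.5, nrow(X)))
  res0 <- cross_validate(const_spec, Xleak, y, folds)
  expect_true(all(res0$per_fold$auc == 0.5))

  # mean curve area stays bracketed by the per-fold areas (up to the
  # 101-point grid discretization)
  noisy_spec <- list(fit = function(X, y) list(),
                     predict = function(model, X) X[, 1] + rnorm(nrow(X), sd = 1.5))
  res2 <- cross_validate(noisy_spec, Xleak, y, folds)
  grid_area <- sum(diff(res2$mean_roc$fpr) *
                     res2$mean_roc$tpr[-1])
  expect_gte(grid_area, min(res2$per_fold$auc) - 0.03)
  expect_lte(grid_area, max(res2$per_fold$auc) + 0.03)
  expect_identical(nrow(res2$oof_scores), as.integer(n))
})

test_that("candidate ranking respects thresholds, top-n and tie order", {
  ids <- c("mir-b", "mir-a", "mir-c", "mir-d")
  sc <- c(0.9, 0.9, 0.4, 0.7)
  out <- rank_candidates(sc, ids)           # default threshold 0.5
  expect_identical(out$mirna_id, c("mir-a", "mir-b", "mir-d"))
  expect_identical(out$rank, 1:3)
  expect_identical(nrow(rank_candidates(sc, ids, threshold = 0.95)), 0L)
  all4 <- rank_candidates(sc, ids, top_n = 4)
  expect_setequal(all4$mirna_id, ids)
  expect_identical(nrow(rank_candidates(sc, ids, top_n = 2)), 2L)
  expect_error(rank_candidates(sc, ids, threshold = 0.5, top_n = 2),
               class = "mirimmune_validation_error")
})
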