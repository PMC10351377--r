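#' Stratified k-fold assignment
#'
#' Assigns labeled examples to `k` folds so that per-fold class counts
#' differ by at most one from proportional allocation.  If a class has
#' fewer than `k` members, stratification degrades gracefully to a plain
#' shuffled split with a warning.
#'
#' @param labels Class labels (any atomic vector).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return A tibble with columns `index`, `label`, `fold`, and attribute
#'   `k`.
#' @examples
#' table(make_folds(rep(0:1, c(50, 13)), k = 5, seed = 1)[, c("label", "fold")])
#' @export
make_folds <- function(labels, k = 10, seed = 1) {
  k <- check_count(k, "k", min = 2)
  n <- length(labels)
  if (k > n) {
    abort(sprintf("k = %d exceeds the number of examples (%d)", k, n),
          class = "mirimmune_validation_error")
  }
  fold <- integer(n)
  with_seed(substream_seed(seed, "folds"), {
    if (any(table(labels) < k)) {
      warn("a class has fewer members than folds; falling back to unstratified shuffling")
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    } else {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
      }
    }
  })
  structure(tibble::tibble(index = seq_len(n), label = labels, fold = fold),
            k = k)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the probability
#' that a random positive outranks a random negative, with ties counted as
#' half a concordance.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.2, 0.8, 0.3), c(1, 0, 0, 1))  # 0.75
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUC needs both classes present", class = "mirimmune_validation_error")
  }
  r <- rank(scores)  # mean ranks handle ties exactly
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-curve integration with precision held right-continuous between
#' achieved recall levels (average precision); tied scores are processed as
#' one block.
#'
#' @inheritParams auc
#' @return AUPR in `(0, 1]`.
#' @examples
#' aupr(c(0.9, 0.8, 0.7), c(1, 0, 1))  # 5/6
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) {
    abort("AUPR needs at least one positive", class = "mirimmune_validation_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  blocks <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  n_seen <- seq_along(y)
  last <- !duplicated(blocks, fromLast = TRUE)  # end of each tie block
  tp_b <- tp[last]
  n_b <- n_seen[last]
  prec <- tp_b / n_b
  rec <- tp_b / n_pos
  d_rec <- diff(c(0, rec))
  sum(d_rec * prec)
}

#' ROC curve points
#'
#' @inheritParams auc
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, sorted along the
#'   threshold sweep from strictest to loosest; carries attribute `area`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- !duplicated(cumsum(!duplicated(s)), fromLast = TRUE)
  tp <- cumsum(y)[last]
  fp <- (seq_along(y) - cumsum(y))[last]
  out <- tibble::tibble(threshold = c(Inf, s[last]),
                        fpr = c(0, fp / n_neg),
                        tpr = c(0, tp / n_pos))
  structure(out, area = auc(scores, labels))
}

#' Precision-recall curve points
#'
#' @inheritParams auc
#' @return Tibble with columns `threshold`, `recall`, `precision`; carries
#'   attribute `area` (the average precision of [aupr()]).
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- !duplicated(cumsum(!duplicated(s)), fromLast = TRUE)
  tp <- cumsum(y)[last]
  n_seen <- seq_along(y)[last]
  out <- tibble::tibble(threshold = s[last],
                        recall = tp / n_pos,
                        precision = tp / n_seen)
  structure(out, area = aupr(scores, labels))
}

# Vertical averaging of step curves on a fixed 101-point grid.
mean_curve <- function(xs, ys, grid = seq(0, 1, by = 0.01)) {
  mats <- purrr::map2(xs, ys, function(x, y) {
    stats::approx(x, y, xout = grid, method = "constant", rule = 2,
                  ties = max)$y
  })
  tibble::tibble(x = grid, y = rowMeans(do.call(cbind, mats)))
}

#' Cross-validate a miRNA-association model
#'
#' Trains the requested model on each fold's complement and scores the
#' held-out fold only; reports per-fold ROC/PR areas, mean areas, vertically
#' averaged mean curves on a 101-point grid, and the pooled out-of-fold
#' scores.
#'
#' @param model_spec `"ccnet"`, `"dnn"`, `"svm"`, `"knn"`, or a list with
#'   elements `fit(X, labels)` and `predict(model, X)` for a custom model.
#' @param X Feature matrix (labeled rows of the association matrix).
#' @param labels 0/1 labels, one per row of `X`.
#' @param folds A fold assignment from [make_folds()].
#' @param train_cfg A [train_config()] used by the neural models; its seed
#'   is re-derived per fold so folds are independent but reproducible.
#' @return A list of class `cv_result`: `per_fold` (tibble of fold, auc,
#'   aupr), `mean_auc`, `mean_aupr`, `mean_roc`, `mean_pr`, `fold_curves`,
#'   `oof_scores`.
#' @export
cross_validate <- function(model_spec, X, labels, folds,
                           train_cfg = train_config()) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  stopifnot(nrow(X) == length(labels), nrow(folds) == length(labels))
  k <- attr(folds, "k")
  fit_fun <- if (is.list(model_spec)) {
    model_spec$fit
  } else {
    function(Xtr, ytr, fold) {
      cfg <- train_cfg
      cfg$seed <- substream_seed(train_cfg$seed, paste0("fold", fold))
      switch(model_spec,
             ccnet = ccnet_train(Xtr, ytr, cfg),
             dnn = ,
             svm = ,
             knn = fit_baseline(model_spec, Xtr, ytr, cfg),
             abort(sprintf("unknown model '%s'", model_spec)))
    }
  }
  predict_fun <- if (is.list(model_spec)) model_spec$predict else predict_scores
  per_fold <- vector("list", k)
  curves <- vector("list", k)
  oof <- vector("list", k)
  for (f in seq_len(k)) {
    te <- folds$index[folds$fold == f]
    tr <- folds$index[folds$fold != f]
    model <- if (is.list(model_spec)) {
      fit_fun(X[tr, , drop = FALSE], labels[tr])
    } else {
      fit_fun(X[tr, , drop = FALSE], labels[tr], f)
    }
    sc <- predict_fun(model, X[te, , drop = FALSE])
    per_fold[[f]] <- tibble::tibble(fold = f,
                                    auc = auc(sc, labels[te]),
                                    aupr = aupr(sc, labels[te]))
    curves[[f]] <- list(roc = roc_curve(sc, labels[te]),
                        pr = pr_curve(sc, labels[te]))
    oof[[f]] <- tibble::tibble(index = te, label = labels[te], fold = f,
                               score = sc)
  }
  per_fold <- dplyr::bind_rows(per_fold)
  mean_roc <- mean_curve(purrr::map(curves, ~ .x$roc$fpr),
                         purrr::map(curves, ~ .x$roc$tpr))
  names(mean_roc) <- c("fpr", "tpr")
  mean_pr <- mean_curve(purrr::map(curves, ~ .x$pr$recall),
                        purrr::map(curves, ~ .x$pr$precision))
  names(mean_pr) <- c("recall", "precision")
  structure(list(per_fold = per_fold,
                 mean_auc = mean(per_fold$auc),
                 mean_aupr = mean(per_fold$aupr),
                 mean_roc = mean_roc, mean_pr = mean_pr,
                 fold_curves = curves,
                 oof_scores = dplyr::bind_rows(oof)),
            class = "cv_result")
}

#' Rank unlabeled miRNAs into a candidate list
#'
#' Orders miRNAs by descending score, breaking ties by identifier
#' (lexicographic, ascending), and keeps either all miRNAs scoring above
#' `threshold` or the first `top_n`.
#'
#' @param scores Numeric scores for unlabeled miRNAs.
#' @param ids miRNA identifiers, same length as `scores`.
#' @param threshold Keep miRNAs with `score > threshold` (default 0.5 when
#'   `top_n` is not given).
#' @param top_n Keep this many top-ranked miRNAs instead.
#' @return Tibble with columns `mirna_id`, `score`, `rank`.
#' @export
rank_candidates <- function(scores, ids, threshold = NULL, top_n = NULL) {
  stopifnot(length(scores) == length(ids), all(is.finite(scores)))
  if (!is.null(threshold) && !is.null(top_n)) {
    abort("give either `threshold` or `top_n`, not both",
          class = "mirimmune_validation_error")
  }
  if (is.null(threshold) && is.null(top_n)) threshold <- 0.5
  ord <- order(-scores, ids)
  out <- tibble::tibble(mirna_id = ids[ord], score = scores[ord],
                        rank = seq_along(ord))
  if (!is.null(top_n)) {
    head(out, top_n)
  } else {
    out[out$score > threshold, ]
  }
}

#' Planted-signal benchmark of the classifier and baselines
#'
#' Generates the synthetic association benchmark for each seed, holds out a
#' stratified test fraction, trains each requested model on the rest, and
#' records the held-out AUC/AUPR.  This is the package's standing check
#' that each model detects the planted over-targeting signal.
#'
#' @param cfg A [synth_config()]; its `seed` is replaced by each value of
#'   `seeds` in turn.
#' @param models Character vector from `"ccnet"`, `"dnn"`, `"svm"`, `"knn"`.
#' @param seeds Integer seeds, one benchmark replicate per seed.
#' @param test_fraction Held-out fraction per class.
#' @param train_cfg A [train_config()] for the neural models.
#' @return Tibble with columns `seed`, `model`, `auc`, `aupr`.
#' @export
benchmark_models <- function(cfg = synth_config(),
                             models = c("ccnet", "knn"),
                             seeds = 1:10, test_fraction = 0.3,
                             train_cfg = train_config()) {
  out <- list()
  for (sd in seeds) {
    cfg_s <- cfg
    cfg_s$seed <- as.integer(sd)
    sim <- generate_associations(cfg_s)
    ids <- c(sim$positive_ids, sim$negative_ids)
    y <- rep(c(1L, 0L), c(length(sim$positive_ids), length(sim$negative_ids)))
    X <- sim$matrix[ids, , drop = FALSE]
    te <- with_seed(substream_seed(sd, "bench_split"), {
      c(sample(which(y == 1L), round(test_fraction * sum(y == 1L))),
        sample(which(y == 0L), round(test_fraction * sum(y == 0L))))
    })
    tr <- setdiff(seq_along(y), te)
    for (m in models) {
      tcfg <- train_cfg
      tcfg$seed <- substream_seed(sd, paste0("bench_", m))
      fit <- if (m == "ccnet") {
        ccnet_train(X[tr, , drop = FALSE], y[tr], tcfg)
      } else {
        fit_baseline(m, X[tr, , drop = FALSE], y[tr], tcfg)
      }
      sc <- predict_scores(fit, X[te, , drop = FALSE])
      out[[length(out) + 1L]] <- tibble::tibble(
        seed = sd, model = m, auc = auc(sc, y[te]), aupr = aupr(sc, y[te]))
    }
  }
  dplyr::bind_rows(out)
}
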