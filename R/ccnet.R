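#' Parameters of the dual-branch miRNA classifier
#'
#' Builds the parameter set of the dual-branch network: a 3-layer MLP
#' branch (fully connected, 256 / 64 / 128 units, ReLU) learning global
#' target-profile features, a 4-layer 1-D CNN branch (256 / 64 / 128 / 128
#' filters with kernel sizes 5 / 3 / 3 / 3, ReLU) learning local features
#' along the fixed gene order, and a 2-layer fusion head (32 units ReLU,
#' then 2 units with softmax) that combines the 128-length MLP output with
#' the 128-length globally average-pooled CNN output.
#'
#' Max-pooling of width `pool_widths[i]` follows conv layer `i` (a wider
#' first pool collapses the long layer-1 position axis early); global
#' average pooling after the last conv layer yields the fixed-size vector
#' for fusion.  Convolutions are valid (no padding), stride 1, and the gene
#' axis is the canonical gene order of the association matrix.
#'
#' @param input_dim Length of the input feature vector (gene-universe size).
#' @param seed Integer seed for He-normal weight initialization.
#' @param init `"he"` (default) or `"zero"` (all weights and biases zero;
#'   the network then outputs (0.5, 0.5) everywhere).
#' @param pool_widths Max-pool widths after conv layers 1-3 (the 4th is
#'   followed by global average pooling); width 1 disables a pool.
#' @return An object of class `ccnet_params`.
#' @examples
#' p <- ccnet_params(600, seed = 1)
#' ccnet_forward(p, rbinom(600, 1, 0.1))
#' @export
ccnet_params <- function(input_dim, seed = 1, init = c("he", "zero"),
                         pool_widths = c(8L, 4L, 4L)) {
  init <- match.arg(init)
  input_dim <- check_count(input_dim, "input_dim")
  stopifnot(length(pool_widths) == 3L, all(pool_widths >= 1))
  # the conv pyramid must leave at least one valid position for layer 4
  p <- input_dim - 4L
  for (w in pool_widths) p <- (p %/% max(1L, as.integer(w))) - 2L
  if (p + 2L < 3L) {
    abort(sprintf(paste0("input_dim = %d is too short for kernel sizes ",
                         "5/3/3/3 with pool widths %s; reduce pool_widths"),
                  input_dim, paste(pool_widths, collapse = "/")),
          class = "mirimmune_shape_error")
  }
  with_seed(substream_seed(seed, "ccnet_init"), {
    params <- list(
      input_dim = input_dim,
      mlp = list(
        new_dense_layer(input_dim, 256L, "relu", init),
        new_dense_layer(256L, 64L, "relu", init),
        new_dense_layer(64L, 128L, "relu", init)
      ),
      cnn = list(
        new_conv_layer(1L, 256L, 5L, pool = pool_widths[1], init = init),
        new_conv_layer(256L, 64L, 3L, pool = pool_widths[2], init = init),
        new_conv_layer(64L, 128L, 3L, pool = pool_widths[3], init = init),
        new_conv_layer(128L, 128L, 3L, pool = 1L, init = init)
      ),
      head = list(
        new_dense_layer(256L, 32L, "relu", init),
        new_dense_layer(32L, 2L, "none", init)
      )
    )
    structure(params, class = "ccnet_params")
  })
}

# Dense-only network with the same MLP branch and fusion head; used as the
# plain deep-neural-network baseline.
dnn_params <- function(input_dim, seed = 1, init = "he") {
  with_seed(substream_seed(seed, "dnn_init"), {
    structure(list(
      input_dim = as.integer(input_dim),
      mlp = list(
        new_dense_layer(input_dim, 256L, "relu", init),
        new_dense_layer(256L, 64L, "relu", init),
        new_dense_layer(64L, 128L, "relu", init)
      ),
      cnn = NULL,
      head = list(
        new_dense_layer(128L, 32L, "relu", init),
        new_dense_layer(32L, 2L, "none", init)
      )
    ), class = "ccnet_params")
  })
}

#' Training configuration for the neural classifiers
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param optimizer Only `"adam"` is implemented.
#' @param class_weighting `"inverse_frequency"` (default; offsets the
#'   positive/negative imbalance, e.g. 133:500) or `"none"`.
#' @param seed Seed for initialization and batch shuffling.
#' @param early_stop_patience Stop when the epoch loss has not improved for
#'   this many epochs; `NULL` disables early stopping.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 32, learning_rate = 1e-3,
                         optimizer = "adam",
                         class_weighting = c("inverse_frequency", "none"),
                         seed = 1, early_stop_patience = NULL) {
  class_weighting <- match.arg(class_weighting)
  stopifnot(optimizer == "adam")
  structure(list(
    epochs = check_count(epochs, "epochs"),
    batch_size = check_count(batch_size, "batch_size"),
    learning_rate = check_fraction(learning_rate, "learning_rate",
                                   lo = 1e-12, hi = Inf),
    optimizer = optimizer,
    class_weighting = class_weighting,
    seed = check_count(seed, "seed", min = 0),
    early_stop_patience = if (!is.null(early_stop_patience)) {
      check_count(early_stop_patience, "early_stop_patience")
    }
  ), class = "train_config")
}

#' Single forward pass of the dual-branch classifier
#'
#' @param params A [ccnet_params()] object.
#' @param x Numeric feature vector of length `params$input_dim`.
#' @return Named numeric `c(p_negative, p_positive)`, summing to 1.
#' @export
ccnet_forward <- function(params, x) {
  stopifnot(inherits(params, "ccnet_params"))
  if (length(x) != params$input_dim) {
    abort(sprintf("feature vector has length %d, expected %d",
                  length(x), params$input_dim),
          class = "mirimmune_shape_error")
  }
  p <- nn_forward(params, matrix(as.numeric(x), 1L))$probs
  c(p_negative = p[1, 1], p_positive = p[1, 2])
}

#' Train the dual-branch classifier on labeled miRNA feature rows
#'
#' Minimizes (class-weighted) softmax cross-entropy with Adam; fully
#' reproducible under `cfg$seed`.
#'
#' @param X Numeric matrix, one row per labeled miRNA (rows of the
#'   association matrix), columns in the canonical gene order.
#' @param labels 0/1 vector (1 = disease-associated).
#' @param cfg A [train_config()].
#' @param arch `"ccnet"` (both branches) or `"dnn"` (MLP branch only, the
#'   deep-neural-network baseline).
#' @param pool_widths Passed to [ccnet_params()] when `arch = "ccnet"`.
#' @return A `ccnet_fit`: list with fitted `params`, `history` (tibble of
#'   per-epoch loss) and the training `config`.
#' @export
ccnet_train <- function(X, labels, cfg = train_config(), arch = "ccnet",
                        pool_widths = c(8L, 4L, 4L)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  labels <- as.integer(labels)
  stopifnot(nrow(X) == length(labels), all(labels %in% c(0L, 1L)))
  params <- if (arch == "ccnet") {
    ccnet_params(ncol(X), seed = cfg$seed, pool_widths = pool_widths)
  } else if (arch == "dnn") {
    dnn_params(ncol(X), seed = cfg$seed)
  } else {
    abort(sprintf("unknown architecture '%s'", arch))
  }
  tr <- nn_train(params, X, labels, cfg)
  structure(list(params = tr$params,
                 history = tibble::tibble(epoch = seq_along(tr$history),
                                          loss = tr$history),
                 config = cfg, arch = arch),
            class = "ccnet_fit")
}

#' Predict disease-association scores
#'
#' Returns the positive-class probability for each row of `X`.  Works for
#' fitted networks ([ccnet_train()]), raw parameter objects and the
#' baseline models of [fit_baseline()].
#'
#' @param model A `ccnet_fit`, `ccnet_params`, or baseline model.
#' @param X Feature matrix with `input_dim` columns.
#' @return Numeric vector of scores in `[0, 1]`, one per row of `X`.
#' @export
predict_scores <- function(model, X) UseMethod("predict_scores")

#' @export
predict_scores.ccnet_params <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    abort(sprintf("feature matrix has %d columns, expected %d",
                  ncol(X), model$input_dim),
          class = "mirimmune_shape_error")
  }
  storage.mode(X) <- "double"
  unname(nn_predict_prob(model, X)[, 2L])
}

#' @export
predict_scores.ccnet_fit <- function(model, X) {
  predict_scores(model$params, X)
}

#' Fit a baseline miRNA-association model
#'
#' The three comparison models: a dense-only deep neural network (the MLP
#' branch plus fusion head, trained like the main model), a linear-kernel
#' support vector machine, and a k-nearest-neighbour scorer on Euclidean
#' (Hamming, for binary profiles) distance whose score is the fraction of
#' positives among the k nearest training rows.
#'
#' @param kind `"dnn"`, `"svm"` or `"knn"`.
#' @param X,labels Training feature matrix and 0/1 labels.
#' @param cfg A [train_config()] (used by `"dnn"`; its `seed` also fixes any
#'   randomness in the other fits).
#' @param k Neighbourhood size for `"knn"`.
#' @return A model object supporting [predict_scores()].
#' @export
fit_baseline <- function(kind, X, labels, cfg = train_config(), k = 5L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    abort("training labels contain a single class",
          class = "mirimmune_validation_error")
  }
  switch(kind,
    dnn = ccnet_train(X, labels, cfg, arch = "dnn"),
    svm = {
      fit <- with_seed(substream_seed(cfg$seed, "svm"), {
        e1071::svm(x = X, y = factor(labels, levels = c(0L, 1L)),
                   kernel = "linear", scale = FALSE)
      })
      structure(list(fit = fit, input_dim = ncol(X)),
                class = "baseline_svm")
    },
    knn = {
      structure(list(X = X, labels = labels, k = as.integer(k),
                     input_dim = ncol(X)),
                class = "baseline_knn")
    },
    abort(sprintf("unknown baseline kind '%s'", kind))
  )
}

#' @export
predict_scores.baseline_svm <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    abort("feature matrix width mismatch", class = "mirimmune_shape_error")
  }
  dv <- attr(predict(model$fit, X, decision.values = TRUE),
             "decision.values")
  v <- drop(dv)
  # orient so larger score = more positive-like, regardless of which class
  # libsvm treated as the first one
  if (grepl("^0/1$", colnames(dv)[1])) v <- -v
  unname(stats::plogis(v))
}

#' @export
predict_scores.baseline_knn <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    abort("feature matrix width mismatch", class = "mirimmune_shape_error")
  }
  # squared Euclidean distances via the expansion |a-b|^2 = |a|^2-2ab+|b|^2
  d2 <- outer(rowSums(X^2), rowSums(model$X^2), "+") -
    2 * tcrossprod(X, model$X)
  k <- min(model$k, ncol(d2))
  apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]
    mean(model$labels[nn])
  })
}

#' Serialize classifier parameters to a single self-describing archive
#'
#' Writes a JSON document holding a manifest (layer shapes, architecture)
#' plus base64-encoded IEEE-754 doubles for every weight array, so a
#' save/load round trip is bit-exact.
#'
#' @param params A `ccnet_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_ccnet <- function(params, path) {
  stopifnot(inherits(params, "ccnet_params"))
  enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8L))
  doc <- list(format = "mirimmune-ccnet", version = 1L,
              input_dim = params$input_dim, branches = list())
  for (branch in c("mlp", "cnn", "head")) {
    if (is.null(params[[branch]])) next
    doc$branches[[branch]] <- lapply(params[[branch]], function(lay) {
      meta <- lay[setdiff(names(lay), c("W", "b"))]
      c(meta, list(W_dim = dim(lay$W), W = enc(lay$W), b = enc(lay$b)))
    })
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load classifier parameters saved by [save_ccnet()]
#'
#' @param path File written by [save_ccnet()].
#' @return A `ccnet_params` object, bit-identical to the one saved.
#' @export
load_ccnet <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "mirimmune-ccnet")) {
    abort("not a mirimmune classifier archive",
          class = "mirimmune_format_error")
  }
  dec <- function(s) {
    r <- jsonlite::base64_dec(s)
    readBin(r, "double", n = length(r) %/% 8L, size = 8L)
  }
  params <- list(input_dim = as.integer(doc$input_dim))
  for (branch in c("mlp", "cnn", "head")) {
    layers <- doc$branches[[branch]]
    if (is.null(layers)) {
      params[branch] <- list(NULL)
      next
    }
    params[[branch]] <- lapply(layers, function(lay) {
      wd <- as.integer(unlist(lay$W_dim))
      out <- list(W = matrix(dec(lay$W), wd[1], wd[2]), b = dec(lay$b))
      for (nm in setdiff(names(lay), c("W_dim", "W", "b"))) {
        v <- lay[[nm]]
        out[[nm]] <- if (is.numeric(v)) as.integer(v) else v
      }
      out
    })
  }
  structure(params, class = "ccnet_params")
}
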