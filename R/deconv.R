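#' Deconvolve one bulk expression sample into cell-type fractions
#'
#' Signature-based deconvolution in the CIBERSORT style: the mixture is
#' restricted to the signature genes, both the mixture and each signature
#' column are z-scored, and a linear nu-support-vector regression of the
#' mixture on the signature columns is solved for nu in {0.25, 0.5, 0.75}.
#' The fit with the lowest reconstruction RMSE (in standardized space) is
#' kept; its coefficients are mapped back to the original expression scale
#' (a z-space weight w_j corresponds to w_j / sd_j worth of column j),
#' clipped at zero and renormalized to sum to 1, so that a mixture composed
#' as `signature %*% p` returns `p` rather than an sd-weighted version of
#' it.  Z-scoring makes the result invariant to positive rescaling of the
#' mixture.
#'
#' @param signature Nonnegative genes-by-cell-types reference matrix with
#'   row and column names.
#' @param mixture Named expression vector covering (a superset of) the
#'   signature genes.
#' @param nu_grid Candidate nu values.
#' @param cost SVR cost parameter (large values weight data fit over the
#'   ridge-like margin penalty, keeping noise-free mixtures nearly exact).
#' @return A list of class `deconv_fit`: `proportions` (named, simplex),
#'   `rmse`, `r` (correlation of the reconstruction), `nu`.
#' @export
deconvolve_sample <- function(signature, mixture,
                              nu_grid = c(0.25, 0.5, 0.75), cost = 100) {
  signature <- as.matrix(signature)
  if (any(colSums(signature != 0) == 0)) {
    abort("signature has an all-zero column", class = "mirimmune_validation_error")
  }
  shared <- intersect(rownames(signature), names(mixture))
  if (length(shared) < 2L) {
    abort("fewer than 2 genes shared between signature and mixture",
          class = "mirimmune_validation_error")
  }
  m <- as.numeric(mixture[shared])
  S <- signature[shared, , drop = FALSE]
  if (all(m == 0)) {
    abort("all-zero mixture", class = "mirimmune_validation_error")
  }
  col_sd <- apply(S, 2L, sd)
  if (any(col_sd == 0)) {
    abort("signature has a constant column", class = "mirimmune_validation_error")
  }
  mz <- (m - mean(m)) / sd(m)
  Sz <- scale(S)
  best <- NULL
  for (nu in nu_grid) {
    fit <- e1071::svm(x = Sz, y = mz, type = "nu-regression",
                      kernel = "linear", nu = nu, cost = cost,
                      scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    w[w < 0] <- 0
    if (sum(w) == 0) {
      warn("all SVR coefficients non-positive; returning uniform fractions")
      w <- rep(1, ncol(S))
    }
    wn <- w / sum(w)
    recon <- drop(Sz %*% wn)
    rmse <- sqrt(mean((recon - mz)^2))
    p <- w / col_sd          # back to the original expression scale
    p <- p / sum(p)
    if (is.null(best) || rmse < best$rmse) {
      best <- list(proportions = stats::setNames(p, colnames(S)),
                   rmse = rmse, r = cor(recon, mz), nu = nu)
    }
  }
  structure(best, class = "deconv_fit")
}

#' Deconvolve a cohort of bulk samples
#'
#' Applies [deconvolve_sample()] to every column of an expression matrix.
#' Per-sample failures are logged and reported as `NA` rows rather than
#' aborting the cohort.
#'
#' @param signature Genes-by-cell-types reference matrix.
#' @param expression Genes-by-samples expression matrix.
#' @inheritParams deconvolve_sample
#' @return Tibble with `sample_id`, one column per cell type, and fit
#'   diagnostics `.rmse`, `.r`, `.nu`.
#' @export
deconvolve_cohort <- function(signature, expression,
                              nu_grid = c(0.25, 0.5, 0.75), cost = 100) {
  expression <- as.matrix(expression)
  if (ncol(expression) == 0L) {
    abort("empty expression matrix", class = "mirimmune_validation_error")
  }
  samples <- colnames(expression) %||% sprintf("sample%03d", seq_len(ncol(expression)))
  types <- colnames(signature)
  rows <- lapply(seq_len(ncol(expression)), function(j) {
    fit <- tryCatch(
      deconvolve_sample(signature, expression[, j], nu_grid, cost),
      error = function(e) {
        warn(sprintf("sample '%s' failed to deconvolve: %s", samples[j],
                     conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) {
      p <- stats::setNames(rep(NA_real_, length(types)), types)
      diag <- c(.rmse = NA_real_, .r = NA_real_, .nu = NA_real_)
    } else {
      p <- fit$proportions
      diag <- c(.rmse = fit$rmse, .r = fit$r, .nu = fit$nu)
    }
    tibble::as_tibble_row(c(list(sample_id = samples[j]),
                            as.list(p), as.list(diag)))
  })
  dplyr::bind_rows(rows)
}

#' Rank cell types by mean abundance across a cohort
#'
#' @param proportions A proportions table from [deconvolve_cohort()] (or
#'   any data frame of samples by cell-type fractions; diagnostic columns
#'   starting with `.` and a `sample_id` column are ignored).
#' @param top_k Optionally keep only the `top_k` most abundant types.
#' @return Tibble with `cell_type`, `mean`, `median`, `rank`, sorted by
#'   decreasing mean abundance.
#' @export
abundance_summary <- function(proportions, top_k = NULL) {
  df <- as.data.frame(proportions)
  df <- df[, setdiff(names(df), "sample_id"), drop = FALSE]
  df <- df[, !startsWith(names(df), "."), drop = FALSE]
  out <- tibble::tibble(
    cell_type = names(df),
    mean = vapply(df, function(v) mean(v, na.rm = TRUE), numeric(1)),
    median = vapply(df, function(v) median(v, na.rm = TRUE), numeric(1))
  )
  out <- dplyr::arrange(out, dplyr::desc(mean), cell_type)
  out$rank <- seq_len(nrow(out))
  if (!is.null(top_k)) out <- head(out, top_k)
  out
}
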