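#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the selected coefficients of a penalized Cox fit
#'
#' @param x A `lasso_cox_fit`.
#' @param all Include zero coefficients too.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `selected`.
#' @export
tidy.lasso_cox_fit <- function(x, all = FALSE, ...) {
  out <- tibble::tibble(term = names(x$coefficients),
                        estimate = unname(x$coefficients),
                        selected = x$coefficients != 0)
  if (!all) out <- out[out$selected, ]
  out
}

#' One-row summary of a penalized Cox fit
#'
#' @param x A `lasso_cox_fit`.
#' @param ... Unused.
#' @return Tibble with `lambda`, `lambda_min`, `lambda_1se`, `n_selected`.
#' @export
glance.lasso_cox_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, lambda_min = x$lambda_min,
                 lambda_1se = x$lambda_1se,
                 n_selected = length(x$selected_genes))
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-fold tibble (`fold`, `auc`, `aupr`).
#' @export
tidy.cv_result <- function(x, ...) x$per_fold

#' One-row summary of a cross-validation run
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with `k`, `mean_auc`, `mean_aupr`.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(k = nrow(x$per_fold), mean_auc = x$mean_auc,
                 mean_aupr = x$mean_aupr)
}

#' Tidy the loss history of a fitted classifier
#'
#' @param x A `ccnet_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`.
#' @export
tidy.ccnet_fit <- function(x, ...) x$history

#' One-row summary of a fitted classifier
#'
#' @param x A `ccnet_fit`.
#' @param ... Unused.
#' @return Tibble with `arch`, `epochs_run`, `final_loss`.
#' @export
glance.ccnet_fit <- function(x, ...) {
  tibble::tibble(arch = x$arch, epochs_run = nrow(x$history),
                 final_loss = x$history$loss[nrow(x$history)])
}

#' @export
print.ccnet_fit <- function(x, ...) {
  cat(sprintf("<ccnet_fit> %s, input_dim = %d, %d epochs, final loss %.4f\n",
              x$arch, x$params$input_dim, nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds: mean AUC %.3f, mean AUPR %.3f\n",
              nrow(x$per_fold), x$mean_auc, x$mean_aupr))
  invisible(x)
}

#' @export
print.immune_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<immune_summary> %d miRNAs -> %d target genes, ",
                     "%d immune-related, %d miRNAs with immune targets\n"),
              s$n_mirnas_in, s$n_target_genes, s$n_immune_targets,
              s$n_mirnas_with_immune_targets))
  invisible(x)
}

#' @export
print.lasso_cox_fit <- function(x, ...) {
  cat(sprintf("<lasso_cox_fit> lambda = %.4g; %d gene(s) selected: %s\n",
              x$lambda, length(x$selected_genes),
              paste(x$selected_genes, collapse = ", ")))
  invisible(x)
}
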