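#' @importFrom ggplot2 ggplot aes geom_line geom_step geom_col geom_abline
#'   labs theme_minimal autoplot coord_flip
NULL

#' Plot per-fold and mean ROC (or PR) curves of a cross-validation run
#'
#' @param x A `cv_result`.
#' @param type `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(x, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    folds <- purrr::imap(x$fold_curves, function(cv, i) {
      dplyr::mutate(cv$roc, fold = factor(i))
    })
    p <- ggplot(dplyr::bind_rows(folds), aes(x = .data$fpr, y = .data$tpr)) +
      geom_step(aes(group = .data$fold), alpha = 0.3) +
      geom_line(data = x$mean_roc, linewidth = 1, colour = "#d1495b") +
      geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      labs(x = "False positive rate", y = "True positive rate",
           title = sprintf("ROC, mean AUC = %.3f", x$mean_auc))
  } else {
    folds <- purrr::imap(x$fold_curves, function(cv, i) {
      dplyr::mutate(cv$pr, fold = factor(i))
    })
    p <- ggplot(dplyr::bind_rows(folds),
                aes(x = .data$recall, y = .data$precision)) +
      geom_step(aes(group = .data$fold), alpha = 0.3) +
      geom_line(data = x$mean_pr, linewidth = 1, colour = "#d1495b") +
      labs(x = "Recall", y = "Precision",
           title = sprintf("Precision-recall, mean AUPR = %.3f", x$mean_aupr))
  }
  p + theme_minimal()
}

#' Plot Kaplan-Meier curves for two groups
#'
#' @param low,high `km_curve` tibbles (as from [km_curve()]).
#' @param label Name of the dichotomized variable, used in the title.
#' @param p_value Optional log-rank p-value to annotate.
#' @return A ggplot object.
#' @export
plot_km <- function(low, high, label = "expression", p_value = NULL) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(low), group = "low"),
    dplyr::mutate(tibble::as_tibble(high), group = "high"))
  # prepend the (0, 1) anchor per group so curves start at S(0) = 1
  anchor <- tibble::tibble(time = 0, n_risk = NA_integer_,
                           n_event = NA_integer_, n_censor = NA_integer_,
                           surv = 1, group = c("low", "high"))
  ttl <- sprintf("Survival by %s level", label)
  if (!is.null(p_value)) ttl <- sprintf("%s (log-rank p = %.3g)", ttl, p_value)
  ggplot(dplyr::bind_rows(anchor, df),
         aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step(linewidth = 0.8) +
    labs(x = "Time", y = "Survival probability", title = ttl,
         colour = label) +
    theme_minimal()
}

#' Stacked-bar plot of estimated cell-type proportions
#'
#' @param proportions Output of [deconvolve_cohort()].
#' @return A ggplot object.
#' @export
plot_proportions <- function(proportions) {
  df <- tidyr::pivot_longer(
    proportions[, !startsWith(names(proportions), "."), drop = FALSE],
    -"sample_id", names_to = "cell_type", values_to = "fraction")
  ggplot(df, aes(x = .data$sample_id, y = .data$fraction,
                 fill = .data$cell_type)) +
    geom_col() +
    labs(x = NULL, y = "Estimated fraction", fill = "Cell type") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Bar plot of the top enriched gene sets
#'
#' @param records Output of [enrich_query()].
#' @return A ggplot object of -log10 adjusted p by set.
#' @export
plot_enrichment <- function(records) {
  df <- dplyr::mutate(records,
                      set_name = stats::reorder(.data$set_name,
                                                -.data$p_value))
  ggplot(df, aes(x = .data$set_name, y = -log10(.data$adjusted_p))) +
    geom_col(fill = "#2e6f95") +
    coord_flip() +
    labs(x = NULL, y = expression(-log[10] ~ "adjusted p")) +
    theme_minimal()
}
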