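#' Construct a survival cohort
#'
#' Pairs a samples-by-genes expression matrix with follow-up time and event
#' status.  Rows with missing covariates are dropped (with a message), as
#' are non-positive times.
#'
#' @param expression Numeric matrix, samples in rows, genes in columns.
#' @param time Positive follow-up times (one unit throughout, e.g. days).
#' @param event 0/1 event indicators (1 = death observed).
#' @param sample_ids Optional sample identifiers (defaults to the matrix
#'   rownames).
#' @param true_beta Optional named vector of true coefficients (synthetic
#'   ground truth; carried along for benchmarking).
#' @return A list of class `survival_cohort` with `expression` and
#'   `survival` (tibble: `sample_id`, `time`, `event`).
#' @export
survival_cohort <- function(expression, time, event, sample_ids = NULL,
                            true_beta = NULL) {
  expression <- as.matrix(expression)
  sample_ids <- sample_ids %||% rownames(expression) %||%
    sprintf("sample%04d", seq_len(nrow(expression)))
  stopifnot(nrow(expression) == length(time),
            length(time) == length(event))
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) {
    abort("`event` must be 0/1", class = "mirimmune_validation_error")
  }
  keep <- stats::complete.cases(expression) & !is.na(time) & time > 0
  if (any(!keep)) {
    inform(sprintf("dropped %d samples with missing covariates or non-positive times",
                   sum(!keep)))
  }
  rownames(expression) <- sample_ids
  structure(list(
    expression = expression[keep, , drop = FALSE],
    survival = tibble::tibble(sample_id = sample_ids[keep],
                              time = as.numeric(time[keep]),
                              event = event[keep]),
    true_beta = true_beta
  ), class = "survival_cohort")
}

# Breslow estimate of the cumulative baseline hazard H0(t) given a linear
# predictor: H0(t) = sum over event times <= t of d_i / sum(at risk exp(lp)).
breslow_baseline <- function(time, event, lp) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; elp <- exp(lp[ord])
  risk_tail <- rev(cumsum(rev(elp)))
  ev_times <- unique(time[event == 1L])
  haz <- vapply(ev_times, function(t) {
    d <- sum(event == 1L & time == t)
    d / risk_tail[match(t, time)]
  }, numeric(1))
  tibble::tibble(time = ev_times, hazard = haz, cumhaz = cumsum(haz))
}

#' LASSO-penalized Cox proportional-hazards gene selection
#'
#' Fits the L1-penalized Cox partial likelihood over a grid of penalties
#' and selects the penalty by k-fold cross-validated partial-likelihood
#' deviance.  Covariates are standardized internally; reported coefficients
#' are on the original expression scale.  Both the deviance-minimizing
#' `lambda_min` and the one-standard-error `lambda_1se` choices are
#' reported; selection defaults to `lambda_min`.  Ties in event times use
#' the Breslow approximation.
#'
#' @param cohort A [survival_cohort()].
#' @param lambda Optional penalty grid (decreasing); default lets the path
#'   algorithm choose.
#' @param nfolds Number of cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @param lambda_choice `"lambda_min"` (default) or `"lambda_1se"`.
#' @return A list of class `lasso_cox_fit`: `coefficients` (named vector at
#'   the chosen penalty), `selected_genes` (nonzero support), `lambda`,
#'   `lambda_min`, `lambda_1se`, `cv` (tibble of the deviance path),
#'   `baseline` (Breslow cumulative baseline hazard), and the underlying
#'   `glmnet` objects.
#' @export
fit_lasso_cox <- function(cohort, lambda = NULL, nfolds = 10, seed = 1,
                          lambda_choice = c("lambda_min", "lambda_1se")) {
  stopifnot(inherits(cohort, "survival_cohort"))
  lambda_choice <- match.arg(lambda_choice)
  X <- cohort$expression
  y <- survival::Surv(cohort$survival$time, cohort$survival$event)
  if (sum(cohort$survival$event) < 2) {
    abort("need at least 2 observed events", class = "mirimmune_validation_error")
  }
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant covariates", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
  }
  single_lambda <- !is.null(lambda) && length(lambda) == 1L
  if (single_lambda) {
    # approach the requested penalty along a decreasing path so the
    # coordinate-descent warm starts converge tightly
    path <- exp(seq(log(max(0.5, lambda + 0.5)), log(max(lambda, 1e-4)),
                    length.out = 30))
    if (lambda == 0) path <- c(path, 0)
    fit <- glmnet::glmnet(X, y, family = "cox", lambda = path,
                          standardize = TRUE, thresh = 1e-12,
                          maxit = 1e6)
    co <- coef(fit, s = lambda, exact = FALSE)
    cf <- drop(as.matrix(co))
    names(cf) <- colnames(X)
    lp <- drop(X %*% cf)
    return(structure(list(
      coefficients = cf,
      selected_genes = names(cf)[cf != 0],
      lambda = lambda, lambda_min = lambda, lambda_1se = lambda,
      cv = NULL,
      baseline = breslow_baseline(cohort$survival$time,
                                  cohort$survival$event, lp),
      glmnet_fit = fit, cv_fit = NULL
    ), class = "lasso_cox_fit"))
  }
  foldid <- integer(nrow(X))
  with_seed(substream_seed(seed, "lasso_cox"), {
    # event-stratified folds so every fold sees events
    for (idx in split(seq_len(nrow(X)), cohort$survival$event)) {
      foldid[idx[sample.int(length(idx))]] <- rep_len(seq_len(nfolds),
                                                      length(idx))
    }
  })
  cvfit <- glmnet::cv.glmnet(X, y, family = "cox", lambda = lambda,
                             foldid = foldid,
                             type.measure = "deviance", standardize = TRUE)
  lam <- if (lambda_choice == "lambda_min") cvfit$lambda.min else cvfit$lambda.1se
  cf <- drop(as.matrix(coef(cvfit, s = lam)))
  names(cf) <- colnames(X)
  lp <- drop(X %*% cf)
  structure(list(
    coefficients = cf,
    selected_genes = names(cf)[cf != 0],
    lambda = lam, lambda_min = cvfit$lambda.min, lambda_1se = cvfit$lambda.1se,
    cv = tibble::tibble(lambda = cvfit$lambda, deviance = cvfit$cvm,
                        deviance_se = cvfit$cvsd,
                        nonzero = cvfit$nzero),
    baseline = breslow_baseline(cohort$survival$time, cohort$survival$event,
                                lp),
    glmnet_fit = cvfit$glmnet.fit, cv_fit = cvfit
  ), class = "lasso_cox_fit")
}

#' Linear-predictor risk score
#'
#' `score_i = sum_g alpha_g * x_ig` over the model's genes.
#'
#' @param model A `lasso_cox_fit` (or any list with a named `coefficients`
#'   vector).
#' @param cohort A [survival_cohort()] or a samples-by-genes matrix.
#' @return Named numeric vector of risk scores, one per sample.
#' @export
risk_score <- function(model, cohort) {
  X <- if (inherits(cohort, "survival_cohort")) cohort$expression else as.matrix(cohort)
  cf <- model$coefficients
  missing <- setdiff(names(cf), colnames(X))
  if (length(missing) > 0) {
    abort(sprintf("expression matrix lacks model gene(s): %s",
                  paste(missing, collapse = ", ")),
          class = "mirimmune_validation_error")
  }
  drop(X[, names(cf), drop = FALSE] %*% cf)
}

#' Split values into high/low groups at the median
#'
#' `high` is strictly above the median; ties at the median go to `low`.
#'
#' @param values Numeric vector (>= 2 values, not all identical).
#' @param rule Only `"median"` is implemented.
#' @return Factor with levels `low`, `high`, same order as `values`.
#' @examples
#' dichotomize(c(1, 2, 3, 4))
#' @export
dichotomize <- function(values, rule = "median") {
  stopifnot(rule == "median", length(values) >= 2)
  if (length(unique(values)) == 1L) {
    abort("all values identical: degenerate split",
          class = "mirimmune_validation_error")
  }
  m <- median(values)
  factor(ifelse(values > m, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators; censored times reduce the at-risk
#'   count without producing a step.
#' @return Tibble of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @examples
#' km_curve(c(1, 2, 3), c(0, 1, 1))
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) > 0, all(time > 0))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        surv = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with 1 degree of
#' freedom; the p-value is the upper chi-square tail.
#'
#' @param group_a,group_b Data frames (or tibbles) with columns `time` and
#'   `event`.
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(group_a, group_b) {
  stopifnot(nrow(group_a) > 0, nrow(group_b) > 0)
  time <- c(group_a$time, group_b$time)
  event <- as.integer(c(group_a$event, group_b$event))
  if (sum(event) == 0L) {
    abort("no events in either group", class = "mirimmune_validation_error")
  }
  grp <- rep(c("a", "b"), c(nrow(group_a), nrow(group_b)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  stat <- sd_$chisq
  tibble::tibble(statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Per-gene and risk-group survival analysis
#'
#' For each gene (or for a risk score), dichotomizes the cohort at the
#' median, computes the two Kaplan-Meier curves and the log-rank p-value --
#' the per-gene survival-curve panel of the prognostic stage.
#'
#' @param cohort A [survival_cohort()].
#' @param genes Character vector of gene columns to test.
#' @param values Optional numeric vector (e.g. a risk score) to test
#'   instead of gene columns; when given, `genes` is ignored and the
#'   result has one row named `risk_score`.
#' @return Tibble with one row per gene: `gene`, `p_value`, `statistic`,
#'   and list-columns `km_low`, `km_high`.
#' @export
survival_by_median <- function(cohort, genes = NULL, values = NULL) {
  stopifnot(inherits(cohort, "survival_cohort"))
  sv <- cohort$survival
  one <- function(name, v) {
    grp <- dichotomize(v)
    a <- sv[grp == "low", ]
    b <- sv[grp == "high", ]
    lr <- logrank_test(a, b)
    tibble::tibble(gene = name, statistic = lr$statistic,
                   p_value = lr$p_value,
                   km_low = list(km_curve(a$time, a$event)),
                   km_high = list(km_curve(b$time, b$event)))
  }
  if (!is.null(values)) return(one("risk_score", values))
  dplyr::bind_rows(lapply(genes, function(g) {
    one(g, cohort$expression[, g])
  }))
}
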