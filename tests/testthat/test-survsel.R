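toy_cohort <- function(n = 100, p = 3, beta = c(1, -1, 0), seed = 7,
                       censor = 0.2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("g", seq_len(p))))
  t_ev <- rexp(n, rate = 0.1 * exp(drop(X %*% beta)))
  cens <- stats::quantile(t_ev, 1 - censor)
  event <- as.integer(t_ev <= cens)
  survival_cohort(X, pmin(t_ev, cens) + 1e-9, event)
}

test_that("kaplan-meier product-limit matches hand-computed tables", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  km2 <- km_curve(c(1, 2, 3), c(0, 1, 1))
  expect_equal(km2$surv[km2$time == 2], 1 / 2)
  expect_equal(km2$surv[km2$time == 3], 0)

  km3 <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km3$surv == 1))

  # survival starts at 1 and never increases
  set.seed(1)
  km4 <- km_curve(rexp(50) + 0.1, rbinom(50, 1, 0.7))
  expect_true(all(diff(km4$surv) <= 0))
  expect_true(all(km4$surv >= 0 & km4$surv <= 1))
})

test_that("log-rank test matches the hand-computed O-E/V table", {
  a <- tibble::tibble(time = c(1, 2), event = c(1, 1))
  b <- tibble::tibble(time = c(3, 4), event = c(1, 1))
  lr <- logrank_test(a, b)
  # by hand: O_A = 2, E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36,
  # statistic = (2 - 5/6)^2 / (17/36) = 49/17
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-6)
  expect_equal(lr$p_value, pchisq(49 / 17, 1, lower.tail = FALSE),
               tolerance = 1e-9)

  same <- tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1))
  lr0 <- logrank_test(same, same)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # invariance under group relabeling
  expect_equal(logrank_test(b, a)$statistic, lr$statistic, tolerance = 1e-12)
  expect_error(logrank_test(tibble::tibble(time = 1, event = 0),
                            tibble::tibble(time = 2, event = 0)),
               class = "mirimmune_validation_error")
})

test_that("median dichotomization follows the stated tie convention", {
  expect_identical(as.character(dichotomize(c(1, 2, 3, 4))),
                   c("low", "low", "high", "high"))
  expect_identical(as.character(dichotomize(c(1, 1, 2))),
                   c("low", "low", "high"))
  v <- c(5, 1, 3, 2, 4)
  perm <- c(2, 4, 3, 5, 1)
  expect_identical(dichotomize(v)[perm], dichotomize(v[perm]))
  expect_error(dichotomize(c(2, 2, 2)), class = "mirimmune_validation_error")
})

test_that("risk scores are the linear predictor and scale linearly", {
  coh <- toy_cohort()
  model <- list(coefficients = c(g1 = 0.5, g2 = -1))
  rs <- risk_score(model, coh)
  expect_equal(rs, drop(coh$expression[, c("g1", "g2")] %*% c(0.5, -1)))
  model2 <- list(coefficients = 2 * model$coefficients)
  expect_equal(risk_score(model2, coh), 2 * rs)
  expect_equal(unique(risk_score(list(coefficients = c(g1 = 0)), coh)), 0)
  expect_error(risk_score(list(coefficients = c(nope = 1)), coh), "nope")
})

test_that("unpenalized fit matches a generic-optimizer partial-likelihood maximum", {
  coh <- toy_cohort(n = 100, p = 3)
  fit <- fit_lasso_cox(coh, lambda = 0)
  oracle <- optim(rep(0, 3), cox_nll_oracle, X = coh$expression,
                  time = coh$survival$time, event = coh$survival$event,
                  method = "BFGS", control = list(reltol = 1e-14))
  expect_lt(max(abs(fit$coefficients - oracle$par)), 1e-3)
  # and agrees with the survival package's independent implementation
  cph <- survival::coxph(
    survival::Surv(coh$survival$time, coh$survival$event) ~ coh$expression,
    ties = "breslow")
  expect_lt(max(abs(fit$coefficients - unname(coef(cph)))), 1e-3)
})

test_that("penalization shrinks to zero and the path support is monotone", {
  coh <- toy_cohort(n = 120, p = 8, beta = c(1, -1, rep(0, 6)), seed = 3)
  big <- fit_lasso_cox(coh, lambda = 50)
  expect_true(all(big$coefficients == 0))
  expect_length(big$selected_genes, 0)

  cvfit <- fit_lasso_cox(coh, nfolds = 5, seed = 2)
  nz <- cvfit$glmnet_fit$df            # nonzero count along decreasing lambda
  expect_true(all(diff(nz) >= 0))
  expect_identical(cvfit$selected_genes,
                   names(cvfit$coefficients)[cvfit$coefficients != 0])
  expect_true(all(diff(cvfit$baseline$cumhaz) > 0))
  g <- glance(cvfit)
  expect_identical(g$n_selected, length(cvfit$selected_genes))
  td <- tidy(cvfit)
  expect_true(all(td$estimate != 0))
})

test_that("constant covariates are dropped with a warning", {
  coh <- toy_cohort(n = 60, p = 3)
  coh$expression[, 2] <- 1
  expect_warning(fit <- fit_lasso_cox(coh, lambda = 0.1), "constant")
  expect_false("g2" %in% names(fit$coefficients))
})

test_that("pooled KM curve lies between the two group curves", {
  set.seed(9)
  t1 <- rexp(60, 0.1); t2 <- rexp(60, 0.3)
  e1 <- rbinom(60, 1, 0.8); e2 <- rbinom(60, 1, 0.8)
  kmA <- km_curve(t1, e1); kmB <- km_curve(t2, e2)
  kmP <- km_curve(c(t1, t2), c(e1, e2))
  step_at <- function(km, t) {
    i <- findInterval(t, km$time)
    if (i == 0) 1 else km$surv[i]
  }
  for (t in stats::quantile(c(t1, t2), c(0.2, 0.5, 0.8))) {
    sP <- step_at(kmP, t)
    expect_gte(sP, min(step_at(kmA, t), step_at(kmB, t)) - 1e-12)
    expect_lte(sP, max(step_at(kmA, t), step_at(kmB, t)) + 1e-12)
  }
})

test_that("median-split survival analysis returns one record per gene", {
  coh <- toy_cohort(n = 80, p = 3, beta = c(1.5, 0, 0), seed = 5)
  res <- survival_by_median(coh, genes = c("g1", "g2"))
  expect_identical(res$gene, c("g1", "g2"))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # a strong true effect should separate the curves more than a null gene
  expect_lt(res$p_value[1], res$p_value[2])
  rs <- risk_score(list(coefficients = c(g1 = 1.5)), coh)
  rr <- survival_by_median(coh, values = rs)
  expect_identical(rr$gene, "risk_score")
})
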