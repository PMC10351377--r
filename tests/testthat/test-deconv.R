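toy_signature <- function(n_types = 4, markers = 6, seed = 1) {
  set.seed(seed)
  n_genes <- n_types * markers
  sig <- matrix(runif(n_genes * n_types, 0.5, 1.5), n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("ct%d", seq_len(n_types))))
  for (ct in seq_len(n_types)) {
    sig[(ct - 1) * markers + seq_len(markers), ct] <- runif(markers, 8, 12)
  }
  sig
}

test_that("pure samples deconvolve to a unit fraction", {
  sig <- toy_signature()
  for (ct in seq_len(ncol(sig))) {
    mix <- sig[, ct]
    fit <- deconvolve_sample(sig, mix)
    expect_lt(abs(fit$proportions[ct] - 1), 1e-3)
    expect_lt(max(fit$proportions[-ct]), 1e-3)
  }
})

test_that("a noise-free two-type mixture is recovered within 1e-2", {
  sig <- toy_signature()
  mix <- 0.3 * sig[, 1] + 0.7 * sig[, 2]
  fit <- deconvolve_sample(sig, mix)
  expect_lt(abs(fit$proportions[1] - 0.3), 1e-2)
  expect_lt(abs(fit$proportions[2] - 0.7), 1e-2)
  expect_lt(sum(fit$proportions[3:4]), 1e-2)
  expect_lt(abs(sum(fit$proportions) - 1), 1e-9)
  # nonnegative least squares on the original scale as independent oracle
  w <- pracma::lsqnonneg(sig, as.numeric(mix))$x
  w <- w / sum(w)
  expect_lt(max(abs(fit$proportions - w)), 0.02)
})

test_that("recovered fractions are scale-invariant in the mixture", {
  sig <- toy_signature()
  set.seed(3)
  p <- c(0.4, 0.3, 0.2, 0.1)
  mix <- drop(sig %*% p) + rnorm(nrow(sig), sd = 0.2)
  mix <- pmax(mix, 0)
  f1 <- deconvolve_sample(sig, mix)
  f2 <- deconvolve_sample(sig, 1000 * mix)
  expect_lt(max(abs(f1$proportions - f2$proportions)), 1e-6)
})

test_that("an absent cell type barely perturbs the others", {
  sig5 <- toy_signature(n_types = 5, markers = 6)
  sig4 <- sig5[, 1:4]
  p <- c(0.4, 0.3, 0.2, 0.1)
  mix <- drop(sig4 %*% p)
  f4 <- deconvolve_sample(sig4, mix[rownames(sig4)])
  f5 <- deconvolve_sample(sig5, mix)
  expect_lt(max(abs(f5$proportions[1:4] - f4$proportions)), 0.02)
  expect_lt(f5$proportions[5], 0.02)
})

test_that("degenerate inputs are rejected", {
  sig <- toy_signature()
  expect_error(deconvolve_sample(sig, setNames(rep(0, nrow(sig)),
                                               rownames(sig))),
               class = "mirimmune_validation_error")
  expect_error(deconvolve_sample(sig, c(x = 1, y = 2)),
               class = "mirimmune_validation_error")
  sig0 <- sig; sig0[, 2] <- 0
  expect_error(deconvolve_sample(sig0, sig[, 1]),
               class = "mirimmune_validation_error")
})

test_that("cohort deconvolution is column-order equivariant and row-normalized", {
  cfg <- synth_config(n_cell_types = 4, markers_per_type = 6,
                      n_mixture_samples = 8, mixture_noise_sd = 0.3, seed = 6)
  mix <- generate_mixtures(cfg)
  tab <- deconvolve_cohort(mix$signature, mix$mixtures)
  types <- colnames(mix$signature)
  expect_true(all(abs(rowSums(tab[, types]) - 1) < 1e-9))
  perm <- c(3, 1, 4, 2)
  tab2 <- deconvolve_cohort(mix$signature[, perm], mix$mixtures)
  # the SVR solver's iteration path depends on column order, so equality is
  # numerical rather than exact
  expect_lt(max(abs(as.matrix(tab2[, types[perm]]) -
                      as.matrix(tab[, types[perm]]))), 2e-3)
})

test_that("abundance summaries rank by mean fraction and sum to one", {
  tab <- tibble::tibble(sample_id = c("s1", "s2"),
                        a = c(0.5, 0.3), b = c(0.3, 0.5), c = c(0.2, 0.2),
                        .rmse = c(0, 0), .r = c(1, 1), .nu = c(0.5, 0.5))
  s <- abundance_summary(tab)
  expect_identical(s$cell_type[3], "c")
  expect_identical(s$rank, 1:3)
  expect_lt(abs(sum(s$mean) - 1), 1e-9)
  one <- abundance_summary(tab[1, ])
  expect_equal(unname(one$mean), c(0.5, 0.3, 0.2))
  expect_identical(nrow(abundance_summary(tab, top_k = 2)), 2L)
})

test_that("designated abundant cell types occupy the top ranks", {
  hits <- 0
  for (seed in 1:15) {
    cfg <- synth_config(n_cell_types = 6, markers_per_type = 6,
                        n_mixture_samples = 25,
                        dirichlet_alpha = c(5, 5, 5, 1, 1, 1),
                        mixture_noise_sd = 0.3, seed = seed)
    mix <- generate_mixtures(cfg)
    tab <- deconvolve_cohort(mix$signature, mix$mixtures)
    top3 <- abundance_summary(tab, top_k = 3)$cell_type
    if (setequal(top3, colnames(mix$signature)[1:3])) hits <- hits + 1
  }
  expect_gte(hits, 14)
})
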