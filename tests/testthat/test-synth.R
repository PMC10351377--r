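test_that("synth_config validates its fields and names the offender", {
  expect_error(synth_config(n_mirna = 10, n_positive = 8, n_negative = 8),
               "n_positive")
  expect_error(synth_config(base_target_density = 1.5), "base_target_density")
  expect_error(synth_config(n_gene = 50, disease_module_size = 60),
               "disease_module_size")
  expect_error(synth_config(true_beta = numeric(0)), "true_beta")
  expect_error(synth_config(true_beta = c(nosuchgene = 1)), "nosuchgene")
})

test_that("association generator is deterministic and honours densities", {
  cfg <- synth_config(n_mirna = 50, n_gene = 80, n_positive = 10,
                      n_negative = 15, disease_module_size = 10,
                      immune_set_size = 12, seed = 7)
  a <- generate_associations(cfg)
  b <- generate_associations(cfg)
  expect_identical(a, b)
  c2 <- generate_associations(synth_config(n_mirna = 50, n_gene = 80,
                                           n_positive = 10, n_negative = 15,
                                           disease_module_size = 10,
                                           immune_set_size = 12, seed = 8))
  expect_false(identical(a$matrix, c2$matrix))

  # degenerate density: zero everywhere
  cfg0 <- synth_config(n_mirna = 20, n_gene = 30, n_positive = 5,
                       n_negative = 5, disease_module_size = 5,
                       immune_set_size = 5, base_target_density = 1e-12,
                       signal_boost = 1)
  z <- generate_associations(cfg0)
  expect_true(all(z$matrix == 0))
})

test_that("non-positive rows match the baseline Bernoulli density", {
  cfg <- synth_config(n_mirna = 2000, n_gene = 500, n_positive = 100,
                      n_negative = 400, disease_module_size = 50,
                      immune_set_size = 60, base_target_density = 0.01,
                      seed = 11)
  sim <- generate_associations(cfg)
  rows <- setdiff(rownames(sim$matrix), sim$positive_ids)
  n_cells <- length(rows) * ncol(sim$matrix)
  dens <- sum(sim$matrix[rows, ]) / n_cells
  se <- sqrt(0.01 * 0.99 / n_cells)
  expect_lt(abs(dens - 0.01), 3 * se)
  # positives over-target the module
  hi <- mean(sim$matrix[sim$positive_ids, sim$disease_module])
  expect_gt(hi, 0.03)
})

test_that("immune set overlaps the disease module by the configured count", {
  cfg <- synth_config(n_mirna = 40, n_gene = 200, n_positive = 10,
                      n_negative = 10, disease_module_size = 30,
                      immune_set_size = 20, immune_disease_overlap = 0.4)
  sim <- generate_associations(cfg)
  expect_length(sim$immune_set, 20)
  expect_identical(length(intersect(sim$immune_set, sim$disease_module)),
                   as.integer(floor(0.4 * 20)))
})

test_that("survival generator follows the proportional-hazards law", {
  # null effects: times are iid exponential(baseline) -- KS test
  cfg <- synth_config(n_gene = 5, n_patients = 2000,
                      disease_module_size = 3, immune_set_size = 3,
                      true_beta = c(gene0001 = 0), censor_fraction = 0,
                      baseline_hazard = 0.1, seed = 21)
  coh <- generate_survival(cfg)
  expect_true(all(coh$survival$event == 1L))
  ks <- suppressWarnings(stats::ks.test(coh$survival$time, "pexp", rate = 0.1))
  expect_gt(ks$p.value, 0.01)

  # nonzero effects: unpenalized Cox recovers them (consistency check)
  cfg2 <- synth_config(n_gene = 10, n_patients = 2000,
                       disease_module_size = 5, immune_set_size = 5,
                       true_beta = c(gene0001 = 1, gene0002 = -1),
                       censor_fraction = 0.2, seed = 22)
  coh2 <- generate_survival(cfg2)
  fit <- survival::coxph(
    survival::Surv(coh2$survival$time, coh2$survival$event) ~
      coh2$expression[, "gene0001"] + coh2$expression[, "gene0002"])
  expect_lt(abs(coef(fit)[1] - 1), 0.15)
  expect_lt(abs(coef(fit)[2] + 1), 0.15)

  # realized censoring approximates the target fraction
  cfg3 <- synth_config(n_gene = 5, n_patients = 2000,
                       disease_module_size = 3, immune_set_size = 3,
                       true_beta = c(gene0001 = 0.5),
                       censor_fraction = 0.4, seed = 23)
  coh3 <- generate_survival(cfg3)
  expect_lt(abs(mean(1 - coh3$survival$event) - 0.4), 0.06)
})

test_that("mixture generator produces simplex proportions and exact noise-free mixes", {
  cfg <- synth_config(n_cell_types = 4, markers_per_type = 6,
                      n_mixture_samples = 15, mixture_noise_sd = 0, seed = 5)
  mix <- generate_mixtures(cfg)
  expect_true(all(abs(rowSums(mix$proportions) - 1) < 1e-12))
  expect_true(all(mix$proportions >= 0))
  expect_equal(mix$mixtures, mix$signature %*% t(mix$proportions))
  expect_identical(mix, generate_mixtures(cfg))
  # markers are elevated for exactly one cell type per block
  expect_true(all(apply(mix$signature, 2, max) > 8))
})

test_that("gene-set generator plants the configured overlap", {
  cfg <- synth_config(n_gene = 300, disease_module_size = 40,
                      n_gene_sets = 10, planted_set_overlap = 1, seed = 2)
  sim <- generate_associations(cfg)
  gs <- generate_gene_sets(cfg, sim$disease_module)
  expect_setequal(gs$sets[[gs$planted_set]], sim$disease_module)
  expect_true(all(unlist(gs$sets) %in% gs$universe))

  cfg2 <- synth_config(n_gene = 300, disease_module_size = 40,
                       n_gene_sets = 10, planted_set_overlap = 0.5, seed = 2)
  gs2 <- generate_gene_sets(cfg2, sim$disease_module)
  expect_identical(length(intersect(gs2$sets[[gs2$planted_set]],
                                    sim$disease_module)),
                   as.integer(floor(0.5 * 40)))
})
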