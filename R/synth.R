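#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the synthetic benchmark into one validated
#' object.  The defaults emulate the real study conditions the pipeline was
#' designed around: a curated positive set of 133 disease-associated miRNAs
#' against 500 sampled negatives drawn from a universe of 2000 miRNAs and
#' 2000 target genes, a survival cohort of 174 patients, and a 22-cell-type
#' immune signature panel.
#'
#' Positive-class miRNAs over-target a hidden "disease module" of genes by a
#' factor `signal_boost`; all other miRNA-gene pairs are Bernoulli with
#' probability `base_target_density`.  An immune gene list overlaps the
#' disease module by `immune_disease_overlap * immune_set_size` genes, and
#' one gene set of the generated collection is planted to overlap the module
#' by `planted_set_overlap` of its size, so that every downstream stage has
#' known ground truth.
#'
#' @param n_mirna,n_gene Size of the miRNA and gene universes.
#' @param n_positive,n_negative Number of labeled positive / negative miRNAs.
#' @param disease_module_size Number of genes in the hidden disease module.
#' @param immune_set_size Number of immune-related genes.
#' @param immune_disease_overlap Fraction of the immune set drawn from the
#'   disease module.
#' @param base_target_density Baseline probability that a miRNA targets a
#'   gene (miRTarBase-like curated interactions are sparse; ~2% is typical
#'   of a few hundred targets per miRNA over a 2000-gene universe).
#' @param signal_boost Multiplier (>= 1) applied to `base_target_density`
#'   for positive miRNAs over disease-module genes; 1 means no signal.
#' @param n_patients Survival-cohort size.
#' @param true_beta Named numeric vector of true log-hazard coefficients
#'   over a subset of genes (Cox model ground truth).
#' @param baseline_hazard Constant baseline hazard rate of the exponential
#'   event-time model (arbitrary time unit).
#' @param censor_fraction Target fraction of right-censored patients.
#' @param n_cell_types,markers_per_type Immune-signature panel dimensions.
#' @param n_mixture_samples Number of bulk mixtures to simulate.
#' @param dirichlet_alpha Symmetric Dirichlet concentration (scalar) or a
#'   vector of length `n_cell_types` for the true cell-type proportions.
#' @param mixture_noise_sd Standard deviation of additive Gaussian noise on
#'   the mixtures (expression units; marker genes sit near 10, so the
#'   default 0.5 is ~5% of the marker signal).
#' @param n_gene_sets Number of gene sets in the generated collection.
#' @param planted_set_overlap Fraction of the planted set shared with the
#'   disease module.
#' @param seed Global integer seed; each generator draws from a named
#'   sub-stream derived from it.
#'
#' @return A validated list of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_mirna = 50, n_gene = 40, n_positive = 10,
#'                     n_negative = 20, disease_module_size = 8,
#'                     immune_set_size = 10)
#' @export
synth_config <- function(n_mirna = 2000, n_gene = 2000,
                         n_positive = 133, n_negative = 500,
                         disease_module_size = 100, immune_set_size = 150,
                         immune_disease_overlap = 0.5,
                         base_target_density = 0.02, signal_boost = 5,
                         n_patients = 174,
                         true_beta = c(gene0001 = 1, gene0002 = -1),
                         baseline_hazard = 0.1, censor_fraction = 0.3,
                         n_cell_types = 22, markers_per_type = 10,
                         n_mixture_samples = 100, dirichlet_alpha = 1,
                         mixture_noise_sd = 0.5,
                         n_gene_sets = 50, planted_set_overlap = 0.5,
                         seed = 1) {
  cfg <- list(
    n_mirna = check_count(n_mirna, "n_mirna"),
    n_gene = check_count(n_gene, "n_gene"),
    n_positive = check_count(n_positive, "n_positive"),
    n_negative = check_count(n_negative, "n_negative", min = 0),
    disease_module_size = check_count(disease_module_size, "disease_module_size"),
    immune_set_size = check_count(immune_set_size, "immune_set_size"),
    immune_disease_overlap = check_fraction(immune_disease_overlap, "immune_disease_overlap"),
    base_target_density = check_fraction(base_target_density, "base_target_density"),
    signal_boost = check_fraction(signal_boost, "signal_boost", lo = 1, hi = Inf),
    n_patients = check_count(n_patients, "n_patients", min = 2),
    true_beta = true_beta,
    baseline_hazard = check_fraction(baseline_hazard, "baseline_hazard", lo = 1e-12, hi = Inf),
    censor_fraction = check_fraction(censor_fraction, "censor_fraction"),
    n_cell_types = check_count(n_cell_types, "n_cell_types", min = 2),
    markers_per_type = check_count(markers_per_type, "markers_per_type"),
    n_mixture_samples = check_count(n_mixture_samples, "n_mixture_samples"),
    dirichlet_alpha = dirichlet_alpha,
    mixture_noise_sd = check_fraction(mixture_noise_sd, "mixture_noise_sd", lo = 0, hi = Inf),
    n_gene_sets = check_count(n_gene_sets, "n_gene_sets"),
    planted_set_overlap = check_fraction(planted_set_overlap, "planted_set_overlap"),
    seed = check_count(seed, "seed", min = 0)
  )
  if (cfg$n_positive + cfg$n_negative > cfg$n_mirna) {
    abort("`n_positive` + `n_negative` must not exceed `n_mirna`",
          class = "mirimmune_validation_error")
  }
  if (cfg$disease_module_size > cfg$n_gene) {
    abort("`disease_module_size` must not exceed `n_gene`",
          class = "mirimmune_validation_error")
  }
  if (cfg$immune_set_size > cfg$n_gene) {
    abort("`immune_set_size` must not exceed `n_gene`",
          class = "mirimmune_validation_error")
  }
  if (length(cfg$true_beta) == 0) {
    abort("`true_beta` must name at least one gene",
          class = "mirimmune_validation_error")
  }
  if (is.null(names(cfg$true_beta)) || any(names(cfg$true_beta) == "")) {
    abort("`true_beta` must be a fully named numeric vector",
          class = "mirimmune_validation_error")
  }
  gene_ids <- synth_gene_ids(cfg$n_gene)
  missing <- setdiff(names(cfg$true_beta), gene_ids)
  if (length(missing) > 0) {
    abort(sprintf("`true_beta` names genes outside the universe: %s",
                  paste(missing, collapse = ", ")),
          class = "mirimmune_validation_error")
  }
  if (!length(cfg$dirichlet_alpha) %in% c(1L, cfg$n_cell_types) ||
      any(cfg$dirichlet_alpha <= 0)) {
    abort("`dirichlet_alpha` must be a positive scalar or one value per cell type",
          class = "mirimmune_validation_error")
  }
  structure(cfg, class = "synth_config")
}

synth_gene_ids <- function(n) sprintf("gene%04d", seq_len(n))
synth_mirna_ids <- function(n) sprintf("mir%04d", seq_len(n))

#' Simulate a miRNA-to-target-gene association matrix with planted signal
#'
#' Positive miRNAs target genes of a hidden disease module with probability
#' `min(1, base_target_density * signal_boost)` and every other gene with
#' `base_target_density`; negative and unlabeled miRNAs use the baseline
#' density everywhere.  The immune gene list is drawn to overlap the disease
#' module by `floor(immune_disease_overlap * immune_set_size)` genes.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_associations`:
#'   `matrix` (binary miRNA x gene matrix with dimnames), `positive_ids`,
#'   `negative_ids`, `unlabeled_ids`, `disease_module`, `immune_set`.
#' @examples
#' sim <- generate_associations(synth_config(n_mirna = 40, n_gene = 30,
#'   n_positive = 8, n_negative = 12, disease_module_size = 6,
#'   immune_set_size = 8))
#' dim(sim$matrix)
#' @export
generate_associations <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(substream_seed(cfg$seed, "associations"), {
    mirna_ids <- synth_mirna_ids(cfg$n_mirna)
    gene_ids <- synth_gene_ids(cfg$n_gene)
    labeled <- sample(mirna_ids, cfg$n_positive + cfg$n_negative)
    positive_ids <- sort(labeled[seq_len(cfg$n_positive)])
    negative_ids <- sort(labeled[cfg$n_positive + seq_len(cfg$n_negative)])
    unlabeled_ids <- sort(setdiff(mirna_ids, labeled))
    disease_module <- sort(sample(gene_ids, cfg$disease_module_size))
    n_shared <- floor(cfg$immune_disease_overlap * cfg$immune_set_size)
    n_shared <- min(n_shared, length(disease_module))
    immune_set <- sort(c(
      sample(disease_module, n_shared),
      sample(setdiff(gene_ids, disease_module), cfg$immune_set_size - n_shared)
    ))
    p_base <- cfg$base_target_density
    p_hi <- min(1, p_base * cfg$signal_boost)
    mat <- matrix(rbinom(cfg$n_mirna * cfg$n_gene, 1L, p_base),
                  nrow = cfg$n_mirna, ncol = cfg$n_gene,
                  dimnames = list(mirna_ids, gene_ids))
    if (p_hi > p_base && cfg$n_positive > 0) {
      mat[positive_ids, disease_module] <-
        rbinom(cfg$n_positive * length(disease_module), 1L, p_hi)
    }
    structure(list(matrix = mat, positive_ids = positive_ids,
                   negative_ids = negative_ids, unlabeled_ids = unlabeled_ids,
                   disease_module = disease_module, immune_set = immune_set),
              class = "synth_associations")
  })
}

#' Simulate a survival cohort under a proportional-hazards model
#'
#' Gene expression is i.i.d. standard normal (log-like scale).  Event times
#' are exponential with rate `baseline_hazard * exp(x' beta_true)` -- the
#' simplest law whose hazard is `h0(t) * exp(a1 x1 + ... + an xn)`.
#' Censoring times are uniform on `(0, c_max)` with `c_max` tuned so the
#' realized censored fraction approximates `censor_fraction`.
#'
#' @param cfg A [synth_config()]; `true_beta` must name genes of the
#'   universe.
#' @return A `survival_cohort`: list with `expression` (samples x genes
#'   matrix) and `survival` (tibble: `sample_id`, `time`, `event`), plus
#'   `true_beta`.
#' @examples
#' cohort <- generate_survival(synth_config(n_gene = 20, n_patients = 50,
#'   true_beta = c(gene0001 = 1)))
#' head(cohort$survival)
#' @export
generate_survival <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(substream_seed(cfg$seed, "survival"), {
    gene_ids <- synth_gene_ids(cfg$n_gene)
    sample_ids <- sprintf("patient%04d", seq_len(cfg$n_patients))
    expr <- matrix(rnorm(cfg$n_patients * cfg$n_gene),
                   nrow = cfg$n_patients,
                   dimnames = list(sample_ids, gene_ids))
    lp <- drop(expr[, names(cfg$true_beta), drop = FALSE] %*% cfg$true_beta)
    times <- rexp(cfg$n_patients, rate = cfg$baseline_hazard * exp(lp))
    event <- rep(1L, cfg$n_patients)
    if (cfg$censor_fraction > 0) {
      # expected censored fraction with C ~ U(0, cmax): mean(min(t/cmax, 1)),
      # strictly decreasing in cmax, so the target has a unique root
      f <- function(cmax) mean(pmin(times / cmax, 1)) - cfg$censor_fraction
      cmax <- stats::uniroot(f, c(min(times) * 1e-6, max(times) * 1e6))$root
      cens <- runif(cfg$n_patients, 0, cmax)
      event <- as.integer(times <= cens)
      times <- pmin(times, cens)
    }
    survival_cohort(expression = expr, time = times, event = event,
                    sample_ids = sample_ids, true_beta = cfg$true_beta)
  })
}

#' Simulate bulk expression mixtures from a known cell-type signature
#'
#' Each cell type gets `markers_per_type` exclusive marker genes with
#' elevated reference expression (Uniform(8, 12)) against a Uniform(0.5,
#' 1.5) background.  True proportions are Dirichlet; mixtures are
#' `signature %*% proportions` plus Gaussian noise, floored at zero.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_mixtures`: `signature` (genes x cell
#'   types), `proportions` (samples x cell types, rows on the simplex),
#'   `mixtures` (genes x samples).
#' @examples
#' mix <- generate_mixtures(synth_config(n_cell_types = 4,
#'   markers_per_type = 5, n_mixture_samples = 10))
#' rowSums(mix$proportions)
#' @export
generate_mixtures <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(substream_seed(cfg$seed, "mixtures"), {
    n_sig_genes <- cfg$n_cell_types * cfg$markers_per_type
    if (n_sig_genes > cfg$n_gene) {
      abort("`n_cell_types * markers_per_type` exceeds `n_gene`",
            class = "mirimmune_validation_error")
    }
    gene_ids <- sort(sample(synth_gene_ids(cfg$n_gene), n_sig_genes))
    cell_types <- sprintf("cell_type_%02d", seq_len(cfg$n_cell_types))
    sig <- matrix(runif(n_sig_genes * cfg$n_cell_types, 0.5, 1.5),
                  nrow = n_sig_genes,
                  dimnames = list(gene_ids, cell_types))
    marker_of <- rep(seq_len(cfg$n_cell_types), each = cfg$markers_per_type)
    for (ct in seq_len(cfg$n_cell_types)) {
      sig[marker_of == ct, ct] <- runif(cfg$markers_per_type, 8, 12)
    }
    alpha <- rep(cfg$dirichlet_alpha, length.out = cfg$n_cell_types)
    g <- matrix(rgamma(cfg$n_mixture_samples * cfg$n_cell_types,
                       shape = rep(alpha, each = cfg$n_mixture_samples)),
                nrow = cfg$n_mixture_samples)
    props <- g / rowSums(g)
    dimnames(props) <- list(sprintf("sample%03d", seq_len(cfg$n_mixture_samples)),
                            cell_types)
    mixtures <- sig %*% t(props)
    if (cfg$mixture_noise_sd > 0) {
      mixtures <- mixtures + rnorm(length(mixtures), sd = cfg$mixture_noise_sd)
      mixtures[mixtures < 0] <- 0
    }
    structure(list(signature = sig, proportions = props, mixtures = mixtures),
              class = "synth_mixtures")
  })
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' One set (the planted one) shares `floor(planted_set_overlap * size)`
#' genes with the disease module; the remaining sets are uniform random
#' samples of the gene universe.
#'
#' @param cfg A [synth_config()].
#' @param disease_module Character vector of module genes (as from
#'   [generate_associations()]).
#' @return A list of class `gene_set_collection`: `sets` (named list of
#'   character vectors), `universe`, and `planted_set` (the planted set's
#'   name).
#' @examples
#' cfg <- synth_config(n_gene = 100, disease_module_size = 10,
#'                     n_gene_sets = 5)
#' sim <- generate_associations(cfg)
#' gs <- generate_gene_sets(cfg, sim$disease_module)
#' names(gs$sets)[1:3]
#' @export
generate_gene_sets <- function(cfg, disease_module) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(substream_seed(cfg$seed, "gene_sets"), {
    universe <- synth_gene_ids(cfg$n_gene)
    stopifnot(all(disease_module %in% universe))
    set_names <- sprintf("set%03d", seq_len(cfg$n_gene_sets))
    size_lo <- min(20L, cfg$n_gene)
    size_hi <- min(150L, cfg$n_gene)
    sizes <- sample(seq(size_lo, size_hi), cfg$n_gene_sets, replace = TRUE)
    planted_size <- min(length(disease_module), cfg$n_gene)
    n_shared <- floor(cfg$planted_set_overlap * planted_size)
    planted <- sort(c(
      sample(disease_module, n_shared),
      sample(setdiff(universe, disease_module), planted_size - n_shared)
    ))
    sets <- lapply(sizes[-1], function(s) sort(sample(universe, s)))
    sets <- c(list(planted), sets)
    names(sets) <- set_names
    structure(list(sets = sets, universe = universe,
                   planted_set = set_names[1]),
              class = "gene_set_collection")
  })
}

#' Generate the full synthetic benchmark in one call
#'
#' @param cfg A [synth_config()].
#' @return A list with `associations`, `cohort`, `mixtures`, `gene_sets`
#'   (the outputs of the four generators, all driven by named sub-streams
#'   of `cfg$seed`) and the `config` itself.
#' @export
synth_all <- function(cfg) {
  assoc <- generate_associations(cfg)
  list(associations = assoc,
       cohort = generate_survival(cfg),
       mixtures = generate_mixtures(cfg),
       gene_sets = generate_gene_sets(cfg, assoc$disease_module),
       config = cfg)
}
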