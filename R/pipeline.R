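#' Pipeline configuration
#'
#' One object holding every stage parameter of the end-to-end synthetic
#' workflow: simulate -> train -> evaluate -> predict -> map_immune ->
#' survival -> deconvolve -> enrich.  Unknown arguments are rejected.
#'
#' @param output_dir Directory receiving all stage outputs.
#' @param seed Global integer seed driving every stage sub-stream.
#' @param synth List of overrides for [synth_config()] (its `seed` is set
#'   from `seed`).
#' @param train List of overrides for [train_config()] (idem).
#' @param cv_folds Folds for the evaluation stage.
#' @param cv_models Models compared in the evaluation stage.
#' @param candidate_threshold,candidate_top_n Candidate-selection rule for
#'   the predict stage (exactly one may be non-NULL).
#' @param survival_nfolds Folds for the penalty cross-validation.
#' @param nu_grid,svr_cost Deconvolution hyperparameters.
#' @param enrich_top_k Records kept by the enrichment stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed = 1, synth = list(),
                            train = list(), cv_folds = 10,
                            cv_models = "ccnet",
                            candidate_threshold = 0.5,
                            candidate_top_n = NULL,
                            survival_nfolds = 10,
                            nu_grid = c(0.25, 0.5, 0.75), svr_cost = 100,
                            enrich_top_k = 25) {
  stopifnot(is.list(synth), is.list(train))
  bad <- setdiff(names(synth), names(formals(synth_config)))
  if (length(bad) > 0) {
    abort(sprintf("unknown synth key(s): %s", paste(bad, collapse = ", ")),
          class = "mirimmune_validation_error")
  }
  bad <- setdiff(names(train), names(formals(train_config)))
  if (length(bad) > 0) {
    abort(sprintf("unknown train key(s): %s", paste(bad, collapse = ", ")),
          class = "mirimmune_validation_error")
  }
  synth$seed <- seed
  train$seed <- seed
  structure(list(
    output_dir = output_dir,
    seed = check_count(seed, "seed", min = 0),
    synth = do.call(synth_config, synth),
    train = do.call(train_config, train),
    cv_folds = check_count(cv_folds, "cv_folds", min = 2),
    cv_models = cv_models,
    candidate_threshold = candidate_threshold,
    candidate_top_n = candidate_top_n,
    survival_nfolds = check_count(survival_nfolds, "survival_nfolds", min = 2),
    nu_grid = nu_grid,
    svr_cost = svr_cost,
    enrich_top_k = enrich_top_k
  ), class = "pipeline_config")
}

pipeline_stages <- function() {
  c("simulate", "train", "evaluate", "predict", "map_immune", "survival",
    "deconvolve", "enrich")
}

stage_path <- function(cfg, file) file.path(cfg$output_dir, file)

require_upstream <- function(cfg, files, producer) {
  missing <- files[!file.exists(stage_path(cfg, files))]
  if (length(missing) > 0) {
    abort(sprintf("missing upstream artifact(s) %s; run stage '%s' first",
                  paste(missing, collapse = ", "), producer),
          class = "mirimmune_pipeline_error")
  }
}

config_hash <- function(cfg) {
  plain <- rapply(unclass(cfg), function(x) x, how = "replace")
  plain$output_dir <- NULL  # outputs must be relocatable byte-for-byte
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

update_manifest <- function(cfg, stage, files) {
  path <- stage_path(cfg, "run_manifest.json")
  manifest <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    list(config_hash = config_hash(cfg), seed = cfg$seed,
         package_version = as.character(utils::packageVersion("mirimmune")),
         stages = list())
  }
  sums <- tools::md5sum(stage_path(cfg, files))
  manifest$stages[[stage]] <- list(outputs = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Run `writer(dir)` against a scratch directory, then move every produced
# file into the output directory only if the whole stage succeeded.
atomic_stage <- function(cfg, stage, writer) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile("stage_", tmpdir = cfg$output_dir)
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE, force = TRUE))
  writer(tmp)
  files <- list.files(tmp)
  for (f in files) {
    file.copy(file.path(tmp, f), stage_path(cfg, f), overwrite = TRUE)
  }
  update_manifest(cfg, stage, files)
  invisible(files)
}

#' Run one pipeline stage
#'
#' Each stage reads its inputs from the files earlier stages wrote under
#' `cfg$output_dir` and writes its own outputs atomically (nothing is left
#' behind on error); `run_manifest.json` records the configuration hash,
#' seed, package version and an md5 checksum of every output, so reruns
#' with an identical configuration and seed are byte-identical.
#'
#' @param name One of `simulate`, `train`, `evaluate`, `predict`,
#'   `map_immune`, `survival`, `deconvolve`, `enrich`.
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the files the stage wrote.
#' @export
run_stage <- function(name, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  name <- match.arg(name, pipeline_stages())
  switch(name,
    simulate = stage_simulate(cfg),
    train = stage_train(cfg),
    evaluate = stage_evaluate(cfg),
    predict = stage_predict(cfg),
    map_immune = stage_map_immune(cfg),
    survival = stage_survival(cfg),
    deconvolve = stage_deconvolve(cfg),
    enrich = stage_enrich(cfg))
}

#' Run the full pipeline
#'
#' @param cfg A [pipeline_config()].
#' @param stages Stages to run, in order (default all).
#' @return Invisibly, `cfg$output_dir`.
#' @export
run_pipeline <- function(cfg, stages = pipeline_stages()) {
  for (s in stages) run_stage(s, cfg)
  invisible(cfg$output_dir)
}

stage_simulate <- function(cfg) {
  sim <- synth_all(cfg$synth)
  atomic_stage(cfg, "simulate", function(dir) {
    assoc <- sim$associations
    idx <- which(assoc$matrix == 1L, arr.ind = TRUE)
    pairs <- tibble::tibble(
      mirna_id = rownames(assoc$matrix)[idx[, 1]],
      gene_id = colnames(assoc$matrix)[idx[, 2]])
    pairs <- dplyr::arrange(pairs, mirna_id, gene_id)
    write_pairs(pairs, file.path(dir, "association_pairs.tsv"))
    write_matrix_tsv(assoc$matrix, file.path(dir, "association_matrix.tsv"),
                     id_column = "mirna_id")
    write_id_list(assoc$positive_ids, file.path(dir, "positives.txt"))
    write_id_list(assoc$negative_ids, file.path(dir, "negatives.txt"))
    write_id_list(assoc$unlabeled_ids, file.path(dir, "unlabeled.txt"))
    write_id_list(assoc$immune_set, file.path(dir, "immune_genes.txt"))
    # expression written genes x samples, the usual omics orientation
    write_matrix_tsv(t(sim$cohort$expression),
                     file.path(dir, "expression.tsv"), id_column = "gene_id")
    write_survival(sim$cohort$survival, file.path(dir, "survival.tsv"))
    write_matrix_tsv(sim$mixtures$signature, file.path(dir, "signature.tsv"),
                     id_column = "gene_id")
    write_matrix_tsv(sim$mixtures$mixtures, file.path(dir, "mixtures.tsv"),
                     id_column = "gene_id")
    write_gmt(sim$gene_sets$sets, file.path(dir, "gene_sets.gmt"))
    truth <- list(disease_module = sim$associations$disease_module,
                  immune_set = sim$associations$immune_set,
                  true_beta = as.list(cfg$synth$true_beta),
                  planted_set = sim$gene_sets$planted_set,
                  true_proportions = as.data.frame(sim$mixtures$proportions))
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  })
}

read_labeled_features <- function(cfg, producer = "simulate") {
  require_upstream(cfg, c("association_matrix.tsv", "positives.txt",
                          "negatives.txt"), producer)
  m <- read_matrix_tsv(stage_path(cfg, "association_matrix.tsv"))
  pos <- read_id_list(stage_path(cfg, "positives.txt"))
  neg <- read_id_list(stage_path(cfg, "negatives.txt"))
  list(X = m[c(pos, neg), , drop = FALSE],
       y = rep(c(1L, 0L), c(length(pos), length(neg))), matrix = m)
}

stage_train <- function(cfg) {
  dat <- read_labeled_features(cfg)
  fit <- ccnet_train(dat$X, dat$y, cfg$train)
  atomic_stage(cfg, "train", function(dir) {
    save_ccnet(fit$params, file.path(dir, "ccnet_model.json"))
    readr::write_tsv(fit$history, file.path(dir, "training_history.tsv"),
                     progress = FALSE)
  })
}

stage_evaluate <- function(cfg) {
  dat <- read_labeled_features(cfg)
  folds <- make_folds(dat$y, k = cfg$cv_folds, seed = cfg$seed)
  results <- lapply(cfg$cv_models, function(m) {
    cross_validate(m, dat$X, dat$y, folds, train_cfg = cfg$train)
  })
  names(results) <- cfg$cv_models
  atomic_stage(cfg, "evaluate", function(dir) {
    metrics <- lapply(results, function(r) {
      list(per_fold = r$per_fold, mean_auc = r$mean_auc,
           mean_aupr = r$mean_aupr)
    })
    jsonlite::write_json(metrics, file.path(dir, "cv_metrics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    first <- results[[1]]
    readr::write_tsv(first$mean_roc, file.path(dir, "mean_roc.tsv"),
                     progress = FALSE)
    readr::write_tsv(first$mean_pr, file.path(dir, "mean_pr.tsv"),
                     progress = FALSE)
  })
}

stage_predict <- function(cfg) {
  require_upstream(cfg, c("ccnet_model.json"), "train")
  require_upstream(cfg, c("association_matrix.tsv", "unlabeled.txt"),
                   "simulate")
  params <- load_ccnet(stage_path(cfg, "ccnet_model.json"))
  m <- read_matrix_tsv(stage_path(cfg, "association_matrix.tsv"))
  unlabeled <- read_id_list(stage_path(cfg, "unlabeled.txt"))
  scores <- predict_scores(params, m[unlabeled, , drop = FALSE])
  cands <- if (!is.null(cfg$candidate_top_n)) {
    rank_candidates(scores, unlabeled, top_n = cfg$candidate_top_n)
  } else {
    rank_candidates(scores, unlabeled, threshold = cfg$candidate_threshold)
  }
  atomic_stage(cfg, "predict", function(dir) {
    readr::write_tsv(tibble::tibble(mirna_id = unlabeled, score = scores),
                     file.path(dir, "scores.tsv"), progress = FALSE)
    readr::write_tsv(cands, file.path(dir, "candidates.tsv"),
                     progress = FALSE)
  })
}

stage_map_immune <- function(cfg) {
  require_upstream(cfg, c("association_pairs.tsv", "immune_genes.txt"),
                   "simulate")
  require_upstream(cfg, "candidates.tsv", "predict")
  pairs <- read_pairs(stage_path(cfg, "association_pairs.tsv"))
  immune <- read_id_list(stage_path(cfg, "immune_genes.txt"))
  cands <- readr::read_tsv(stage_path(cfg, "candidates.tsv"),
                           col_types = "cdd", progress = FALSE)
  map <- build_target_map(pairs)
  summ <- summarize_immune(map, cands$mirna_id, immune)
  atomic_stage(cfg, "map_immune", function(dir) {
    jsonlite::write_json(summ$summary, file.path(dir, "immune_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    per <- summ$per_mirna[summ$per_mirna$n_immune_targets > 0, ]
    write_gmt(stats::setNames(per$immune_targets, per$mirna_id),
              file.path(dir, "immune_targets.gmt"))
    write_id_list(sort(unique(unlist(per$immune_targets))),
                  file.path(dir, "immune_target_union.txt"))
  })
}

stage_survival <- function(cfg) {
  require_upstream(cfg, c("expression.tsv", "survival.tsv"), "simulate")
  require_upstream(cfg, "immune_target_union.txt", "map_immune")
  expr <- t(read_matrix_tsv(stage_path(cfg, "expression.tsv")))
  sv <- read_survival(stage_path(cfg, "survival.tsv"))
  genes <- intersect(read_id_list(stage_path(cfg, "immune_target_union.txt")),
                     colnames(expr))
  if (length(genes) < 2L) {
    warn("fewer than 2 immune target genes in the expression matrix; using all genes")
    genes <- colnames(expr)
  }
  cohort <- survival_cohort(expr[sv$sample_id, genes, drop = FALSE],
                            sv$time, sv$event, sv$sample_id)
  fit <- fit_lasso_cox(cohort, nfolds = cfg$survival_nfolds, seed = cfg$seed)
  sel <- fit$selected_genes
  tests <- if (length(sel) > 0) survival_by_median(cohort, genes = sel)
  rs <- risk_score(fit, cohort)
  risk_test <- if (length(sel) > 0 && length(unique(rs)) > 1) {
    survival_by_median(cohort, values = rs)
  }
  atomic_stage(cfg, "survival", function(dir) {
    model <- list(selected_genes = sel,
                  coefficients = as.list(fit$coefficients[sel]),
                  lambda = fit$lambda, lambda_min = fit$lambda_min,
                  lambda_1se = fit$lambda_1se, cv_path = fit$cv)
    jsonlite::write_json(model, file.path(dir, "cox_model.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    res <- list()
    curves <- list()
    for (tst in list(tests, risk_test)) {
      if (is.null(tst)) next
      for (i in seq_len(nrow(tst))) {
        res[[tst$gene[i]]] <- list(statistic = tst$statistic[i],
                                   p_value = tst$p_value[i])
        for (side in c("km_low", "km_high")) {
          cv <- tst[[side]][[i]]
          cv$group <- paste(tst$gene[i], sub("km_", "", side), sep = "_")
          curves[[length(curves) + 1L]] <- cv
        }
      }
    }
    jsonlite::write_json(res, file.path(dir, "survival_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    if (length(curves) > 0) {
      readr::write_tsv(dplyr::bind_rows(curves),
                       file.path(dir, "km_curves.tsv"), progress = FALSE)
    }
  })
}

stage_deconvolve <- function(cfg) {
  require_upstream(cfg, c("signature.tsv", "mixtures.tsv"), "simulate")
  sig <- read_matrix_tsv(stage_path(cfg, "signature.tsv"))
  mix <- read_matrix_tsv(stage_path(cfg, "mixtures.tsv"))
  props <- deconvolve_cohort(sig, mix, nu_grid = cfg$nu_grid,
                             cost = cfg$svr_cost)
  summ <- abundance_summary(props)
  atomic_stage(cfg, "deconvolve", function(dir) {
    readr::write_tsv(props, file.path(dir, "proportions.tsv"),
                     progress = FALSE)
    jsonlite::write_json(summ, file.path(dir, "abundance_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  })
}

stage_enrich <- function(cfg) {
  require_upstream(cfg, c("gene_sets.gmt", "association_matrix.tsv"),
                   "simulate")
  require_upstream(cfg, "immune_target_union.txt", "map_immune")
  sets <- read_gmt(stage_path(cfg, "gene_sets.gmt"))
  universe <- colnames(read_matrix_tsv(stage_path(cfg, "association_matrix.tsv")))
  query <- read_id_list(stage_path(cfg, "immune_target_union.txt"))
  coll <- gene_set_collection(sets, universe)
  recs <- enrich_query(query, coll, top_k = cfg$enrich_top_k)
  atomic_stage(cfg, "enrich", function(dir) {
    out <- recs
    out$overlap_genes <- vapply(out$overlap_genes, paste, character(1),
                                collapse = ",")
    readr::write_tsv(out, file.path(dir, "enrichment.tsv"), progress = FALSE)
  })
}
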