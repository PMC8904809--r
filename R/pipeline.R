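# End-to-end orchestration: fold construction -> negative sampling ->
# (optional) imputer training and feature substitution -> residual-model
# training -> evaluation, for every fold of the drug-based (or
# pair-based) cross-validation.

#' Cross-validation run configuration
#'
#' @param mode feature scenario for unseen drugs:
#'   `"available"` uses the true heterogeneous rows for test drugs;
#'   `"predicted"` substitutes imputed DDI/DSIE/DDIS rows for test drugs
#'   and imputed PDIS rows for all proteins;
#'   `"available_pdis"` is `"predicted"` but keeps the true PDIS rows.
#' @param ratio negatives per positive (1, 3 or 5 in the standard
#'   protocol).
#' @param k number of folds.
#' @param val_fraction validation share of all pairs (default 0.05; with
#'   balanced folds this yields the 85/5/10 train/validation/test split).
#' @param feature_config a [feature_config()]; `NULL` selects all blocks.
#' @param model_config a [dti_config()] for the classifier.
#' @param imputer_cfg an [imputer_train_config()] for the imputers.
#' @param imputer_hidden optional named list of 3-vectors overriding the
#'   imputer hidden dimensions per target (useful at small scale).
#' @param imputer_ensemble number of imputers trained (and averaged) per
#'   block; small ensembles stabilize the imputed rankings.
#' @param imputer_dropout dropout rate for the imputers (`NULL` keeps the
#'   architecture default of 0.5, suited to the wide full-scale nets; at
#'   small scale weight decay in `imputer_cfg` is the better regularizer
#'   and dropout can be set to 0).
#' @param zero_positive_count negatives drawn for drugs with no
#'   positives (default 3).
#' @param leakage_safe if TRUE, DDI columns that reference the current
#'   test drugs are zeroed in every drug's feature row during that fold.
#' @param seed master seed; all per-fold seeds derive from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("available", "predicted", "available_pdis"),
                       ratio = 1L, k = 10L, val_fraction = 0.05,
                       feature_config = NULL,
                       model_config = dti_config(),
                       imputer_cfg = imputer_train_config(),
                       imputer_hidden = NULL,
                       imputer_ensemble = 1L,
                       imputer_dropout = NULL,
                       zero_positive_count = 3L,
                       leakage_safe = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(ratio >= 1, k >= 2)
  if (is.null(feature_config)) feature_config <- feature_config()
  structure(list(mode = mode, ratio = as.integer(ratio), k = as.integer(k),
                 val_fraction = val_fraction, feature_config = feature_config,
                 model_config = model_config, imputer_cfg = imputer_cfg,
                 imputer_hidden = imputer_hidden,
                 imputer_ensemble = as.integer(imputer_ensemble),
                 imputer_dropout = imputer_dropout,
                 zero_positive_count = as.integer(zero_positive_count),
                 leakage_safe = isTRUE(leakage_safe), seed = as.integer(seed)),
            class = "run_config")
}

# Positive counts per drug over the full registry (zeros included).
.drug_positive_counts <- function(bundle) {
  tab <- table(bundle$dti$drug_id)
  counts <- stats::setNames(integer(length(bundle$drugs$ids)), bundle$drugs$ids)
  counts[names(tab)] <- as.integer(tab)
  counts
}

# Build labelled pairs (positives + per-drug sampled negatives).
.build_all_pairs <- function(bundle, cfg) {
  negatives <- sample_negatives(bundle$dti, bundle$proteins, cfg$ratio,
                                cfg$zero_positive_count, seed = cfg$seed,
                                drugs = bundle$drugs$ids)
  pair_set(c(bundle$dti$drug_id, negatives$drug_id),
           c(bundle$dti$protein_id, negatives$protein_id),
           c(rep(1L, nrow(bundle$dti)), rep(0L, nrow(negatives))))
}

.imputer_hidden_for <- function(cfg, target) {
  if (!is.null(cfg$imputer_hidden) && target %in% names(cfg$imputer_hidden)) {
    cfg$imputer_hidden[[target]]
  } else NULL
}

# Train the drug-side imputers on the non-test drugs and return imputed
# rows (real-valued, in [0,1]) for the test drugs, per block.
.impute_drug_blocks <- function(bundle, cfg, blocks, train_drugs, test_drugs,
                                fold_seed) {
  overrides <- list()
  emb <- bundle$drug_embeddings
  for (blk in blocks) {
    icfg <- cfg$imputer_cfg
    icfg$seed <- fold_seed + match(blk, c("DDI", "DSIE", "DDIS"))
    model <- fit_imputer(blk, emb, bundle$matrices[[blk]], train_drugs,
                         cfg = icfg, n_models = cfg$imputer_ensemble,
                         hidden_dims = .imputer_hidden_for(cfg, blk),
                         dropout_rate = if (is.null(cfg$imputer_dropout)) 0.5
                                        else cfg$imputer_dropout)
    E <- emb$values[registry_pos(emb$registry, test_drugs), , drop = FALSE]
    overrides[[blk]] <- impute(model, E)
  }
  overrides
}

# Train the protein-disease imputer on all proteins and return imputed
# rows for every protein (proteins are all "seen" in drug-based folds;
# this reproduces the scenario where protein-disease links are unknown).
.impute_pdis_block <- function(bundle, cfg, fold_seed) {
  emb <- bundle$protein_embeddings
  icfg <- cfg$imputer_cfg
  icfg$seed <- fold_seed + 7L
  model <- fit_imputer("PDIS", emb, bundle$matrices$PDIS, bundle$proteins$ids,
                       cfg = icfg, n_models = cfg$imputer_ensemble,
                       hidden_dims = .imputer_hidden_for(cfg, "PDIS"),
                       dropout_rate = if (is.null(cfg$imputer_dropout)) 0.5
                                      else cfg$imputer_dropout)
  impute(model, emb$values)
}

#' Run drug-based cross-validation
#'
#' For every fold: builds the 85/5/10 split with test drugs held out
#' entirely; in the predicted-feature modes trains the imputers on the
#' non-test drugs and substitutes imputed rows for test drugs (and
#' imputed PDIS rows in `"predicted"` mode); trains the residual
#' classifier with early stopping; and scores the test pairs. The whole
#' run is reproducible from (config, bundle).
#'
#' @param bundle a [dataset_bundle()].
#' @param cfg a [run_config()].
#' @param folds optional subset of folds to run (default all `1:k`).
#' @return A list of class `cv_run`: `report` ([eval_report()]),
#'   `records` (pooled [prediction_records()]), `plan`, `all_pairs`,
#'   `cfg`.
#' @export
run_crossval <- function(bundle, cfg = run_config(), folds = NULL) {
  counts <- .drug_positive_counts(bundle)
  plan <- assign_drug_folds(counts, cfg$k)
  all_pairs <- .build_all_pairs(bundle, cfg)
  fc <- cfg$feature_config
  P_true <- assemble_protein_features(bundle, fc)
  D_true <- assemble_drug_features(bundle, fc)
  pdis_active <- "PDIS" %in% fc$protein_blocks
  drug_hetero <- intersect(fc$drug_blocks, c("DDI", "DSIE", "DDIS"))
  if (is.null(folds)) folds <- seq_len(cfg$k)
  records <- list()
  for (f in folds) {
    fold_seed <- cfg$seed + 100L * f
    splits <- make_splits(plan, all_pairs, f, cfg$val_fraction, seed = fold_seed)
    test_drugs <- unique(splits$test$drug_id)
    train_drugs <- setdiff(bundle$drugs$ids, test_drugs)
    D <- D_true
    P <- P_true
    if (cfg$mode %in% c("predicted", "available_pdis")) {
      if (length(drug_hetero) && length(test_drugs)) {
        ov <- .impute_drug_blocks(bundle, cfg, drug_hetero, train_drugs,
                                  test_drugs, fold_seed)
        D <- assemble_drug_features(bundle, fc, block_overrides = ov)
      }
      if (cfg$mode == "predicted" && pdis_active) {
        pd <- .impute_pdis_block(bundle, cfg, fold_seed)
        P <- assemble_protein_features(bundle, fc,
                                       block_overrides = list(PDIS = pd))
      }
    }
    if (cfg$leakage_safe && "DDI" %in% fc$drug_blocks && length(test_drugs)) {
      off <- attr(D, "blocks")$DDI
      cols <- off[1] + registry_pos(bundle$drugs, test_drugs)
      blocks_attr <- attr(D, "blocks")
      D[, cols] <- 0
      attr(D, "blocks") <- blocks_attr
    }
    mcfg <- cfg$model_config
    mcfg$seed <- fold_seed
    model <- build_dti_model(ncol(D) + ncol(P), mcfg)
    model <- train_dti(model,
                       assemble_pair_input(D, P, splits$train), splits$train$label,
                       assemble_pair_input(D, P, splits$val), splits$val$label)
    prob <- predict_dti(model, assemble_pair_input(D, P, splits$test))
    records[[f]] <- prediction_records(splits$test$drug_id, splits$test$protein_id,
                                       prob, splits$test$label, fold = f)
  }
  records <- do.call(rbind, records)
  class(records) <- c("prediction_records", "data.frame")
  structure(list(report = eval_report(records), records = records,
                 plan = plan, all_pairs = all_pairs, cfg = cfg),
            class = "cv_run")
}

#' @export
print.cv_run <- function(x, ...) {
  cat(sprintf("<cv_run> mode=%s ratio=1:%d k=%d\n", x$cfg$mode, x$cfg$ratio,
              x$cfg$k))
  print(x$report)
  invisible(x)
}

#' Run pair-based random cross-validation
#'
#' The permissive protocol: all positives plus `ratio` times as many
#' negatives sampled uniformly over the whole drug-protein grid are
#' partitioned into k random folds by pair (not by drug), so drugs recur
#' across training and test sets. Features are always the true
#' (available) ones.
#'
#' @inheritParams run_crossval
#' @return A `cv_run` list, as in [run_crossval()].
#' @export
run_pair_crossval <- function(bundle, cfg = run_config(), folds = NULL) {
  negatives <- sample_negatives_global(bundle$dti, bundle$drugs, bundle$proteins,
                                       cfg$ratio * nrow(bundle$dti),
                                       seed = cfg$seed)
  all_pairs <- pair_set(c(bundle$dti$drug_id, negatives$drug_id),
                        c(bundle$dti$protein_id, negatives$protein_id),
                        c(rep(1L, nrow(bundle$dti)), rep(0L, nrow(negatives))))
  pf <- make_pair_folds(all_pairs, cfg$k, seed = cfg$seed)
  fc <- cfg$feature_config
  D <- assemble_drug_features(bundle, fc)
  P <- assemble_protein_features(bundle, fc)
  if (is.null(folds)) folds <- seq_len(cfg$k)
  records <- list()
  for (f in folds) {
    fold_seed <- cfg$seed + 100L * f
    splits <- make_pair_splits(pf, all_pairs, f, cfg$val_fraction, seed = fold_seed)
    mcfg <- cfg$model_config
    mcfg$seed <- fold_seed
    model <- build_dti_model(ncol(D) + ncol(P), mcfg)
    model <- train_dti(model,
                       assemble_pair_input(D, P, splits$train), splits$train$label,
                       assemble_pair_input(D, P, splits$val), splits$val$label)
    prob <- predict_dti(model, assemble_pair_input(D, P, splits$test))
    records[[f]] <- prediction_records(splits$test$drug_id, splits$test$protein_id,
                                       prob, splits$test$label, fold = f)
  }
  records <- do.call(rbind, records)
  class(records) <- c("prediction_records", "data.frame")
  structure(list(report = eval_report(records), records = records,
                 plan = NULL, all_pairs = all_pairs, cfg = cfg),
            class = "cv_run")
}

#' Run an ablation variant
#'
#' Re-runs [run_crossval()] with the given heterogeneous blocks removed
#' from the feature configuration. Embedding blocks cannot be dropped;
#' dropping every heterogeneous block yields the embeddings-only
#' baseline.
#'
#' @param bundle a [dataset_bundle()].
#' @param cfg a [run_config()].
#' @param drop character vector of blocks to drop (subset of DDI, DSIE,
#'   DDIS, PPI, PSIM, PDIS).
#' @param folds optional subset of folds to run.
#' @return A `cv_run` list tagged with the dropped blocks.
#' @export
run_ablation <- function(bundle, cfg = run_config(), drop = character(0),
                         folds = NULL) {
  if (any(drop %in% c("Drug", "Protein"))) {
    stop("embedding blocks cannot be dropped")
  }
  bad <- setdiff(drop, c("DDI", "DSIE", "DDIS", "PPI", "PSIM", "PDIS"))
  if (length(bad)) stop("unknown block(s): ", paste(bad, collapse = ", "))
  fc <- cfg$feature_config
  cfg$feature_config <- feature_config(
    drug_blocks = setdiff(fc$drug_blocks, drop),
    protein_blocks = setdiff(fc$protein_blocks, drop))
  run <- run_crossval(bundle, cfg, folds = folds)
  run$dropped <- drop
  run
}
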