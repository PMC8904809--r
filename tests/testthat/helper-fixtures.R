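# Shared fixtures: tiny registries/bundles built in code, and the small
# training configurations used across tests.

tiny_registry <- function(n, kind = "drug", prefix = toupper(substr(kind, 1, 1))) {
  entity_registry(sprintf("%s%03d", prefix, seq_len(n)), kind)
}

# A fully consistent hand-sized bundle (no planted signal; structural tests).
tiny_bundle <- function(n_drugs = 6, n_proteins = 8, n_se = 4, n_dis = 5, seed = 7) {
  withr_seed <- function(code) hetdti:::.local_seed(seed, code)
  drugs <- tiny_registry(n_drugs, "drug", "D")
  proteins <- tiny_registry(n_proteins, "protein", "P")
  side_effects <- tiny_registry(n_se, "side_effect", "S")
  diseases <- tiny_registry(n_dis, "disease", "Z")
  withr_seed({
    sym <- function(n, p) {
      m <- matrix(rbinom(n * n, 1, p), n, n)
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      diag(m) <- 0
      m
    }
    rect <- function(n, m, p) matrix(rbinom(n * m, 1, p), n, m)
    psim <- matrix(runif(n_proteins^2), n_proteins, n_proteins)
    psim <- (psim + t(psim)) / 2
    matrices <- list(
      DDI = hetero_matrix("DDI", drugs, drugs, sym(n_drugs, 0.3)),
      DSIE = hetero_matrix("DSIE", drugs, side_effects, rect(n_drugs, n_se, 0.3)),
      DDIS = hetero_matrix("DDIS", drugs, diseases, rect(n_drugs, n_dis, 0.3)),
      PPI = hetero_matrix("PPI", proteins, proteins, sym(n_proteins, 0.3)),
      PSIM = hetero_matrix("PSIM", proteins, proteins, psim),
      PDIS = hetero_matrix("PDIS", proteins, diseases, rect(n_proteins, n_dis, 0.3)))
    de <- embedding_table(drugs, matrix(rnorm(n_drugs * 5), n_drugs, 5))
    pe <- embedding_table(proteins, matrix(rnorm(n_proteins * 3), n_proteins, 3))
    # a couple of positives per drug
    dti <- pair_set(rep(drugs$ids, each = 2),
                    proteins$ids[(seq_len(2 * n_drugs) %% n_proteins) + 1])
    dataset_bundle(drugs, proteins, side_effects, diseases, matrices, de, pe, dti)
  })
}

# Desk-scale training configs shared by pipeline-level tests: small
# residual widths and short epoch budgets sized to the desk preset.
desk_model_config <- function(seed = 1L, ...) {
  dti_config(m1 = 128L, m2 = 64L, classifier_width = 64L,
             learning_rate = 1e-3, max_epochs = 60L, patience = 8L,
             seed = seed, ...)
}

desk_baseline_config <- function(seed = 1L) {
  dti_config(use_residual = FALSE, n_classifier_hidden = 2L,
             classifier_width = 64L, learning_rate = 1e-3,
             max_epochs = 60L, patience = 8L, seed = seed)
}

desk_imputer_config <- function(seed = 1L) {
  imputer_train_config(learning_rate = 1e-2, max_epochs = 400L,
                       patience = 60L, weight_decay = 1e-3, seed = seed)
}

desk_imputer_hidden <- function() {
  list(DDI = c(64L, 32L, 16L), DSIE = c(64L, 32L, 16L),
       DDIS = c(64L, 32L, 16L), PDIS = c(64L, 32L, 16L))
}

# Brute-force ROC AUC by concordant-pair counting (independent oracle).
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
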