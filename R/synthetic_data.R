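# Synthetic dataset generator with planted latent structure. Every
# entity carries a latent factor vector; association matrices are
# Bernoulli draws on logistic link scores between latents, DTI labels
# are driven by the drug-protein latent inner product, and embeddings
# are noisy linear transforms of the latents. Because one latent set
# drives both the association matrices and the DTI labels, (a) the
# imputers can genuinely predict association rows from embeddings and
# (b) heterogeneous blocks carry signal beyond the (noisy) embeddings —
# the structure the full pipeline is meant to exploit.

#' Synthetic dataset configuration
#'
#' @param n_drugs,n_proteins,n_side_effects,n_diseases entity counts
#'   (all at least 2).
#' @param latent_dim dimension of the planted latent factors.
#' @param drug_embedding_dim,protein_embedding_dim embedding widths.
#' @param densities named numeric vector of target densities for the
#'   binary association matrices (names DDI, DSIE, DDIS, PPI, PDIS).
#' @param dti_rate target positive rate over the drug x protein grid.
#' @param embedding_noise_sd standard deviation of the Gaussian noise
#'   added to the latent-derived embeddings; larger values make the
#'   heterogeneous blocks more informative relative to the embeddings.
#' @param assoc_scale slope of the logistic link for association
#'   matrices.
#' @param dti_scale slope of the logistic link for DTI labels; 0 plants
#'   no signal (null-control datasets).
#' @param dti_promiscuity_sd standard deviation of a per-drug random
#'   intercept added to the DTI logits: idiosyncratic drug promiscuity
#'   that is not reflected in embeddings or association matrices. It is
#'   invisible to any cold-start model but memorizable when the same
#'   drug appears in training and test (pair-based cross-validation).
#'   Set to 0 alongside `dti_scale = 0` for a fully null dataset.
#' @param seed RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 120L, n_proteins = 200L,
                         n_side_effects = 60L, n_diseases = 80L,
                         latent_dim = 8L,
                         drug_embedding_dim = 32L, protein_embedding_dim = 16L,
                         densities = c(DDI = 0.05, DSIE = 0.10, DDIS = 0.10,
                                       PPI = 0.05, PDIS = 0.10),
                         dti_rate = 0.04, embedding_noise_sd = 1.0,
                         assoc_scale = 5, dti_scale = 4,
                         dti_promiscuity_sd = 1.5, seed = 1L) {
  need <- c("DDI", "DSIE", "DDIS", "PPI", "PDIS")
  if (!all(need %in% names(densities))) {
    stop("densities must name ", paste(need, collapse = ", "))
  }
  if (any(densities <= 0 | densities >= 1) || dti_rate <= 0 || dti_rate >= 1) {
    stop("densities and dti_rate must lie in (0, 1)")
  }
  counts <- c(n_drugs, n_proteins, n_side_effects, n_diseases)
  if (any(counts < 2)) stop("all entity counts must be at least 2")
  structure(list(n_drugs = as.integer(n_drugs), n_proteins = as.integer(n_proteins),
                 n_side_effects = as.integer(n_side_effects),
                 n_diseases = as.integer(n_diseases),
                 latent_dim = as.integer(latent_dim),
                 drug_embedding_dim = as.integer(drug_embedding_dim),
                 protein_embedding_dim = as.integer(protein_embedding_dim),
                 densities = densities[need], dti_rate = dti_rate,
                 embedding_noise_sd = embedding_noise_sd,
                 assoc_scale = assoc_scale, dti_scale = dti_scale,
                 dti_promiscuity_sd = dti_promiscuity_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Scale presets
#'
#' `"paper"` mirrors the benchmark dataset dimensions (707 drugs, 1489
#' proteins, 4192 side effects, 5603 diseases, 300/100-dim embeddings);
#' `"desk"` is a small configuration (120 drugs, 200 proteins, 60 side
#' effects, 80 diseases, 32/16-dim embeddings) on which the complete
#' cross-validation pipeline runs on one CPU in minutes.
#'
#' @param name `"paper"` or `"desk"`.
#' @param ... overrides forwarded to [synth_config()].
#' @return A [synth_config()].
#' @export
scale_preset <- function(name = c("desk", "paper"), ...) {
  name <- match.arg(name)
  if (name == "paper") {
    synth_config(n_drugs = 707L, n_proteins = 1489L, n_side_effects = 4192L,
                 n_diseases = 5603L, drug_embedding_dim = 300L,
                 protein_embedding_dim = 100L, ...)
  } else {
    synth_config(...)
  }
}

# Find the intercept b such that mean(sigmoid(logits + b)) = target, by
# bisection (the mean is strictly increasing in b).
.calibrate_intercept <- function(logits, target, lo = -40, hi = 40, tol = 1e-10) {
  f <- function(b) mean(.sigmoid(logits + b)) - target
  if (f(lo) > 0 || f(hi) < 0) stop("density target unreachable by intercept calibration")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

.rand_string <- function(alphabet, len) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic dataset bundle
#'
#' Draws unit-Gaussian latents for every entity, fills each association
#' matrix with Bernoulli draws on `sigmoid(assoc_scale * <u, v> /
#' sqrt(latent_dim) + b)` (the intercept `b` calibrated to the density
#' target by bisection), symmetrizes DDI and PPI, sets PSIM to the
#' real-valued `sigmoid(<v_i, v_j> / sqrt(latent_dim))`, plants DTI
#' positives with slope `dti_scale`, and produces embeddings as a random
#' linear transform of the latents plus Gaussian noise. Entity payloads
#' are syntactically plausible placeholder SMILES/sequence strings.
#'
#' @param cfg a [synth_config()].
#' @return A list: `bundle` (a [dataset_bundle()]), `latents` (named list
#'   of the planted latent matrices), `dti_prob` (the full planted
#'   interaction probability matrix) and `realized_densities`.
#' @export
generate_bundle <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  .local_seed(cfg$seed, {
    L <- cfg$latent_dim
    lat <- list(
      drugs = matrix(stats::rnorm(cfg$n_drugs * L), cfg$n_drugs, L),
      proteins = matrix(stats::rnorm(cfg$n_proteins * L), cfg$n_proteins, L),
      side_effects = matrix(stats::rnorm(cfg$n_side_effects * L), cfg$n_side_effects, L),
      diseases = matrix(stats::rnorm(cfg$n_diseases * L), cfg$n_diseases, L))

    ids <- list(
      drugs = sprintf("DR%04d", seq_len(cfg$n_drugs)),
      proteins = sprintf("PR%04d", seq_len(cfg$n_proteins)),
      side_effects = sprintf("SE%04d", seq_len(cfg$n_side_effects)),
      diseases = sprintf("DI%04d", seq_len(cfg$n_diseases)))
    smiles <- vapply(seq_len(cfg$n_drugs), function(i)
      .rand_string(c("C", "N", "O", "c1ccccc1", "C(=O)", "Cl"), 4 + i %% 5),
      character(1))
    seqs <- vapply(seq_len(cfg$n_proteins), function(i)
      .rand_string(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 20 + i %% 15),
      character(1))
    reg <- list(
      drugs = entity_registry(ids$drugs, "drug", payload = smiles),
      proteins = entity_registry(ids$proteins, "protein", payload = seqs),
      side_effects = entity_registry(ids$side_effects, "side_effect"),
      diseases = entity_registry(ids$diseases, "disease"))

    link <- function(A, B) cfg$assoc_scale * (A %*% t(B)) / sqrt(L)
    draw_binary <- function(logits, target, symmetric = FALSE) {
      b <- .calibrate_intercept(logits, target)
      p <- .sigmoid(logits + b)
      m <- matrix(stats::rbinom(length(p), 1L, as.vector(p)), nrow(p), ncol(p))
      if (symmetric) {
        m[lower.tri(m)] <- t(m)[lower.tri(m)]
        diag(m) <- 0
      }
      m
    }
    DDI <- draw_binary(link(lat$drugs, lat$drugs), cfg$densities[["DDI"]], TRUE)
    DSIE <- draw_binary(link(lat$drugs, lat$side_effects), cfg$densities[["DSIE"]])
    DDIS <- draw_binary(link(lat$drugs, lat$diseases), cfg$densities[["DDIS"]])
    PPI <- draw_binary(link(lat$proteins, lat$proteins), cfg$densities[["PPI"]], TRUE)
    PDIS <- draw_binary(link(lat$proteins, lat$diseases), cfg$densities[["PDIS"]])
    PSIM <- .sigmoid((lat$proteins %*% t(lat$proteins)) / sqrt(L))
    PSIM <- (PSIM + t(PSIM)) / 2  # exact symmetry against rounding

    promiscuity <- cfg$dti_promiscuity_sd * stats::rnorm(cfg$n_drugs)
    dti_logits <- cfg$dti_scale * (lat$drugs %*% t(lat$proteins)) / sqrt(L) +
      promiscuity
    d0 <- .calibrate_intercept(dti_logits, cfg$dti_rate)
    dti_prob <- .sigmoid(dti_logits + d0)
    dti_draw <- matrix(stats::rbinom(length(dti_prob), 1L, as.vector(dti_prob)),
                       nrow(dti_prob), ncol(dti_prob))
    pos_idx <- which(dti_draw == 1L, arr.ind = TRUE)

    make_emb <- function(latents, dim) {
      Tm <- matrix(stats::rnorm(L * dim), L, dim) / sqrt(L)
      latents %*% Tm + cfg$embedding_noise_sd *
        matrix(stats::rnorm(nrow(latents) * dim), nrow(latents), dim)
    }
    drug_emb <- embedding_table(reg$drugs, make_emb(lat$drugs, cfg$drug_embedding_dim))
    prot_emb <- embedding_table(reg$proteins, make_emb(lat$proteins, cfg$protein_embedding_dim))

    matrices <- list(
      DDI = hetero_matrix("DDI", reg$drugs, reg$drugs, DDI),
      DSIE = hetero_matrix("DSIE", reg$drugs, reg$side_effects, DSIE),
      DDIS = hetero_matrix("DDIS", reg$drugs, reg$diseases, DDIS),
      PPI = hetero_matrix("PPI", reg$proteins, reg$proteins, PPI),
      PSIM = hetero_matrix("PSIM", reg$proteins, reg$proteins, PSIM),
      PDIS = hetero_matrix("PDIS", reg$proteins, reg$diseases, PDIS))
    dti <- pair_set(ids$drugs[pos_idx[, 1]], ids$proteins[pos_idx[, 2]])

    bundle <- dataset_bundle(reg$drugs, reg$proteins, reg$side_effects,
                             reg$diseases, matrices, drug_emb, prot_emb, dti)
    realized <- c(vapply(c("DDI", "DSIE", "DDIS", "PPI", "PDIS"),
                         function(nm) mean(matrices[[nm]]$values), numeric(1)),
                  DTI = mean(dti_draw))
    list(bundle = bundle, latents = lat, dti_prob = dti_prob,
         promiscuity = promiscuity, realized_densities = realized)
  })
}

#' Write a synthetic bundle in the standard file formats
#'
#' Emits the entity tables, edge lists, embedding tables and positive DTI
#' pairs as TSV files under `dir`, plus a JSON manifest with the
#' configuration and realized densities.
#'
#' @param synth result of [generate_bundle()].
#' @param cfg the [synth_config()] used.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(synth, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- synth$bundle
  wr_entities <- function(reg, file) {
    lines <- if (is.null(reg$payload)) reg$ids
             else paste(reg$ids, reg$payload[reg$ids], sep = "\t")
    writeLines(lines, file.path(dir, file))
  }
  wr_entities(b$drugs, "drugs.tsv")
  wr_entities(b$proteins, "proteins.tsv")
  wr_entities(b$side_effects, "side_effects.tsv")
  wr_entities(b$diseases, "diseases.tsv")
  for (nm in names(b$matrices)) {
    write_edge_list(b$matrices[[nm]], file.path(dir, paste0(tolower(nm), ".tsv")))
  }
  wr_emb <- function(tab, file) {
    df <- data.frame(id = tab$registry$ids, tab$values, check.names = FALSE)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  wr_emb(b$drug_embeddings, "drug_embeddings.tsv")
  wr_emb(b$protein_embeddings, "protein_embeddings.tsv")
  utils::write.table(b$dti[, c("drug_id", "protein_id")],
                     file.path(dir, "dti_positives.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(cfg), realized_densities = as.list(synth$realized_densities)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a bundle previously written by [write_bundle()]
#'
#' @param dir directory holding the TSV files.
#' @return A [dataset_bundle()].
#' @export
read_bundle <- function(dir) {
  drugs <- load_entities(file.path(dir, "drugs.tsv"), "drug")
  proteins <- load_entities(file.path(dir, "proteins.tsv"), "protein")
  side_effects <- load_entities(file.path(dir, "side_effects.tsv"), "side_effect")
  diseases <- load_entities(file.path(dir, "diseases.tsv"), "disease")
  axes <- list(DDI = list(drugs, drugs), DSIE = list(drugs, side_effects),
               DDIS = list(drugs, diseases), PPI = list(proteins, proteins),
               PSIM = list(proteins, proteins), PDIS = list(proteins, diseases))
  matrices <- lapply(names(axes), function(nm) {
    load_edge_list(file.path(dir, paste0(tolower(nm), ".tsv")),
                   axes[[nm]][[1]], axes[[nm]][[2]], nm)
  })
  names(matrices) <- names(axes)
  dataset_bundle(
    drugs, proteins, side_effects, diseases, matrices,
    load_embedding_table(file.path(dir, "drug_embeddings.tsv"), drugs),
    load_embedding_table(file.path(dir, "protein_embeddings.tsv"), proteins),
    load_dti_pairs(file.path(dir, "dti_positives.tsv")))
}
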