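#' Feature configuration
#'
#' Selects which blocks enter the concatenated drug-related vector D and
#' protein-related vector P. The embedding blocks (`Drug`, `Protein`) are
#' always present; association blocks can be dropped for ablations. The
#' concatenation order is fixed — `[Drug; DDI; DSIE; DDIS]` and
#' `[Protein; PPI; PSIM; PDIS]` — regardless of the order blocks are
#' requested in, so column offsets are stable across ablation variants.
#'
#' @param drug_blocks subset of `c("Drug", "DDI", "DSIE", "DDIS")`.
#' @param protein_blocks subset of `c("Protein", "PPI", "PSIM", "PDIS")`.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(drug_blocks = c("Drug", "DDI", "DSIE", "DDIS"),
                           protein_blocks = c("Protein", "PPI", "PSIM", "PDIS")) {
  d_all <- c("Drug", "DDI", "DSIE", "DDIS")
  p_all <- c("Protein", "PPI", "PSIM", "PDIS")
  drug_blocks <- unique(match.arg(drug_blocks, d_all, several.ok = TRUE))
  protein_blocks <- unique(match.arg(protein_blocks, p_all, several.ok = TRUE))
  if (!"Drug" %in% drug_blocks) stop("the Drug embedding block cannot be dropped")
  if (!"Protein" %in% protein_blocks) stop("the Protein embedding block cannot be dropped")
  structure(list(drug_blocks = d_all[d_all %in% drug_blocks],
                 protein_blocks = p_all[p_all %in% protein_blocks]),
            class = "feature_config")
}

#' Embedding providers
#'
#' A provider maps registry entries to fixed-length embedding vectors.
#' `table_provider` wraps a pre-computed [embedding_table()] (e.g.
#' pre-trained molecular or protein-sequence embeddings read from disk);
#' `synthetic_provider` derives a deterministic standard-normal vector
#' from each id and a seed, as a reproducible stand-in when no
#' pre-trained table is available.
#'
#' @param table an [embedding_table()].
#' @return An object of class `embedding_provider`.
#' @export
table_provider <- function(table) {
  stopifnot(inherits(table, "embedding_table"))
  structure(list(kind = "table", table = table, dim = table$dim),
            class = "embedding_provider")
}

#' @rdname table_provider
#' @param dim embedding dimension of the synthetic provider.
#' @param seed integer seed; the same (id, seed) always yields the same vector.
#' @export
synthetic_provider <- function(dim, seed = 1L) {
  stopifnot(dim >= 1)
  structure(list(kind = "synthetic", dim = as.integer(dim), seed = as.integer(seed)),
            class = "embedding_provider")
}

#' Materialize embeddings for a registry
#'
#' @param provider an embedding provider ([table_provider()] or
#'   [synthetic_provider()]).
#' @param registry the [entity_registry()] to cover.
#' @return An [embedding_table()] with rows in registry order.
#' @export
embed_entities <- function(provider, registry) {
  stopifnot(inherits(provider, "embedding_provider"))
  if (provider$kind == "table") {
    tab <- provider$table
    missing <- setdiff(registry$ids, tab$registry$ids)
    if (length(missing)) {
      stop("embedding table is missing id(s): ", paste(missing, collapse = ", "))
    }
    vals <- tab$values[registry$ids, , drop = FALSE]
    return(embedding_table(registry, vals))
  }
  vals <- t(vapply(registry$ids, function(id) {
    .local_seed(.id_hash(id, provider$seed), stats::rnorm(provider$dim))
  }, numeric(provider$dim)))
  embedding_table(registry, vals)
}

# Concatenate the selected blocks for one entity side; returns the matrix
# with a "blocks" attribute mapping block name -> 0-based half-open
# column range [start, end).
.assemble_side <- function(embeddings, blocks, sources, overrides = NULL) {
  parts <- list()
  offsets <- list()
  at <- 0L
  for (b in blocks) {
    m <- if (b %in% c("Drug", "Protein")) embeddings$values else sources[[b]]$values
    if (!is.null(overrides) && b %in% names(overrides)) {
      ov <- overrides[[b]]
      if (is.null(rownames(ov))) stop("override for ", b, " must have rownames")
      if (ncol(ov) != ncol(m)) stop("override for ", b, " has wrong width")
      pos <- match(rownames(ov), rownames(m))
      if (anyNA(pos)) stop("override for ", b, " names unknown entities")
      m[pos, ] <- ov
    }
    parts[[b]] <- m
    offsets[[b]] <- c(at, at + ncol(m))
    at <- at + ncol(m)
  }
  out <- do.call(cbind, parts)
  rownames(out) <- rownames(parts[[1]])
  attr(out, "blocks") <- offsets
  out
}

#' Assemble the drug-related feature matrix D
#'
#' Row i is the concatenation, in fixed block order, of drug i's embedding
#' and its rows of the selected association matrices (DDI, DSIE, DDIS).
#' `block_overrides` replaces selected rows of an association block with
#' externally supplied (e.g. imputed) real-valued vectors: a named list
#' `list(DDI = m, ...)` where each `m` has rownames identifying the drugs
#' to replace.
#'
#' @param bundle a [dataset_bundle()].
#' @param config a [feature_config()].
#' @param block_overrides optional named list of override matrices.
#' @return Numeric matrix `n_drugs x width` with a `"blocks"` attribute
#'   giving each block's 0-based half-open column range.
#' @export
assemble_drug_features <- function(bundle, config = feature_config(),
                                   block_overrides = NULL) {
  .assemble_side(bundle$drug_embeddings, config$drug_blocks,
                 bundle$matrices, block_overrides)
}

#' Assemble the protein-related feature matrix P
#'
#' @inheritParams assemble_drug_features
#' @return Numeric matrix `n_proteins x width` with a `"blocks"` attribute.
#' @export
assemble_protein_features <- function(bundle, config = feature_config(),
                                      block_overrides = NULL) {
  .assemble_side(bundle$protein_embeddings, config$protein_blocks,
                 bundle$matrices, block_overrides)
}

#' Build model inputs for drug-protein pairs
#'
#' Each pair becomes the row `[D[drug, ]; P[protein, ]]`.
#'
#' @param D,P feature matrices from [assemble_drug_features()] /
#'   [assemble_protein_features()] (rownames are entity ids).
#' @param pairs a [pair_set()] or data.frame with `drug_id` and
#'   `protein_id` columns.
#' @return Numeric matrix `nrow(pairs) x (width(D) + width(P))`.
#' @export
assemble_pair_input <- function(D, P, pairs) {
  di <- match(pairs$drug_id, rownames(D))
  pi_ <- match(pairs$protein_id, rownames(P))
  if (anyNA(di)) stop("unknown drug id(s): ",
                      paste(unique(pairs$drug_id[is.na(di)]), collapse = ", "))
  if (anyNA(pi_)) stop("unknown protein id(s): ",
                       paste(unique(pairs$protein_id[is.na(pi_)]), collapse = ", "))
  cbind(D[di, , drop = FALSE], P[pi_, , drop = FALSE])
}

#' Export a feature matrix with its block-offset sidecar
#'
#' Writes the matrix as TSV (`id` column first) and the block offsets as a
#' JSON sidecar (`<path>.blocks.json`, block name -> `[start, end)` 0-based
#' column range).
#'
#' @param features matrix from [assemble_drug_features()] or
#'   [assemble_protein_features()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(attr(features, "blocks"), paste0(path, ".blocks.json"),
                       auto_unbox = FALSE)
  invisible(path)
}
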