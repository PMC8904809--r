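#' Entity registries
#'
#' An `entity_registry` fixes an ordered id -> 0-based index map for one
#' entity kind (drugs, proteins, side effects or diseases). Every matrix
#' axis and feature-vector dimension in the package is pinned to a
#' registry, so the registry order is the single source of truth for
#' "which row is which entity".
#'
#' @param ids character vector of unique entity identifiers (order is kept).
#' @param kind one of `"drug"`, `"protein"`, `"side_effect"`, `"disease"`.
#' @param payload optional character vector parallel to `ids` (SMILES
#'   strings for drugs, amino-acid sequences for proteins).
#' @return An object of class `entity_registry`.
#' @export
entity_registry <- function(ids, kind = c("drug", "protein", "side_effect", "disease"),
                            payload = NULL) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("registry must contain at least one id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate %s id(s): %s", kind, paste(unique(dup), collapse = ", ")))
  }
  if (!is.null(payload)) {
    stopifnot(length(payload) == length(ids))
    payload <- as.character(payload)
    names(payload) <- ids
  }
  structure(
    list(kind = kind, ids = ids,
         index = stats::setNames(seq_along(ids) - 1L, ids),
         payload = payload),
    class = "entity_registry"
  )
}

#' @export
length.entity_registry <- function(x) length(x$ids)

#' @export
print.entity_registry <- function(x, ...) {
  cat(sprintf("<entity_registry> kind=%s n=%d\n", x$kind, length(x$ids)))
  invisible(x)
}

#' Resolve registry ids to 1-based row positions
#'
#' @param registry an [entity_registry()].
#' @param ids character vector of ids to resolve.
#' @return integer vector of 1-based positions.
#' @export
registry_pos <- function(registry, ids) {
  pos <- match(ids, registry$ids)
  if (anyNA(pos)) {
    stop(sprintf("unknown %s id(s): %s", registry$kind,
                 paste(unique(ids[is.na(pos)]), collapse = ", ")))
  }
  pos
}

.HETERO_NAMES <- c("DDI", "DSIE", "DDIS", "PPI", "PSIM", "PDIS")
.SQUARE_NAMES <- c("DDI", "PPI", "PSIM")

#' Named heterogeneous association matrix
#'
#' Wraps one of the six association matrices: DDI (drug-drug interactions),
#' DSIE (drug-side-effect), DDIS (drug-disease), PPI (protein-protein
#' interactions), PSIM (protein-protein similarity) and PDIS
#' (protein-disease). All are binary except PSIM, whose entries are
#' arbitrary non-negative reals (e.g. normalized local-alignment scores).
#' DDI, PPI and PSIM must be square and symmetric.
#'
#' @param name one of `"DDI"`, `"DSIE"`, `"DDIS"`, `"PPI"`, `"PSIM"`, `"PDIS"`.
#' @param rows,cols the [entity_registry()] objects for the two axes.
#' @param values dense numeric matrix, `length(rows) x length(cols)`.
#' @return An object of class `hetero_matrix`.
#' @export
hetero_matrix <- function(name, rows, cols, values) {
  name <- match.arg(name, .HETERO_NAMES)
  values <- as.matrix(values)
  if (nrow(values) != length(rows$ids) || ncol(values) != length(cols$ids)) {
    stop(sprintf("%s: matrix is %dx%d but registries demand %dx%d",
                 name, nrow(values), ncol(values), length(rows$ids), length(cols$ids)))
  }
  if (any(values < 0)) stop(sprintf("%s: negative entries are not allowed", name))
  if (name != "PSIM" && !all(values %in% c(0, 1))) {
    stop(sprintf("%s must be binary (0/1)", name))
  }
  if (name %in% .SQUARE_NAMES) {
    if (nrow(values) != ncol(values)) stop(sprintf("%s must be square", name))
    if (!isTRUE(all.equal(values, t(values), tolerance = 1e-12))) {
      stop(sprintf("%s must be symmetric", name))
    }
  }
  dimnames(values) <- list(rows$ids, cols$ids)
  structure(list(name = name, rows = rows, cols = cols, values = values),
            class = "hetero_matrix")
}

#' @export
print.hetero_matrix <- function(x, ...) {
  cat(sprintf("<hetero_matrix> %s %dx%d density=%.4f\n", x$name,
              nrow(x$values), ncol(x$values), mean(x$values != 0)))
  invisible(x)
}

#' Embedding table aligned to a registry
#'
#' Dense per-entity embedding vectors (e.g. 300-dim molecular embeddings
#' for drugs, 100-dim sequence embeddings for proteins), one row per
#' registry entry, in registry order.
#'
#' @param registry an [entity_registry()].
#' @param values numeric matrix with `length(registry)` rows.
#' @return An object of class `embedding_table` with a `dim` field.
#' @export
embedding_table <- function(registry, values) {
  values <- as.matrix(values)
  if (nrow(values) != length(registry$ids)) {
    stop(sprintf("embedding table has %d rows but registry has %d entries",
                 nrow(values), length(registry$ids)))
  }
  rownames(values) <- registry$ids
  structure(list(registry = registry, dim = ncol(values), values = values),
            class = "embedding_table")
}

#' Labelled drug-protein pair set
#'
#' Holds (drug_id, protein_id, label) triples with provenance: the fold a
#' pair belongs to and its split role (train/val/test/unassigned).
#' Duplicate (drug, protein) pairs are rejected.
#'
#' @param drug_id,protein_id character vectors of equal length.
#' @param label integer 0/1 vector (defaults to all 1, i.e. positives).
#' @param role one of `"train"`, `"val"`, `"test"`, `"unassigned"`,
#'   recycled to the pair count.
#' @param fold integer fold ids or `NA`, recycled.
#' @return A `pair_set`: a data.frame with columns drug_id, protein_id,
#'   label, role, fold.
#' @export
pair_set <- function(drug_id, protein_id, label = 1L, role = "unassigned", fold = NA_integer_) {
  n <- length(drug_id)
  stopifnot(length(protein_id) == n)
  label <- as.integer(rep_len(label, n))
  if (n > 0 && !all(label %in% c(0L, 1L))) stop("labels must be 0/1")
  df <- data.frame(drug_id = as.character(drug_id),
                   protein_id = as.character(protein_id),
                   label = label,
                   role = rep_len(as.character(role), n),
                   fold = rep_len(as.integer(fold), n),
                   stringsAsFactors = FALSE)
  key <- paste(df$drug_id, df$protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE]
    stop(sprintf("duplicate pair(s), e.g. (%s, %s)", d$drug_id[1], d$protein_id[1]))
  }
  class(df) <- c("pair_set", "data.frame")
  df
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d pairs (%d positive, %d negative)\n",
              nrow(x), sum(x$label == 1L), sum(x$label == 0L)))
  invisible(x)
}

#' Assemble a full dataset bundle
#'
#' Binds the four registries, the six association matrices, the two
#' embedding tables and the positive DTI pair list into one object, after
#' checking that every matrix axis matches its registry.
#'
#' @param drugs,proteins,side_effects,diseases [entity_registry()] objects.
#' @param matrices named list holding the six [hetero_matrix()] objects
#'   (names DDI, DSIE, DDIS, PPI, PSIM, PDIS).
#' @param drug_embeddings,protein_embeddings [embedding_table()] objects.
#' @param dti a [pair_set()] of known interactions; all labels must be 1
#'   at load time (negatives are sampled later by the CV protocol).
#' @return An object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(drugs, proteins, side_effects, diseases,
                           matrices, drug_embeddings, protein_embeddings, dti) {
  missing <- setdiff(.HETERO_NAMES, names(matrices))
  if (length(missing)) stop("missing matrices: ", paste(missing, collapse = ", "))
  axes <- list(
    DDI = list(drugs, drugs), DSIE = list(drugs, side_effects),
    DDIS = list(drugs, diseases), PPI = list(proteins, proteins),
    PSIM = list(proteins, proteins), PDIS = list(proteins, diseases)
  )
  for (nm in .HETERO_NAMES) {
    m <- matrices[[nm]]
    if (!identical(m$rows$ids, axes[[nm]][[1]]$ids) ||
        !identical(m$cols$ids, axes[[nm]][[2]]$ids)) {
      stop(sprintf("matrix %s axes do not match the bundle registries", nm))
    }
  }
  stopifnot(identical(drug_embeddings$registry$ids, drugs$ids),
            identical(protein_embeddings$registry$ids, proteins$ids))
  if (nrow(dti) > 0 && !all(dti$label == 1L)) {
    stop("dti pair set must contain positives only at load time")
  }
  registry_pos(drugs, dti$drug_id)
  registry_pos(proteins, dti$protein_id)
  structure(
    list(drugs = drugs, proteins = proteins, side_effects = side_effects,
         diseases = diseases, matrices = matrices,
         drug_embeddings = drug_embeddings,
         protein_embeddings = protein_embeddings, dti = dti),
    class = "dataset_bundle"
  )
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf(
    "<dataset_bundle> %d drugs, %d proteins, %d side effects, %d diseases, %d DTI pairs\n",
    length(x$drugs$ids), length(x$proteins$ids), length(x$side_effects$ids),
    length(x$diseases$ids), nrow(x$dti)))
  invisible(x)
}

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  lines
}

#' Load an entity table from a delimited file
#'
#' One record per line: `id<TAB>payload`, payload optional (SMILES for
#' drugs, amino-acid sequence for proteins). Lines beginning `#` are
#' skipped. File order is preserved.
#'
#' @param path path to a tab-separated file.
#' @param kind entity kind, see [entity_registry()].
#' @return An [entity_registry()].
#' @export
load_entities <- function(path, kind = c("drug", "protein", "side_effect", "disease")) {
  kind <- match.arg(kind)
  lines <- .read_tsv_lines(path)
  if (length(lines) == 0L) stop("empty entity file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  payload <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_,
                    character(1))
  if (all(is.na(payload))) payload <- NULL
  entity_registry(ids, kind, payload = payload)
}

#' Load an association edge list into a dense matrix
#'
#' Each line is `row_id<TAB>col_id[<TAB>weight]`; weights are only legal
#' for PSIM. Listed cells become 1 (or the weight), everything else 0.
#' For the square symmetric matrices (DDI, PPI, PSIM) each edge is
#' mirrored.
#'
#' @param path path to a tab-separated edge file.
#' @param rows,cols [entity_registry()] objects for the two axes.
#' @param name matrix name, see [hetero_matrix()].
#' @return A [hetero_matrix()].
#' @export
load_edge_list <- function(path, rows, cols, name) {
  name <- match.arg(name, .HETERO_NAMES)
  lines <- .read_tsv_lines(path)
  m <- matrix(0, nrow = length(rows$ids), ncol = length(cols$ids))
  if (length(lines) > 0L) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 2L)) stop("malformed edge line ", which(nf < 2L)[1], " in ", path)
    rid <- vapply(parts, `[[`, character(1), 1L)
    cid <- vapply(parts, `[[`, character(1), 2L)
    w <- rep(1, length(parts))
    has_w <- nf >= 3L
    if (any(has_w)) {
      if (name != "PSIM") {
        stop(sprintf("weight on binary matrix %s (line %d)", name, which(has_w)[1]))
      }
      w[has_w] <- as.numeric(vapply(parts[has_w], `[[`, character(1), 3L))
    }
    ri <- match(rid, rows$ids)
    ci <- match(cid, cols$ids)
    bad <- which(is.na(ri) | is.na(ci))
    if (length(bad)) {
      b <- bad[1]
      stop(sprintf("unknown id '%s' at line %d of %s",
                   if (is.na(ri[b])) rid[b] else cid[b], b, path))
    }
    m[cbind(ri, ci)] <- w
    if (name %in% .SQUARE_NAMES) m[cbind(ci, ri)] <- w
  }
  hetero_matrix(name, rows, cols, m)
}

#' Write a hetero matrix back to an edge list
#'
#' Inverse of [load_edge_list()]: emits one line per nonzero cell (upper
#' triangle plus diagonal only, for the symmetric matrices) with the
#' weight appended for PSIM.
#'
#' @param mat a [hetero_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(mat, path) {
  idx <- which(mat$values != 0, arr.ind = TRUE)
  if (mat$name %in% .SQUARE_NAMES) idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  lines <- character(0)
  if (nrow(idx) > 0) {
    lines <- paste(mat$rows$ids[idx[, 1]], mat$cols$ids[idx[, 2]], sep = "\t")
    if (mat$name == "PSIM") {
      lines <- paste(lines, format(mat$values[idx], digits = 10, trim = TRUE), sep = "\t")
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Validate a dataset bundle
#'
#' Runs structural checks on every matrix (dimensions against the
#' registries, binary values where required, symmetry for DDI/PPI/PSIM)
#' and on the embedding tables and DTI pairs, and reports per-matrix
#' densities.
#'
#' @param bundle a [dataset_bundle()].
#' @return A data.frame report with one row per check (`check`, `target`,
#'   `pass`, `detail`) plus an attribute `ok` that is TRUE iff all checks
#'   pass.
#' @export
validate_bundle <- function(bundle) {
  rows <- list()
  add <- function(check, target, pass, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, target = target, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }
  exp_dims <- list(
    DDI = c("drugs", "drugs"), DSIE = c("drugs", "side_effects"),
    DDIS = c("drugs", "diseases"), PPI = c("proteins", "proteins"),
    PSIM = c("proteins", "proteins"), PDIS = c("proteins", "diseases"))
  for (nm in .HETERO_NAMES) {
    m <- bundle$matrices[[nm]]
    want <- vapply(exp_dims[[nm]], function(k) length(bundle[[k]]$ids), integer(1))
    got <- dim(m$values)
    add("dimensions", nm, all(got == want),
        sprintf("%dx%d (expected %dx%d), density %.4f",
                got[1], got[2], want[1], want[2], mean(m$values != 0)))
    if (nm != "PSIM") {
      add("binary", nm, all(m$values %in% c(0, 1)), "")
    } else {
      add("nonnegative", nm, all(m$values >= 0), "")
    }
    if (nm %in% .SQUARE_NAMES) {
      add("symmetric", nm, isTRUE(all.equal(m$values, t(m$values), tolerance = 1e-12)), "")
    }
  }
  add("embedding_rows", "drug_embeddings",
      nrow(bundle$drug_embeddings$values) == length(bundle$drugs$ids), "")
  add("embedding_rows", "protein_embeddings",
      nrow(bundle$protein_embeddings$values) == length(bundle$proteins$ids), "")
  add("dti_ids", "dti",
      all(bundle$dti$drug_id %in% bundle$drugs$ids) &&
        all(bundle$dti$protein_id %in% bundle$proteins$ids), "")
  report <- do.call(rbind, rows)
  attr(report, "ok") <- all(report$pass)
  report
}

#' Load an embedding table from a delimited file
#'
#' Lines are `id<TAB>v1<TAB>...<TAB>vK`; every registry id must be
#' present. Rows are re-ordered to registry order.
#'
#' @param path path to a tab-separated file.
#' @param registry the [entity_registry()] the table must cover.
#' @return An [embedding_table()].
#' @export
load_embedding_table <- function(path, registry) {
  lines <- .read_tsv_lines(path)
  if (length(lines) == 0L) stop("empty embedding file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  k <- unique(lengths(parts)) - 1L
  if (length(k) != 1L) stop("inconsistent embedding dimension in ", path)
  vals <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(k)))
  rownames(vals) <- ids
  missing <- setdiff(registry$ids, ids)
  if (length(missing)) {
    stop("embedding table is missing id(s): ", paste(missing, collapse = ", "))
  }
  embedding_table(registry, vals[registry$ids, , drop = FALSE])
}

#' Load positive DTI pairs
#'
#' Lines are `drug_id<TAB>protein_id`; all pairs are labelled 1.
#'
#' @param path path to a tab-separated file.
#' @return A [pair_set()] of positives.
#' @export
load_dti_pairs <- function(path) {
  lines <- .read_tsv_lines(path)
  if (length(lines) == 0L) return(pair_set(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pair_set(vapply(parts, `[[`, character(1), 1L),
           vapply(parts, `[[`, character(1), 2L))
}
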