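# Cold-start cross-validation protocol: folds are built over drugs, not
# pairs, so every test drug is unseen during training. Fold loads are
# balanced on positive-interaction counts by a deterministic greedy rule,
# negatives are sampled per drug at a fixed ratio to its positives, and
# pairs split 85/5/10 into train/validation/test.

#' Assign drugs to balanced folds
#'
#' Drugs are sorted by descending positive-interaction count (ties broken
#' by id, lexicographically) and greedily assigned to the fold with the
#' smallest running positive total (ties to the lowest fold index), so
#' per-fold positive totals end up near-equal. Drugs with zero positives
#' are then distributed round-robin.
#'
#' @param positive_counts named integer vector: positives per drug (zeros
#'   allowed; names are drug ids).
#' @param k number of folds (default 10).
#' @return An object of class `fold_plan`: `k`, `drug_fold` (named
#'   integer, folds 1..k), `fold_positive_totals`.
#' @export
assign_drug_folds <- function(positive_counts, k = 10L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (is.null(names(positive_counts))) stop("positive_counts must be named by drug id")
  if (length(positive_counts) < k) stop("fewer drugs than folds")
  if (any(positive_counts < 0)) stop("counts must be non-negative")
  drugs <- names(positive_counts)
  pos <- positive_counts[order(-positive_counts, drugs)]
  with_pos <- pos[pos > 0]
  zero <- names(pos)[pos == 0]
  totals <- numeric(k)
  assignment <- integer(0)
  for (d in names(with_pos)) {
    f <- which.min(totals)  # ties -> lowest index
    totals[f] <- totals[f] + with_pos[[d]]
    assignment[d] <- f
  }
  if (length(zero)) {
    assignment[zero] <- rep_len(seq_len(k), length(zero))
  }
  structure(list(k = k, drug_fold = assignment[drugs],
                 fold_positive_totals = totals),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k=%d, positive totals: %s\n", x$k,
              paste(x$fold_positive_totals, collapse = ", ")))
  invisible(x)
}

#' Sample negative pairs per drug
#'
#' For each drug with positives, draws exactly `ratio x (its positives)`
#' negatives uniformly without replacement from that drug's non-positive
#' proteins; drugs with no positives receive `zero_positive_count`
#' negatives (default 3). Negatives never collide with known positives.
#'
#' @param positives a [pair_set()] of positive pairs.
#' @param proteins the protein [entity_registry()].
#' @param ratio negatives per positive (1, 3 or 5 in the standard
#'   protocol; any positive integer is accepted).
#' @param zero_positive_count negatives for drugs without positives.
#' @param seed RNG seed.
#' @param drugs drug ids to sample for; defaults to the drugs appearing
#'   in `positives` (pass the full registry id vector to include
#'   zero-positive drugs).
#' @return A [pair_set()] of negatives (label 0).
#' @export
sample_negatives <- function(positives, proteins, ratio = 1L,
                             zero_positive_count = 3L, seed = 1L,
                             drugs = NULL) {
  ratio <- as.integer(ratio)
  stopifnot(ratio >= 1, zero_positive_count >= 0)
  if (is.null(drugs)) drugs <- unique(positives$drug_id)
  drugs <- as.character(drugs)
  pos_by_drug <- split(positives$protein_id, positives$drug_id)
  n_prot <- length(proteins$ids)
  out_d <- list(); out_p <- list()
  .local_seed(seed, {
    for (d in drugs) {
      pos_p <- pos_by_drug[[d]]
      n_pos <- length(pos_p)
      need <- if (n_pos == 0L) zero_positive_count else ratio * n_pos
      if (need == 0L) next
      pool <- setdiff(proteins$ids, pos_p)
      if (need > length(pool)) {
        stop(sprintf(
          "drug %s: needs %d negatives but only %d non-positive proteins exist",
          d, need, length(pool)))
      }
      draw <- sample(pool, need)
      out_d[[d]] <- rep(d, need)
      out_p[[d]] <- draw
    }
  })
  pair_set(unlist(out_d, use.names = FALSE), unlist(out_p, use.names = FALSE),
           label = 0L)
}

#' Sample negative pairs globally
#'
#' Draws `n` negatives uniformly without replacement from all
#' (drug, protein) cells that are not known positives — the sampling
#' used with pair-based random cross-validation, where negatives are
#' picked over the whole grid rather than per drug.
#'
#' @param positives a [pair_set()] of positive pairs.
#' @param drugs,proteins the two [entity_registry()] objects.
#' @param n number of negatives to draw (conventionally
#'   `ratio * nrow(positives)`).
#' @param seed RNG seed.
#' @return A [pair_set()] of negatives (label 0).
#' @export
sample_negatives_global <- function(positives, drugs, proteins, n, seed = 1L) {
  nd <- length(drugs$ids); np <- length(proteins$ids)
  pos_cells <- (registry_pos(drugs, positives$drug_id) - 1) * np +
    registry_pos(proteins, positives$protein_id)
  n_free <- nd * np - length(pos_cells)
  if (n > n_free) stop("not enough non-positive cells to sample from")
  cells <- .local_seed(seed, {
    picked <- integer(0)
    # rejection sampling; the grid is far larger than the positive set
    while (length(picked) < n) {
      cand <- sample.int(nd * np, min(n * 2L, nd * np))
      cand <- setdiff(cand, c(pos_cells, picked))
      picked <- c(picked, cand[seq_len(min(length(cand), n - length(picked)))])
    }
    picked
  })
  di <- (cells - 1) %/% np + 1
  pi_ <- (cells - 1) %% np + 1
  pair_set(drugs$ids[di], proteins$ids[pi_], label = 0L)
}

#' Split pairs into train/validation/test for one fold
#'
#' Test pairs are all pairs whose drug lies in `test_fold`; the
#' validation set is a seeded pair-level sample from the remaining pairs
#' sized to `val_fraction` of all pairs (~5%), and the rest trains
#' (~85% with balanced folds). Train and validation drugs are disjoint
#' from test drugs by construction, so every test drug is unseen.
#'
#' @param plan a [fold_plan()].
#' @param all_pairs a labelled [pair_set()] (positives and negatives).
#' @param test_fold fold index in 1..k.
#' @param val_fraction validation share of all pairs (default 0.05).
#' @param seed RNG seed for the validation sample.
#' @return A list of three [pair_set()]s: `train`, `val`, `test`, with
#'   roles and fold ids filled in.
#' @export
make_splits <- function(plan, all_pairs, test_fold, val_fraction = 0.05, seed = 1L) {
  test_fold <- as.integer(test_fold)
  if (test_fold < 1L || test_fold > plan$k) stop("test_fold out of range")
  fold_of <- plan$drug_fold[all_pairs$drug_id]
  if (anyNA(fold_of)) {
    stop("pair drug(s) missing from the fold plan: ",
         paste(unique(all_pairs$drug_id[is.na(fold_of)]), collapse = ", "))
  }
  is_test <- fold_of == test_fold
  rest <- which(!is_test)
  n_val <- min(length(rest), round(val_fraction * nrow(all_pairs)))
  val_idx <- .local_seed(seed, sample(rest, n_val))
  roles <- rep("train", nrow(all_pairs))
  roles[is_test] <- "test"
  roles[val_idx] <- "val"
  mk <- function(role) {
    p <- all_pairs[roles == role, , drop = FALSE]
    pair_set(p$drug_id, p$protein_id, p$label, role = role,
             fold = rep(test_fold, nrow(p)))
  }
  list(train = mk("train"), val = mk("val"), test = mk("test"))
}

#' Random pair-based fold assignment
#'
#' The permissive alternative to drug-based folds: pairs are partitioned
#' uniformly at random into k near-equal folds, so the same drug can
#' appear in both training and test folds.
#'
#' @param all_pairs a [pair_set()].
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids (1..k), one per pair.
#' @export
make_pair_folds <- function(all_pairs, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  n <- nrow(all_pairs)
  .local_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Splits for one pair-based fold
#'
#' Test pairs are those assigned to `test_fold`; validation is a seeded
#' `val_fraction` sample of the remaining pairs; the rest trains. Unlike
#' [make_splits()], drugs may be shared across the three sets.
#'
#' @param pair_folds integer vector from [make_pair_folds()].
#' @param all_pairs the matching [pair_set()].
#' @param test_fold fold index in 1..k.
#' @param val_fraction validation share of all pairs.
#' @param seed RNG seed.
#' @return A list of [pair_set()]s: `train`, `val`, `test`.
#' @export
make_pair_splits <- function(pair_folds, all_pairs, test_fold,
                             val_fraction = 0.05, seed = 1L) {
  stopifnot(length(pair_folds) == nrow(all_pairs))
  is_test <- pair_folds == test_fold
  rest <- which(!is_test)
  n_val <- min(length(rest), round(val_fraction * nrow(all_pairs)))
  val_idx <- .local_seed(seed, sample(rest, n_val))
  roles <- rep("train", nrow(all_pairs))
  roles[is_test] <- "test"
  roles[val_idx] <- "val"
  mk <- function(role) {
    p <- all_pairs[roles == role, , drop = FALSE]
    pair_set(p$drug_id, p$protein_id, p$label, role = role,
             fold = rep(as.integer(test_fold), nrow(p)))
  }
  list(train = mk("train"), val = mk("val"), test = mk("test"))
}

#' Filter near-duplicate test drugs
#'
#' Retains only the test drugs whose similarity to every training drug is
#' strictly below `threshold` (default 0.6), removing redundant test
#' drugs that could inflate cold-start performance. The similarity matrix
#' is supplied by the caller (e.g. fingerprint Tanimoto similarity) and
#' must have row/column names covering all listed drugs.
#'
#' @param test_drugs,train_drugs character vectors of drug ids.
#' @param similarity numeric matrix with dimnames.
#' @param threshold strict upper bound on train-test similarity.
#' @return Character vector of retained test drug ids.
#' @export
filter_redundant_test_drugs <- function(test_drugs, train_drugs, similarity,
                                        threshold = 0.6) {
  if (length(train_drugs) == 0L) return(test_drugs)
  miss <- setdiff(c(test_drugs, train_drugs), rownames(similarity))
  if (length(miss) || !all(train_drugs %in% colnames(similarity))) {
    stop("similarity matrix is missing entries for: ",
         paste(unique(c(miss, setdiff(train_drugs, colnames(similarity)))),
               collapse = ", "))
  }
  sub <- similarity[test_drugs, train_drugs, drop = FALSE]
  test_drugs[apply(sub, 1, max) < threshold]
}

#' Write and read fold plans
#'
#' Fold plans round-trip through TSV (`drug_id<TAB>fold`).
#'
#' @param plan a [fold_plan()].
#' @param path file path.
#' @return `path` (write) or a `fold_plan` (read).
#' @export
write_fold_plan <- function(plan, path) {
  utils::write.table(
    data.frame(drug_id = names(plan$drug_fold), fold = plan$drug_fold),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  df <- utils::read.table(path, sep = "\t", col.names = c("drug_id", "fold"),
                          stringsAsFactors = FALSE)
  k <- max(df$fold)
  structure(list(k = as.integer(k),
                 drug_fold = stats::setNames(as.integer(df$fold), df$drug_id),
                 fold_positive_totals = NULL),
            class = "fold_plan")
}
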