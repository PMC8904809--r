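#' Prediction records
#'
#' The common currency of the evaluation suite: one row per scored
#' drug-protein pair, with the predicted probability, the true label and
#' the fold the pair was tested in.
#'
#' @param drug_id,protein_id character vectors.
#' @param probability numeric vector of predicted probabilities.
#' @param label 0/1 vector of true labels.
#' @param fold integer fold ids (NA allowed).
#' @return A data.frame of class `prediction_records`.
#' @export
prediction_records <- function(drug_id, protein_id, probability, label,
                               fold = NA_integer_) {
  stopifnot(all(is.finite(probability)), all(label %in% c(0, 1)))
  df <- data.frame(drug_id = as.character(drug_id),
                   protein_id = as.character(protein_id),
                   probability = as.numeric(probability),
                   label = as.integer(label),
                   fold = rep_len(as.integer(fold), length(probability)),
                   stringsAsFactors = FALSE)
  class(df) <- c("prediction_records", "data.frame")
  df
}

#' Confusion counts at a probability threshold
#'
#' A pair is predicted positive iff its probability is `>= threshold`
#' (ties at the threshold count as positive).
#'
#' @param records a [prediction_records()] data.frame (or anything with
#'   `probability` and `label` columns).
#' @param threshold decision threshold, default 0.5.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(records, threshold = 0.5) {
  if (nrow(records) == 0L) stop("records must be non-empty")
  pred <- records$probability >= threshold
  pos <- records$label == 1L
  c(TP = sum(pred & pos), FP = sum(pred & !pos),
    TN = sum(!pred & !pos), FN = sum(!pred & pos))
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' F1 = 2*Precision*Recall/(Precision+Recall); any 0/0 is defined as 0.
#'
#' @param counts named vector from [confusion_counts()].
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' ROC AUC (Mann-Whitney concordance)
#'
#' The probability that a random positive is scored above a random
#' negative, with ties counted one half: computed exactly from midranks.
#'
#' @param probabilities numeric scores.
#' @param labels 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc undefined: both classes must be present")
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall AUC (step integration)
#'
#' Walks the thresholds from the highest score down (grouping tied
#' scores) and accumulates `(R_k - R_{k-1}) * P_k` — the step-wise
#' average-precision integral over recall, with no trapezoidal
#' interpolation.
#'
#' @inheritParams roc_auc
#' @return AUCPR in `[0, 1]`.
#' @export
pr_auc <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L || n_pos == length(labels)) {
    stop("pr_auc undefined: both classes must be present")
  }
  o <- order(probabilities, decreasing = TRUE)
  s <- probabilities[o]
  y <- labels[o]
  # cut at each distinct score (last index of every tie group)
  cuts <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[cuts]
  n_at <- cuts
  precision <- tp / n_at
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Per-drug ROC AUC
#'
#' AUC over each drug's own test pairs. Drugs whose pairs are
#' single-class — including single-target drugs, for which no AUC can be
#' computed — are excluded from the AUC table and reported separately.
#'
#' @param records a [prediction_records()] data.frame.
#' @return A list: `auc` (data.frame drug_id / n_pairs / n_targets /
#'   auc) and `excluded` (data.frame drug_id / n_pairs).
#' @export
per_drug_auc <- function(records) {
  split_ <- split(seq_len(nrow(records)), records$drug_id)
  kept <- list(); excl <- list()
  for (d in names(split_)) {
    idx <- split_[[d]]
    y <- records$label[idx]
    if (length(unique(y)) < 2L) {
      excl[[d]] <- data.frame(drug_id = d, n_pairs = length(idx),
                              stringsAsFactors = FALSE)
    } else {
      kept[[d]] <- data.frame(
        drug_id = d, n_pairs = length(idx), n_targets = sum(y == 1),
        auc = roc_auc(records$probability[idx], y), stringsAsFactors = FALSE)
    }
  }
  list(auc = if (length(kept)) do.call(rbind, c(kept, make.row.names = FALSE))
             else data.frame(drug_id = character(0), n_pairs = integer(0),
                             n_targets = integer(0), auc = numeric(0)),
       excluded = if (length(excl)) do.call(rbind, c(excl, make.row.names = FALSE))
                  else data.frame(drug_id = character(0), n_pairs = integer(0)))
}

#' Per-drug probability separation ("distance")
#'
#' For each drug, the absolute difference between the mean probability of
#' its predicted-positive pairs and the mean probability of its
#' predicted-negative pairs (prediction at `threshold`). Drugs with all
#' pairs in one predicted class have no defined distance and are excluded.
#'
#' @param records a [prediction_records()] data.frame.
#' @param threshold decision threshold, default 0.5.
#' @return A list: `distance` (data.frame drug_id / distance) and
#'   `excluded` (character vector of drug ids).
#' @export
drug_distance <- function(records, threshold = 0.5) {
  split_ <- split(seq_len(nrow(records)), records$drug_id)
  kept <- list(); excl <- character(0)
  for (d in names(split_)) {
    idx <- split_[[d]]
    p <- records$probability[idx]
    pred <- p >= threshold
    if (all(pred) || all(!pred)) {
      excl <- c(excl, d)
    } else {
      kept[[d]] <- data.frame(drug_id = d,
                              distance = abs(mean(p[pred]) - mean(p[!pred])),
                              stringsAsFactors = FALSE)
    }
  }
  list(distance = if (length(kept)) do.call(rbind, c(kept, make.row.names = FALSE))
                  else data.frame(drug_id = character(0), distance = numeric(0)),
       excluded = excl)
}

#' Protein-frequency threshold baseline
#'
#' A calibration-free frequency rule: for each protein, compute the ratio
#' of positive pairs among all of its pairs in the training set (sampled
#' negatives included); a test pair is predicted positive (probability 1)
#' iff that ratio is `>= threshold`. Proteins absent from training get
#' ratio 0.
#'
#' @param train a labelled [pair_set()] (positives and negatives).
#' @param test a labelled [pair_set()] to score.
#' @param threshold positive-ratio cut-off, conventionally 0.25, 0.50 or
#'   0.75.
#' @return A list: `records` ([prediction_records()] with 0/1
#'   probabilities), `counts`, `metrics` (precision/recall/F1) and
#'   `ratios` (per-protein training positive ratio).
#' @export
thr_baseline <- function(train, test, threshold = 0.5) {
  if (nrow(train) == 0L) stop("training pairs must be non-empty")
  tot <- table(train$protein_id)
  pos <- table(train$protein_id[train$label == 1L])
  ratios <- stats::setNames(as.numeric(pos[names(tot)]), names(tot))
  ratios[is.na(ratios)] <- 0
  ratios <- ratios / as.numeric(tot)
  r_test <- ratios[test$protein_id]
  r_test[is.na(r_test)] <- 0
  prob <- as.numeric(r_test >= threshold)
  records <- prediction_records(test$drug_id, test$protein_id, prob,
                                test$label, test$fold)
  counts <- confusion_counts(records)
  list(records = records, counts = counts,
       metrics = precision_recall_f1(counts), ratios = ratios)
}

#' Paired fold-wise t-test between two methods
#'
#' Two-sided paired t-test on per-fold metric values (folds are matched
#' across methods). Degenerate cases follow fixed conventions: identical
#' vectors give p = 1; a constant non-zero difference (zero variance)
#' gives a p-value reported at the machine floor.
#'
#' @param metric_a,metric_b equal-length numeric vectors (one value per
#'   fold).
#' @return The p-value.
#' @export
compare_folds_ttest <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b)) stop("fold vectors differ in length")
  if (length(metric_a) < 2L) stop("at least two folds are required")
  d <- metric_a - metric_b
  if (stats::sd(d) < .Machine$double.eps) {
    return(if (abs(mean(d)) < .Machine$double.eps) 1 else .Machine$double.xmin)
  }
  stats::t.test(metric_a, metric_b, paired = TRUE)$p.value
}

#' Aggregate per-fold evaluation report
#'
#' Computes ROC AUC, PR AUC, precision, recall and F1 per fold and their
#' mean and standard deviation across folds.
#'
#' @param records a [prediction_records()] data.frame with a `fold`
#'   column.
#' @param threshold decision threshold for the confusion-based metrics.
#' @return A list of class `eval_report`: `per_fold` (data.frame) and
#'   `summary` (data.frame metric / mean / sd).
#' @export
eval_report <- function(records, threshold = 0.5) {
  folds <- sort(unique(records$fold))
  per <- lapply(folds, function(f) {
    r <- records[records$fold == f, , drop = FALSE]
    counts <- confusion_counts(r, threshold)
    prf <- precision_recall_f1(counts)
    data.frame(fold = f, n = nrow(r),
               auc = roc_auc(r$probability, r$label),
               aucpr = pr_auc(r$probability, r$label),
               precision = prf[["precision"]], recall = prf[["recall"]],
               f1 = prf[["f1"]])
  })
  per <- do.call(rbind, per)
  metrics <- c("auc", "aucpr", "precision", "recall", "f1")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(per_fold = per, summary = summary), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d fold(s)\n", nrow(x$per_fold)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i],
                ifelse(is.na(s$sd[i]), 0, s$sd[i])))
  }
  invisible(x)
}

#' Write prediction records and a report to disk
#'
#' Predictions go to TSV (`drug_id, protein_id, probability, label,
#' fold`); the report to JSON.
#'
#' @param records a [prediction_records()] data.frame.
#' @param report an [eval_report()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_outputs <- function(records, report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(records, file.path(dir, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(per_fold = report$per_fold, summary = report$summary),
                       file.path(dir, "report.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
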