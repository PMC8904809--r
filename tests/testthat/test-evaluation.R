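test_that("confusion counts use the >= threshold convention", {
  r <- prediction_records(c("d", "d"), c("p1", "p2"), c(0.9, 0.4), c(1, 0))
  expect_equal(confusion_counts(r), c(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  # exactly at the threshold counts as predicted positive
  r2 <- prediction_records("d", "p", 0.5, 0)
  expect_equal(confusion_counts(r2)[["FP"]], 1L)
  r3 <- prediction_records(rep("d", 4), paste0("p", 1:4), rep(0, 4), rep(1, 4))
  expect_equal(confusion_counts(r3)[["FN"]], 4L)
  expect_equal(sum(confusion_counts(r3)), 4L)
})

test_that("precision/recall/F1 follow the closed forms with 0/0 -> 0", {
  m <- precision_recall_f1(c(TP = 2, FP = 1, TN = 0, FN = 2))
  expect_equal(m[["precision"]], 2 / 3)
  expect_equal(m[["recall"]], 1 / 2)
  expect_equal(m[["f1"]], 4 / 7)
  expect_equal(unname(precision_recall_f1(c(TP = 0, FP = 0, TN = 5, FN = 0))),
               c(0, 0, 0))
  expect_equal(unname(precision_recall_f1(c(TP = 3, FP = 0, TN = 2, FN = 0))),
               c(1, 1, 1))
})

test_that("roc_auc matches brute-force concordant-pair counting", {
  expect_equal(roc_auc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6), c(1, 1, 0)), 0.5)
  set.seed(11)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    scores <- round(runif(n), 2)              # rounding induces ties
    expect_equal(roc_auc(scores, labels), brute_force_auc(scores, labels))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("roc_auc on random scores concentrates at one half", {
  set.seed(3)
  labels <- rep(c(0, 1), 5000)
  expect_equal(roc_auc(runif(10000), labels), 0.5, tolerance = 0.02)
})

test_that("pr_auc performs step integration over recall", {
  # perfect ranking: precision 1 at every recall level
  expect_equal(pr_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  # hand case: scores .9(+), .8(-), .7(+); steps: R=1/2 at P=1, R=1 at P=2/3
  expect_equal(pr_auc(c(0.9, 0.8, 0.7), c(1, 0, 1)), 0.5 * 1 + 0.5 * (2 / 3))
  # tied scores are grouped into one step
  expect_equal(pr_auc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(pr_auc(c(0.1, 0.2), c(0, 0)), "both classes")
})

test_that("per-drug AUC excludes single-class drugs and conserves records", {
  r <- prediction_records(
    c("a", "a", "b", "c", "c"), paste0("p", 1:5),
    c(0.9, 0.2, 0.8, 0.3, 0.6), c(1, 0, 1, 1, 1))
  out <- per_drug_auc(r)
  expect_equal(out$auc$drug_id, "a")
  expect_equal(out$auc$auc, 1)
  expect_setequal(out$excluded$drug_id, c("b", "c"))
  expect_equal(sum(out$auc$n_pairs) + sum(out$excluded$n_pairs), nrow(r))
})

test_that("drug distance is the separation of predicted classes", {
  r <- prediction_records(c("a", "a"), c("p1", "p2"), c(0.9, 0.2), c(1, 0))
  out <- drug_distance(r)
  expect_equal(out$distance$distance, 0.7)
  r2 <- prediction_records(c("b", "b"), c("p1", "p2"), c(0.9, 0.8), c(1, 0))
  out2 <- drug_distance(r2)
  expect_equal(out2$excluded, "b")
  set.seed(4)
  r3 <- prediction_records(rep("c", 20), paste0("p", 1:20), runif(20),
                           rbinom(20, 1, 0.5))
  d3 <- drug_distance(r3)$distance$distance
  expect_true(all(d3 >= 0 & d3 <= 1))
})

test_that("the frequency-rule baseline thresholds per-protein positive ratios", {
  train <- pair_set(sprintf("d%02d", 1:10), rep("pA", 10),
                    label = c(rep(1, 3), rep(0, 7)))
  test <- pair_set("d99", "pA", label = 1L)
  expect_equal(thr_baseline(train, test, 0.25)$records$probability, 1)  # 0.3 >= 0.25
  expect_equal(thr_baseline(train, test, 0.50)$records$probability, 0)
  expect_equal(thr_baseline(train, test, 0.75)$records$probability, 0)
  # protein absent from training -> ratio 0 -> negative everywhere
  test_new <- pair_set("d99", "pNew", label = 0L)
  expect_equal(thr_baseline(train, test_new, 0.25)$records$probability, 0)
  # all-positive protein -> positive at every threshold
  train2 <- pair_set(c("d1", "d2"), c("pB", "pB"), label = 1L)
  test2 <- pair_set("d9", "pB", label = 1L)
  expect_equal(thr_baseline(train2, test2, 0.75)$records$probability, 1)
})

test_that("fold-wise t-test follows the paired closed form and conventions", {
  expect_equal(compare_folds_ttest(rep(0.8, 5), rep(0.8, 5)), 1)
  expect_equal(compare_folds_ttest(c(1, 1, 1, 1), c(0, 0, 0, 0)),
               .Machine$double.xmin)
  a <- c(0.8, 0.7, 0.9, 0.75, 0.85)
  b <- a - c(0.1, -0.1, 0.2, 0.0, 0.05)
  d <- a - b
  t_stat <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(compare_folds_ttest(a, b), 2 * pt(-abs(t_stat), df = 4))
  expect_error(compare_folds_ttest(1:3, 1:4), "length")
})

test_that("eval reports aggregate per-fold metrics consistently", {
  set.seed(9)
  r <- prediction_records(rep(sprintf("d%d", 1:4), each = 10),
                          rep(paste0("p", 1:10), 4),
                          runif(40), rbinom(40, 1, 0.5),
                          fold = rep(1:2, each = 20))
  rep_ <- eval_report(r)
  expect_equal(nrow(rep_$per_fold), 2L)
  expect_true(all(rep_$per_fold$auc >= 0 & rep_$per_fold$auc <= 1))
  # threshold consistency: report metrics equal direct recomputation
  f1 <- r[r$fold == 1, ]
  expect_equal(rep_$per_fold$precision[1],
               precision_recall_f1(confusion_counts(f1))[["precision"]])
  expect_equal(rep_$summary$mean[rep_$summary$metric == "auc"],
               mean(rep_$per_fold$auc))
})
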