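test_that("greedy fold assignment balances positive totals deterministically", {
  counts <- c(A = 5L, B = 4L, C = 3L, D = 2L, E = 1L, F = 1L)
  plan <- assign_drug_folds(counts, k = 2)
  expect_setequal(names(plan$drug_fold)[plan$drug_fold == 1], c("A", "D", "E"))
  expect_setequal(names(plan$drug_fold)[plan$drug_fold == 2], c("B", "C", "F"))
  expect_equal(plan$fold_positive_totals, c(8, 8))

  # equal counts, k divides n -> perfectly equal folds
  eq <- assign_drug_folds(stats::setNames(rep(2L, 12), sprintf("d%02d", 1:12)), k = 4)
  expect_equal(as.vector(table(eq$drug_fold)), rep(3L, 4))
  expect_equal(eq$fold_positive_totals, rep(6, 4))

  expect_error(assign_drug_folds(c(a = 1L), k = 2), "fewer drugs")
})

test_that("fold balance never exceeds the largest single-drug count", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    k <- sample(2:min(4, n), 1)
    counts <- stats::setNames(rpois(n, 3), sprintf("d%02d", seq_len(n)))
    plan <- assign_drug_folds(counts, k)
    # partition: every drug in exactly one fold
    expect_setequal(names(plan$drug_fold), names(counts))
    expect_true(all(plan$drug_fold %in% seq_len(k)))
    totals <- vapply(seq_len(k), function(f)
      sum(counts[names(plan$drug_fold)[plan$drug_fold == f]]), numeric(1))
    expect_lte(max(totals) - min(totals), max(c(counts, 1)))
  }
})

test_that("negative sampling is exact per drug, seeded, and collision-free", {
  proteins <- tiny_registry(30, "protein", "P")
  positives <- pair_set(c("a", "a", "b"), c("P001", "P002", "P003"))
  neg <- sample_negatives(positives, proteins, ratio = 3, seed = 5,
                          drugs = c("a", "b", "zero"))
  expect_equal(sum(neg$drug_id == "a"), 6L)   # 2 positives x 3
  expect_equal(sum(neg$drug_id == "b"), 3L)
  expect_equal(sum(neg$drug_id == "zero"), 3L)  # zero-positive convention
  expect_true(all(neg$label == 0L))
  # disjoint from the drug's own positives
  expect_false(any(neg$protein_id[neg$drug_id == "a"] %in% c("P001", "P002")))
  neg2 <- sample_negatives(positives, proteins, ratio = 3, seed = 5,
                           drugs = c("a", "b", "zero"))
  expect_identical(neg, neg2)
  # infeasible request errors with the drug named
  few <- tiny_registry(4, "protein", "P")
  expect_error(sample_negatives(positives, few, ratio = 3, seed = 1), "a")
})

test_that("drug-based splits partition pairs with the cold-start guarantee", {
  set.seed(31)
  drugs <- sprintf("d%02d", 1:20)
  counts <- stats::setNames(sample(0:6, 20, replace = TRUE), drugs)
  counts[1:15] <- pmax(counts[1:15], 1L)
  plan <- assign_drug_folds(counts, k = 5)
  proteins <- tiny_registry(40, "protein", "P")
  pos <- pair_set(rep(drugs, counts), proteins$ids[unlist(lapply(counts, seq_len))])
  neg <- sample_negatives(pos, proteins, ratio = 1, seed = 2, drugs = drugs)
  all_pairs <- pair_set(c(pos$drug_id, neg$drug_id),
                        c(pos$protein_id, neg$protein_id),
                        c(rep(1L, nrow(pos)), rep(0L, nrow(neg))))
  for (f in 1:5) {
    sp <- make_splits(plan, all_pairs, f, seed = 7)
    expect_equal(nrow(sp$train) + nrow(sp$val) + nrow(sp$test), nrow(all_pairs))
    key <- function(p) paste(p$drug_id, p$protein_id)
    expect_equal(anyDuplicated(c(key(sp$train), key(sp$val), key(sp$test))), 0L)
    # no test drug leaks into train or val
    expect_length(intersect(unique(sp$test$drug_id),
                            c(sp$train$drug_id, sp$val$drug_id)), 0)
    expect_equal(nrow(sp$val), round(0.05 * nrow(all_pairs)))
  }
})

test_that("split sizes approximate the 85/5/10 design with balanced folds", {
  set.seed(41)
  drugs <- sprintf("d%03d", 1:100)
  counts <- stats::setNames(rep(5L, 100), drugs)
  plan <- assign_drug_folds(counts, k = 10)
  proteins <- tiny_registry(60, "protein", "P")
  pos <- pair_set(rep(drugs, each = 5),
                  unlist(lapply(1:100, function(i) proteins$ids[((i + 1:5) %% 60) + 1])))
  neg <- sample_negatives(pos, proteins, ratio = 1, seed = 3, drugs = drugs)
  all_pairs <- pair_set(c(pos$drug_id, neg$drug_id),
                        c(pos$protein_id, neg$protein_id),
                        c(rep(1L, nrow(pos)), rep(0L, nrow(neg))))
  sp <- make_splits(plan, all_pairs, 1, seed = 9)
  n <- nrow(all_pairs)
  expect_equal(nrow(sp$test) / n, 0.10, tolerance = 0.03)
  expect_equal(nrow(sp$val) / n, 0.05, tolerance = 0.01)
  expect_equal(nrow(sp$train) / n, 0.85, tolerance = 0.03)
})

test_that("pair-based folds are near-equal, seeded, and share drugs across folds", {
  pairs <- pair_set(rep(sprintf("d%d", 1:10), each = 10),
                    rep(sprintf("p%02d", 1:10), 10))
  f <- make_pair_folds(pairs, k = 10, seed = 4)
  expect_equal(as.vector(table(f)), rep(10L, 10))
  expect_identical(f, make_pair_folds(pairs, k = 10, seed = 4))
  # a drug with >= 2 pairs lands in >= 2 folds (the permissive protocol)
  expect_gt(length(unique(f[pairs$drug_id == "d1"])), 1L)
  sp <- make_pair_splits(f, pairs, 1, seed = 4)
  expect_equal(nrow(sp$test), 10L)
  expect_gt(length(intersect(unique(sp$test$drug_id), unique(sp$train$drug_id))), 0)
})

test_that("redundancy filtering removes test drugs at similarity >= threshold", {
  sim <- matrix(0, 3, 3, dimnames = list(c("t1", "t2", "r1"),
                                         c("t1", "t2", "r1")))
  sim["t1", "r1"] <- 0.59
  sim["t2", "r1"] <- 0.60
  kept <- filter_redundant_test_drugs(c("t1", "t2"), "r1", sim)
  expect_equal(kept, "t1")   # 0.59 retained, 0.60 removed (strict <)
  expect_equal(filter_redundant_test_drugs(c("t1", "t2"), character(0), sim),
               c("t1", "t2"))
  expect_error(filter_redundant_test_drugs("t9", "r1", sim), "t9")
})

test_that("fold plans round-trip through TSV", {
  counts <- stats::setNames(c(3L, 2L, 1L, 0L), c("a", "b", "c", "d"))
  plan <- assign_drug_folds(counts, 2)
  path <- withr::local_tempfile()
  write_fold_plan(plan, path)
  again <- read_fold_plan(path)
  expect_equal(again$drug_fold[names(plan$drug_fold)], plan$drug_fold)
})
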