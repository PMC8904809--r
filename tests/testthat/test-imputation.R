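test_that("imputer architecture pins input/output widths to the block sizes", {
  m <- build_imputer("DDI", 300, 707, seed = 1)
  expect_equal(dim(m$params$W1), c(300L + 707L, 1024L))  # default DDI dims
  expect_equal(m$hidden_dims, c(1024L, 512L, 128L))
  expect_equal(dim(m$params$W4), c(128L, 707L))
  m2 <- build_imputer("PDIS", 100, 5603, hidden_dims = c(8, 8, 8), seed = 1)
  expect_equal(dim(m2$params$W1)[1], 5703L)
  expect_equal(dim(m2$params$W4)[2], 5603L)
  expect_equal(build_imputer("DSIE", 4, 9, hidden_dims = c(5, 4, 3), seed = 1)$hidden_dims,
               c(5L, 4L, 3L))
  expect_error(build_imputer("DDI", 0, 5), "positive")
  expect_error(build_imputer("DDI", 4, 5, hidden_dims = c(3, 2)), "three hidden")
  expect_identical(build_imputer("DDI", 4, 5, hidden_dims = c(4, 3, 2), seed = 7),
                   build_imputer("DDI", 4, 5, hidden_dims = c(4, 3, 2), seed = 7))
})

tiny_imputer_setup <- function(n = 12, d = 4, k = 6, seed = 3) {
  hetdti:::.local_seed(seed, {
    reg <- tiny_registry(n, "drug", "D")
    emb <- embedding_table(reg, matrix(rnorm(n * d), n, d))
    mat <- hetero_matrix("DSIE", reg, tiny_registry(k, "side_effect", "S"),
                         matrix(rbinom(n * k, 1, 0.4), n, k))
    list(reg = reg, emb = emb, mat = mat)
  })
}

test_that("an imputer can overfit a single training entity", {
  s <- tiny_imputer_setup()
  m <- build_imputer("DSIE", 4, 6, hidden_dims = c(16, 12, 8), seed = 1,
                     dropout_rate = 0)
  cfg <- imputer_train_config(learning_rate = 0.05, max_epochs = 300,
                              val_fraction = 0, weight_decay = 0,
                              ema_decay = 0, seed = 1)
  m <- train_imputer(m, s$emb, s$mat, s$reg$ids[1], cfg)
  pred <- impute(m, s$emb$values[1, ])
  expect_lt(max(abs(pred - s$mat$values[1, ])), 0.1)
})

test_that("zero-epoch training leaves the model unchanged with empty history", {
  s <- tiny_imputer_setup()
  m <- build_imputer("DSIE", 4, 6, hidden_dims = c(5, 4, 3), seed = 2)
  out <- train_imputer(m, s$emb, s$mat, s$reg$ids,
                       imputer_train_config(max_epochs = 0))
  expect_identical(out$params, m$params)
  expect_equal(nrow(out$history), 0L)
  expect_error(train_imputer(m, s$emb, s$mat, character(0)), "empty")
})

test_that("training is deterministic under a fixed seed", {
  s <- tiny_imputer_setup()
  cfg <- imputer_train_config(learning_rate = 1e-2, max_epochs = 20, seed = 9)
  m1 <- train_imputer(build_imputer("DSIE", 4, 6, hidden_dims = c(8, 6, 4), seed = 5),
                      s$emb, s$mat, s$reg$ids, cfg)
  m2 <- train_imputer(build_imputer("DSIE", 4, 6, hidden_dims = c(8, 6, 4), seed = 5),
                      s$emb, s$mat, s$reg$ids, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("imputation is zero-masked: true association rows are never read", {
  s <- tiny_imputer_setup()
  cfg <- imputer_train_config(learning_rate = 1e-2, max_epochs = 30, seed = 4)
  m <- train_imputer(build_imputer("DSIE", 4, 6, hidden_dims = c(8, 6, 4), seed = 5),
                     s$emb, s$mat, s$reg$ids[1:8], cfg)
  target <- s$reg$ids[9]
  before <- impute(m, s$emb$values[target, ])
  # corrupt the held-out entity's true row; the imputation must not move
  s$mat$values[target, ] <- 1 - s$mat$values[target, ]
  after <- impute(m, s$emb$values[target, ])
  expect_identical(before, after)
  expect_true(all(before >= 0 & before <= 1))
  expect_length(before, 6L)
  expect_error(impute(m, rnorm(3)), "width")
})

test_that("a zero embedding gives the model's constant bias response", {
  m <- build_imputer("DSIE", 4, 6, hidden_dims = c(8, 6, 4), seed = 5)
  p1 <- impute(m, rep(0, 4))
  p2 <- impute(m, rep(0, 4))
  expect_identical(p1, p2)
})

test_that("dropout perturbs training-mode forwards but never inference", {
  m <- build_imputer("DSIE", 4, 6, hidden_dims = c(8, 6, 4), seed = 5,
                     dropout_rate = 0.5)
  X <- cbind(matrix(rnorm(8), 2, 4), matrix(0, 2, 6))
  set.seed(1)
  tr1 <- hetdti:::.imputer_fwd(m, X, training = TRUE)$out
  tr2 <- hetdti:::.imputer_fwd(m, X, training = TRUE)$out
  expect_false(identical(tr1, tr2))
  inf1 <- hetdti:::.imputer_fwd(m, X)$out
  inf2 <- hetdti:::.imputer_fwd(m, X)$out
  expect_identical(inf1, inf2)
})

test_that("reconstruction AUC scores perfect, constant and hand cases correctly", {
  s <- tiny_imputer_setup()
  m <- build_imputer("DSIE", 4, 6, hidden_dims = c(8, 6, 4), seed = 5)
  held <- s$reg$ids[1:3]
  # a perfect imputer (scores equal the truth) ranks at AUC 1
  truth <- as.vector(s$mat$values[1:3, ])
  expect_equal(roc_auc(truth, truth), 1)
  # constant scores give AUC 0.5 (all ties)
  expect_equal(roc_auc(rep(0.3, length(truth)), truth), 0.5)
  # the hand case: truths [1,0,1,0], scores [.9,.8,.7,.1] -> 3 of 4 pairs concordant
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  # single-class held-out rows are excluded with a warning
  s$mat$values[2, ] <- 0
  expect_warning(r <- reconstruction_auc(m, s$emb, s$mat, held), "single-class")
  expect_false("D002" %in% r$per_row$id)
  expect_equal(r$excluded, "D002")
})

test_that("held-out reconstruction recovers planted logistic structure", {
  # ~100 entities, 50 columns: rows are Bernoulli draws on a logistic link
  # of the embedding (no extra latent noise), the regime an imputer must master
  n <- 100; d <- 8; k <- 50
  hetdti:::.local_seed(13, {
    reg <- tiny_registry(n, "drug", "D")
    E <- matrix(rnorm(n * d), n, d)
    W <- matrix(rnorm(d * k), d, k)
    P <- hetdti:::.sigmoid(3 * E %*% W / sqrt(d) - 1)
    R <- matrix(rbinom(n * k, 1, as.vector(P)), n, k)
    emb <- embedding_table(reg, E)
    mat <- hetero_matrix("DSIE", reg, tiny_registry(k, "side_effect", "S"), R)
    held <- reg$ids[1:20]
    m <- fit_imputer("DSIE", emb, mat, setdiff(reg$ids, held),
                     cfg = imputer_train_config(learning_rate = 1e-2,
                                                max_epochs = 300, patience = 50,
                                                weight_decay = 1e-3, seed = 1),
                     n_models = 2, hidden_dims = c(64, 32, 16), dropout_rate = 0)
    r <- suppressWarnings(reconstruction_auc(m, emb, mat, held))
    expect_gt(r$auc, 0.8)
  })
})
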