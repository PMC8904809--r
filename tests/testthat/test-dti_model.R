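# Independent dense-algebra oracle for the residual block and the full
# forward pass, coded per-vector with explicit loops (no shared code with
# the implementation's batched path).
oracle_layernorm <- function(z, gain, bias, eps) {
  mu <- mean(z)
  v <- mean((z - mu)^2)  # population (biased) variance
  gain * (z - mu) / sqrt(v + eps) + bias
}

oracle_block <- function(x, p) {
  a <- as.vector(t(p$W1) %*% x) + p$b1
  r1 <- pmax(oracle_layernorm(a, p$g1, p$n1, p$eps), 0)
  f <- as.vector(t(p$W2) %*% r1) + p$b2
  skip <- as.vector(t(p$W3) %*% x) + p$b3
  pmax(oracle_layernorm(f + p$lambda * skip, p$g2, p$n2, p$eps), 0)
}

oracle_forward <- function(model, x) {
  h <- x
  for (b in model$blocks) h <- oracle_block(h, b)
  cls <- model$classifier
  for (j in seq_len(model$config$n_classifier_hidden)) {
    h <- pmax(as.vector(t(cls[[j]]$W) %*% h) + cls[[j]]$b, 0)
  }
  1 / (1 + exp(-(sum(cls$out$W * h) + cls$out$b)))
}

test_that("the residual block reproduces the hand-computed example", {
  p <- residual_block_params(2, 2, 2, seed = 1, eps = 1e-5)
  p$W1 <- diag(2); p$W2 <- diag(2); p$W3 <- diag(2)
  p$b1[] <- 0; p$b2[] <- 0; p$b3[] <- 0
  # x=[1,-1] -> LN -> [1,-1] -> ReLU -> [1,0] -> +x = [2,-1] -> LN -> [1,-1] -> ReLU -> [1,0]
  expect_equal(residual_block_forward(c(1, -1), p), c(1, 0), tolerance = 1e-4)
})

test_that("zeroed weights and biases give a zero block output", {
  p <- residual_block_params(3, 4, 2, seed = 2)
  for (k in c("W1", "b1", "W2", "b2", "W3", "b3", "g1", "n1", "g2", "n2")) p[[k]][] <- 0
  expect_equal(residual_block_forward(c(1, 2, 3), p), c(0, 0))
})

test_that("block and full forward match the independent oracle on random instances", {
  set.seed(5)
  for (i in 1:100) {
    M <- sample(3:7, 1); M1 <- sample(2:6, 1); M2 <- sample(2:6, 1)
    p <- residual_block_params(M, M1, M2, seed = i)
    x <- rnorm(M)
    expect_equal(residual_block_forward(x, p), oracle_block(x, p),
                 tolerance = 1e-5)
  }
  for (i in 1:30) {
    M <- sample(4:8, 1)
    cfg <- dti_config(n_residual_blocks = sample(1:3, 1),
                      n_classifier_hidden = sample(1:3, 1),
                      m1 = sample(3:6, 1), m2 = sample(3:6, 1),
                      classifier_width = sample(3:6, 1), seed = i)
    m <- build_dti_model(M, cfg)
    x <- rnorm(M)
    expect_equal(predict_dti(m, x), oracle_forward(m, x), tolerance = 1e-5)
  }
})

test_that("probabilities are bounded, 0.5 at zero weights, and monotone in the logit", {
  cfg <- dti_config(m1 = 4, m2 = 3, classifier_width = 3, seed = 1)
  m <- build_dti_model(5, cfg)
  # zero weights throughout -> sigmoid(0) = 0.5
  z <- m
  for (b in seq_along(z$blocks)) for (k in names(z$blocks[[b]])) {
    if (is.numeric(z$blocks[[b]][[k]]) && k %in% c("W1","b1","W2","b2","W3","b3","g1","n1","g2","n2"))
      z$blocks[[b]][[k]][] <- 0
  }
  for (h in seq_len(z$config$n_classifier_hidden)) {
    z$classifier[[h]]$W[] <- 0; z$classifier[[h]]$b[] <- 0
  }
  z$classifier$out$W[] <- 0; z$classifier$out$b[] <- 0
  expect_equal(predict_dti(z, rnorm(5)), 0.5)
  # raising the output bias raises the probability
  z$classifier$out$b[] <- 2
  expect_gt(predict_dti(z, rnorm(5)), 0.5)
  set.seed(8)
  X <- matrix(rnorm(50 * 5), 50, 5)
  pr <- predict_dti(m, X)
  expect_true(all(pr > 0 & pr < 1))
  expect_error(predict_dti(m, rnorm(4)), "width")
})

test_that("binary cross-entropy matches its closed form", {
  expect_equal(bce_loss(1, 1), 0, tolerance = 1e-6)
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(0.5, 0), log(2))  # label symmetry at 0.5
  expect_equal(bce_loss(c(0.8, 0.3), c(1, 0)),
               mean(-c(log(0.8), log(0.7))))
  expect_error(bce_loss(c(0.5, 0.5), 1), "length")
  expect_true(is.finite(bce_loss(c(0, 1), c(1, 0))))  # clamped at 1e-7
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  cfg <- dti_config(n_residual_blocks = 2, n_classifier_hidden = 2,
                    m1 = 5, m2 = 4, classifier_width = 3, seed = 3)
  m <- build_dti_model(6, cfg)
  X <- matrix(rnorm(7 * 6), 7, 6)
  y <- rbinom(7, 1, 0.5)
  g <- hetdti:::.model_flat(m, hetdti:::.model_bwd(m, hetdti:::.model_fwd(m, X), y))
  params <- hetdti:::.model_flat(m)
  loss_at <- function(pl) {
    bce_loss(hetdti:::.model_fwd(hetdti:::.model_unflat(m, pl), X)$prob, y)
  }
  eps <- 1e-6
  for (k in names(params)) {
    for (i in sample(length(params[[k]]), min(2, length(params[[k]])))) {
      up <- params; up[[k]][i] <- up[[k]][i] + eps
      dn <- params; dn[[k]][i] <- dn[[k]][i] - eps
      expect_equal((loss_at(up) - loss_at(dn)) / (2 * eps), g[[k]][i],
                   tolerance = 1e-4)
    }
  }
})

make_separable <- function(n = 300, d = 10, seed = 6) {
  hetdti:::.local_seed(seed, {
    X <- matrix(rnorm(n * d), n, d)
    w <- rnorm(d)
    y <- as.integer(X %*% w > 0)
    list(X = X, y = y)
  })
}

test_that("training reduces loss on separable data and is deterministic", {
  dat <- make_separable()
  idx <- 1:240
  cfg <- dti_config(m1 = 16, m2 = 8, classifier_width = 8,
                    learning_rate = 1e-2, batch_size = 64,
                    max_epochs = 50, patience = 50, seed = 2)
  m <- build_dti_model(10, cfg)
  fit <- train_dti(m, dat$X[idx, ], dat$y[idx], dat$X[-idx, ], dat$y[-idx])
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_gt(roc_auc(predict_dti(fit, dat$X[-idx, ]), dat$y[-idx]), 0.9)
  fit2 <- train_dti(build_dti_model(10, cfg), dat$X[idx, ], dat$y[idx],
                    dat$X[-idx, ], dat$y[-idx])
  expect_identical(fit$history, fit2$history)
  expect_equal(predict_dti(fit, dat$X[1:5, ]), predict_dti(fit2, dat$X[1:5, ]))
  expect_error(train_dti(m, dat$X[idx, ], dat$y[idx],
                         dat$X[0, , drop = FALSE], integer(0)), "non-empty")
})

test_that("early stopping respects patience and restores the best epoch", {
  dat <- make_separable(n = 100)
  cfg <- dti_config(m1 = 8, m2 = 4, classifier_width = 4,
                    learning_rate = 1, batch_size = 100,  # divergent lr
                    max_epochs = 50, patience = 1, seed = 3)
  m <- build_dti_model(10, cfg)
  fit <- train_dti(m, dat$X[1:80, ], dat$y[1:80], dat$X[81:100, ], dat$y[81:100])
  h <- fit$history
  best_epoch <- which.min(h$val_loss)
  # stopped one epoch (patience=1) after the last improvement
  expect_lte(nrow(h), 50)
  # restored weights reproduce the best validation loss, not the last
  expect_equal(bce_loss(predict_dti(fit, dat$X[81:100, ]), dat$y[81:100]),
               min(h$val_loss), tolerance = 1e-9)
})

test_that("same-seed weight initialization is identical", {
  cfg <- dti_config(m1 = 6, m2 = 4, classifier_width = 4, seed = 9)
  expect_identical(build_dti_model(7, cfg), build_dti_model(7, cfg))
  p1 <- residual_block_params(4, 3, 2, seed = 11)
  p2 <- residual_block_params(4, 3, 2, seed = 11)
  expect_identical(p1, p2)
})

test_that("disabling the residual stack yields the plain two-hidden-layer baseline", {
  cfg <- dti_config(use_residual = FALSE, n_classifier_hidden = 2,
                    classifier_width = 8, seed = 4)
  m <- build_dti_model(12, cfg)
  expect_length(m$blocks, 0)
  expect_equal(dim(m$classifier[[1]]$W), c(12L, 8L))  # classifier sees raw input
  expect_equal(dim(m$classifier[[2]]$W), c(8L, 8L))
  x <- rnorm(12)
  h <- pmax(as.vector(t(m$classifier[[1]]$W) %*% x) + m$classifier[[1]]$b, 0)
  h <- pmax(as.vector(t(m$classifier[[2]]$W) %*% h) + m$classifier[[2]]$b, 0)
  expect_equal(predict_dti(m, x),
               1 / (1 + exp(-(sum(m$classifier$out$W * h) + m$classifier$out$b))))
})

test_that("grid search enumerates the lattice and breaks ties deterministically", {
  dat <- make_separable(n = 120, d = 6)
  base <- dti_config(m1 = 6, m2 = 4, classifier_width = 4, batch_size = 60,
                     max_epochs = 3, patience = 3, seed = 5)
  # single point -> that point returned
  g1 <- grid_search_dti(dat$X[1:90, ], dat$y[1:90], dat$X[91:120, ], dat$y[91:120],
                        base, blocks = 2, hidden_layers = 1, learning_rates = 1e-3)
  expect_equal(g1$best_config$n_residual_blocks, 2L)
  expect_equal(nrow(g1$results), 1L)
  # the standard lattice has 3 x 3 x 6 = 54 points (enumerated lazily here
  # with a 2 x 2 x 2 sub-lattice to keep the test fast)
  g2 <- grid_search_dti(dat$X[1:90, ], dat$y[1:90], dat$X[91:120, ], dat$y[91:120],
                        base, blocks = 1:2, hidden_layers = 1:2,
                        learning_rates = c(1e-3, 1e-2))
  expect_equal(nrow(g2$results), 8L)
  expect_equal(g2$results$n_residual_blocks[1:4], c(1L, 1L, 1L, 1L))
  # tie rule: first point in enumeration order wins
  best_auc <- max(g2$results$val_auc)
  first_best <- which(g2$results$val_auc == best_auc)[1]
  expect_equal(g2$best_config$n_residual_blocks,
               g2$results$n_residual_blocks[first_best])
  expect_equal(g2$best_config$learning_rate, g2$results$learning_rate[first_best])
})
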