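# The residual DTI classifier. A pair vector x = [D_drug; P_protein] is
# passed through a stack of layer-normalized residual blocks
#   y = ReLU(LayerNorm(W2 ReLU(LayerNorm(W1 x)) + lambda * W3 x))
# (lambda fixed to 1; W3 projects the skip path so the block also
# performs feature reduction), then through a small ReLU classifier with
# a single sigmoid output unit. Weight matrices are stored input x output
# so the batched forward pass is X %*% W.

#' Residual block parameters
#'
#' Builds one block with deterministic seeded initialization. Shapes:
#' `W1` is `M x M1`, `W2` is `M1 x M2`, `W3` is `M x M2` (input x output
#' convention); both layer norms carry learnable gain (init 1) and bias
#' (init 0). `lambda` scales the skip path and is fixed to 1, the setting
#' that keeps the skip gradient well-behaved.
#'
#' @param input_dim block input width M.
#' @param m1,m2 inner and output widths M1, M2.
#' @param seed integer seed.
#' @param eps layer-norm variance floor.
#' @return A named list of block parameters.
#' @export
residual_block_params <- function(input_dim, m1, m2, seed = 1L, eps = 1e-5) {
  stopifnot(input_dim >= 1, m1 >= 1, m2 >= 1, eps > 0)
  .local_seed(seed, {
    d1 <- .init_dense(input_dim, m1)
    d2 <- .init_dense(m1, m2)
    d3 <- .init_dense(input_dim, m2)
    list(W1 = d1$W, b1 = d1$b, g1 = rep(1, m1), n1 = rep(0, m1),
         W2 = d2$W, b2 = d2$b, W3 = d3$W, b3 = d3$b,
         g2 = rep(1, m2), n2 = rep(0, m2), eps = eps, lambda = 1)
  })
}

# Forward through one block; returns caches for backprop.
.block_fwd <- function(X, p) {
  A <- .add_bias(X %*% p$W1, p$b1)
  ln1 <- .ln_fwd(A, p$g1, p$n1, p$eps)
  R1 <- .relu(ln1$Y)
  f <- .add_bias(R1 %*% p$W2, p$b2)
  skip <- .add_bias(X %*% p$W3, p$b3)
  S <- f + p$lambda * skip
  ln2 <- .ln_fwd(S, p$g2, p$n2, p$eps)
  Y <- .relu(ln2$Y)
  list(X = X, ln1 = ln1, R1 = R1, ln2 = ln2, Y = Y)
}

.block_bwd <- function(dY, cache, p) {
  dL2 <- dY * (cache$ln2$Y > 0)
  b2_ <- .ln_bwd(dL2, cache$ln2, p$g2)
  dS <- b2_$dZ
  g <- list(g2 = b2_$dgain, n2 = b2_$dbias)
  # skip path
  dskip <- p$lambda * dS
  g$W3 <- t(cache$X) %*% dskip
  g$b3 <- colSums(dskip)
  dX <- dskip %*% t(p$W3)
  # main path
  g$W2 <- t(cache$R1) %*% dS
  g$b2 <- colSums(dS)
  dR1 <- dS %*% t(p$W2)
  dL1 <- dR1 * (cache$ln1$Y > 0)
  b1_ <- .ln_bwd(dL1, cache$ln1, p$g1)
  g$g1 <- b1_$dgain
  g$n1 <- b1_$dbias
  g$W1 <- t(cache$X) %*% b1_$dZ
  g$b1 <- colSums(b1_$dZ)
  dX <- dX + b1_$dZ %*% t(p$W1)
  list(grads = g, dX = dX)
}

#' Residual block forward pass
#'
#' Computes `y = ReLU(LayerNorm(W2 ReLU(LayerNorm(W1 x)) + lambda W3 x))`
#' with population-variance layer normalization over the feature axis.
#'
#' @param x numeric vector of length M, or a matrix with one sample per row.
#' @param params a block parameter list from [residual_block_params()].
#' @return A vector of length M2 (or matrix of such rows).
#' @export
residual_block_forward <- function(x, params) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != nrow(params$W1)) {
    stop(sprintf("input width %d does not match block input width %d",
                 ncol(X), nrow(params$W1)))
  }
  Y <- .block_fwd(X, params)$Y
  if (is.matrix(x)) Y else as.vector(Y)
}

#' Model configuration and hyperparameter grid values
#'
#' The tuned hyperparameters are the number of residual blocks (1-3), the
#' number of classifier hidden layers (1-3) and the Adam learning rate
#' (1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1); defaults follow that grid's
#' smallest-capacity corner with the reference initial learning rate
#' 1e-5. `use_residual = FALSE` bypasses the residual stack entirely and
#' feeds the raw pair vector to the classifier, which with two hidden
#' layers is the embeddings-only baseline architecture.
#'
#' @param n_residual_blocks number of stacked residual blocks.
#' @param n_classifier_hidden number of classifier hidden layers.
#' @param learning_rate Adam learning rate.
#' @param m1,m2 residual block inner/output widths (blocks after the
#'   first take the previous block's M2-wide output).
#' @param classifier_width width of each classifier hidden layer.
#' @param batch_size mini-batch size (default 512).
#' @param max_epochs,patience early-stopping budget: training stops when
#'   validation loss has not improved for `patience` epochs.
#' @param seed RNG seed (weights and shuffling).
#' @param use_residual logical; FALSE removes the residual stack.
#' @param eps layer-norm variance floor.
#' @param feature_config optional [feature_config()] recorded with the model.
#' @return An object of class `dti_config`.
#' @export
dti_config <- function(n_residual_blocks = 1L, n_classifier_hidden = 1L,
                       learning_rate = 1e-5, m1 = 1024L, m2 = 512L,
                       classifier_width = 512L, batch_size = 512L,
                       max_epochs = 300L, patience = 10L, seed = 1L,
                       use_residual = TRUE, eps = 1e-5,
                       feature_config = NULL) {
  stopifnot(n_residual_blocks >= 1, n_classifier_hidden >= 1,
            learning_rate > 0, batch_size >= 1, patience >= 1, eps > 0)
  structure(list(n_residual_blocks = as.integer(n_residual_blocks),
                 n_classifier_hidden = as.integer(n_classifier_hidden),
                 learning_rate = learning_rate, m1 = as.integer(m1),
                 m2 = as.integer(m2),
                 classifier_width = as.integer(classifier_width),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 use_residual = isTRUE(use_residual), eps = eps,
                 feature_config = feature_config),
            class = "dti_config")
}

#' Build the residual DTI classifier
#'
#' @param input_dim width of the concatenated pair vector `[D; P]`.
#' @param config a [dti_config()].
#' @return An object of class `dti_model`.
#' @export
build_dti_model <- function(input_dim, config = dti_config()) {
  stopifnot(input_dim >= 1)
  blocks <- list()
  cls_in <- input_dim
  if (config$use_residual) {
    d <- input_dim
    for (b in seq_len(config$n_residual_blocks)) {
      blocks[[b]] <- residual_block_params(d, config$m1, config$m2,
                                           seed = config$seed + b, eps = config$eps)
      d <- config$m2
    }
    cls_in <- config$m2
  }
  classifier <- .local_seed(config$seed + 1000L, {
    layers <- list()
    d <- cls_in
    for (h in seq_len(config$n_classifier_hidden)) {
      layers[[h]] <- .init_dense(d, config$classifier_width)
      d <- config$classifier_width
    }
    layers$out <- .init_dense(d, 1L)
    layers
  })
  structure(list(input_dim = as.integer(input_dim), config = config,
                 blocks = blocks, classifier = classifier, trained = FALSE),
            class = "dti_model")
}

#' @export
print.dti_model <- function(x, ...) {
  cat(sprintf("<dti_model> input %d | %s | %d classifier hidden layer(s)%s\n",
              x$input_dim,
              if (x$config$use_residual)
                sprintf("%d residual block(s) (M1=%d, M2=%d)",
                        x$config$n_residual_blocks, x$config$m1, x$config$m2)
              else "no residual stack",
              x$config$n_classifier_hidden,
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

.model_fwd <- function(model, X) {
  caches <- list(blocks = list())
  A <- X
  for (b in seq_along(model$blocks)) {
    c_ <- .block_fwd(A, model$blocks[[b]])
    caches$blocks[[b]] <- c_
    A <- c_$Y
  }
  cls <- model$classifier
  nh <- model$config$n_classifier_hidden
  caches$cls_in <- A
  caches$Z <- list()
  caches$H <- list()
  for (h in seq_len(nh)) {
    Z <- .add_bias(A %*% cls[[h]]$W, cls[[h]]$b)
    A2 <- .relu(Z)
    caches$Z[[h]] <- Z
    caches$H[[h]] <- A2
    A <- A2
  }
  logit <- .add_bias(A %*% cls$out$W, cls$out$b)
  caches$logit <- as.vector(logit)
  caches$prob <- .sigmoid(caches$logit)
  caches
}

.model_bwd <- function(model, caches, labels) {
  n <- length(labels)
  dlogit <- matrix((caches$prob - labels) / n, ncol = 1)
  cls <- model$classifier
  nh <- model$config$n_classifier_hidden
  g <- list(classifier = vector("list", nh), blocks = list())
  Alast <- if (nh >= 1) caches$H[[nh]] else caches$cls_in
  g$out <- list(W = t(Alast) %*% dlogit, b = colSums(dlogit))
  dA <- dlogit %*% t(cls$out$W)
  for (h in rev(seq_len(nh))) {
    dZ <- dA * (caches$Z[[h]] > 0)
    Aprev <- if (h == 1) caches$cls_in else caches$H[[h - 1]]
    g$classifier[[h]] <- list(W = t(Aprev) %*% dZ, b = colSums(dZ))
    dA <- dZ %*% t(cls[[h]]$W)
  }
  for (b in rev(seq_along(model$blocks))) {
    bk <- .block_bwd(dA, caches$blocks[[b]], model$blocks[[b]])
    g$blocks[[b]] <- bk$grads
    dA <- bk$dX
  }
  g
}

# Flatten model parameters (and matching gradients) for Adam.
.model_flat <- function(model, grads = NULL) {
  params <- list()
  for (b in seq_along(model$blocks)) {
    src <- if (is.null(grads)) model$blocks[[b]] else grads$blocks[[b]]
    for (k in c("W1", "b1", "g1", "n1", "W2", "b2", "W3", "b3", "g2", "n2")) {
      params[[sprintf("blk%d_%s", b, k)]] <- src[[k]]
    }
  }
  nh <- model$config$n_classifier_hidden
  for (h in seq_len(nh)) {
    src <- if (is.null(grads)) model$classifier[[h]] else grads$classifier[[h]]
    params[[sprintf("cls%d_W", h)]] <- src$W
    params[[sprintf("cls%d_b", h)]] <- src$b
  }
  src <- if (is.null(grads)) model$classifier$out else grads$out
  params$out_W <- src$W
  params$out_b <- src$b
  params
}

.model_unflat <- function(model, params) {
  for (b in seq_along(model$blocks)) {
    for (k in c("W1", "b1", "g1", "n1", "W2", "b2", "W3", "b3", "g2", "n2")) {
      model$blocks[[b]][[k]] <- params[[sprintf("blk%d_%s", b, k)]]
    }
  }
  for (h in seq_len(model$config$n_classifier_hidden)) {
    model$classifier[[h]]$W <- params[[sprintf("cls%d_W", h)]]
    model$classifier[[h]]$b <- as.vector(params[[sprintf("cls%d_b", h)]])
  }
  model$classifier$out$W <- params$out_W
  model$classifier$out$b <- as.vector(params$out_b)
  model
}

#' Predict interaction probabilities
#'
#' Chains the residual blocks (when enabled), the classifier hidden
#' layers and the final sigmoid unit.
#'
#' @param model a [build_dti_model()] model.
#' @param x numeric vector (one pair) or matrix (one pair per row).
#' @param ... unused.
#' @return Probabilities in (0, 1), one per input row.
#' @export
predict_dti <- function(model, x, ...) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != model$input_dim) {
    stop(sprintf("input width %d does not match model input width %d",
                 ncol(X), model$input_dim))
  }
  .model_fwd(model, X)$prob
}

#' @export
predict.dti_model <- function(object, newdata, ...) predict_dti(object, newdata, ...)

#' Train the DTI classifier
#'
#' Minimizes binary cross-entropy with Adam on seeded shuffled
#' mini-batches. Training stops when the validation loss fails to improve
#' for `patience` consecutive epochs; the best-validation weights are
#' restored. The returned history records per-epoch training loss,
#' validation loss and validation ROC AUC.
#'
#' @param model a [build_dti_model()] model.
#' @param x_train,y_train training pair matrix and 0/1 labels.
#' @param x_val,y_val validation pair matrix and labels (must be
#'   non-empty; early stopping is undefined otherwise).
#' @param config optional [dti_config()] override (defaults to the
#'   model's own config).
#' @return The trained model with a `history` data.frame.
#' @export
train_dti <- function(model, x_train, y_train, x_val, y_val, config = NULL) {
  cfg <- if (is.null(config)) model$config else config
  if (is.null(x_val) || nrow(x_val) == 0L) stop("validation set must be non-empty")
  stopifnot(nrow(x_train) == length(y_train), nrow(x_val) == length(y_val))
  if (nrow(x_train) == 0L) stop("training set must be non-empty")
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_auc = numeric(0))
  model <- .local_seed(cfg$seed, {
    params <- .model_flat(model)
    opt <- .adam_new(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    stale <- 0L
    n <- nrow(x_train)
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        Xb <- x_train[bi, , drop = FALSE]
        yb <- y_train[bi]
        caches <- .model_fwd(model, Xb)
        g <- .model_bwd(model, caches, yb)
        st <- .adam_step(opt, params, .model_flat(model, g), cfg$learning_rate)
        opt <- st$state
        params <- st$params
        model <- .model_unflat(model, params)
        pc <- pmin(pmax(caches$prob, 1e-7), 1 - 1e-7)
        ep_loss <- ep_loss - sum(yb * log(pc) + (1 - yb) * log(1 - pc))
      }
      vp <- .model_fwd(model, x_val)$prob
      vl <- bce_loss(vp, y_val)
      va <- if (length(unique(y_val)) == 2L) roc_auc(vp, y_val) else NA_real_
      history[nrow(history) + 1L, ] <- list(epoch, ep_loss / n, vl, va)
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, params = params, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      if (stale >= cfg$patience) break
    }
    .model_unflat(model, best$params)
  })
  model$trained <- TRUE
  model$history <- history
  model
}

#' Grid search over the model hyperparameters
#'
#' Trains one model per lattice point (blocks x classifier hidden layers
#' x learning rate, enumerated in that nesting order) and selects the
#' configuration with the highest validation ROC AUC; ties go to the
#' earliest point in enumeration order.
#'
#' @param x_train,y_train,x_val,y_val as in [train_dti()].
#' @param base_config a [dti_config()] supplying all non-grid settings.
#' @param blocks,hidden_layers,learning_rates grid values.
#' @return A list: `best_config`, `best_model`, and `results` (one row
#'   per lattice point with its validation AUC and loss).
#' @export
grid_search_dti <- function(x_train, y_train, x_val, y_val,
                            base_config = dti_config(),
                            blocks = 1:3, hidden_layers = 1:3,
                            learning_rates = c(1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1)) {
  stopifnot(length(blocks) >= 1, length(hidden_layers) >= 1,
            length(learning_rates) >= 1)
  results <- data.frame(n_residual_blocks = integer(0),
                        n_classifier_hidden = integer(0),
                        learning_rate = numeric(0),
                        val_auc = numeric(0), val_loss = numeric(0))
  best <- list(auc = -Inf, config = NULL, model = NULL)
  for (nb in blocks) for (nh in hidden_layers) for (lr in learning_rates) {
    cfg <- base_config
    cfg$n_residual_blocks <- as.integer(nb)
    cfg$n_classifier_hidden <- as.integer(nh)
    cfg$learning_rate <- lr
    m <- build_dti_model(ncol(x_train), cfg)
    m <- train_dti(m, x_train, y_train, x_val, y_val)
    vp <- predict_dti(m, x_val)
    va <- roc_auc(vp, y_val)
    results[nrow(results) + 1L, ] <- list(nb, nh, lr, va, bce_loss(vp, y_val))
    if (va > best$auc) best <- list(auc = va, config = cfg, model = m)
  }
  list(best_config = best$config, best_model = best$model, results = results)
}
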