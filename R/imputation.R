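# Feed-forward imputers that complete a heterogeneous association vector
# for an entity missing from training. Each imputer is an autoencoder-like
# predictor: during training the input is [embedding; true association
# row] and the target is the same association row; at prediction time the
# association part of the input is zero-masked, so the output depends on
# the embedding alone.

#' Build an association-vector imputer
#'
#' Constructs the feed-forward predictor for one association block
#' (DDI, DSIE, DDIS or PDIS): input `[embedding; association row]`, three
#' ReLU hidden layers with dropout, and a sigmoid output of the block
#' width. Default hidden dimensions follow the reference architecture:
#' `c(1024, 512, 128)` for DDI and `c(4096, 2048, 1024)` for the others.
#'
#' @param target one of `"DDI"`, `"DSIE"`, `"DDIS"`, `"PDIS"`.
#' @param embedding_dim width of the entity embedding.
#' @param target_dim width of the association row to reconstruct.
#' @param hidden_dims three positive integers.
#' @param seed integer seed for the deterministic weight initialization.
#' @param dropout_rate dropout probability applied after each hidden
#'   layer during training (default 0.5).
#' @return An object of class `imputer_model`.
#' @export
build_imputer <- function(target = c("DDI", "DSIE", "DDIS", "PDIS"),
                          embedding_dim, target_dim,
                          hidden_dims = NULL, seed = 1L, dropout_rate = 0.5) {
  target <- match.arg(target)
  if (is.null(hidden_dims)) {
    hidden_dims <- if (target == "DDI") c(1024L, 512L, 128L) else c(4096L, 2048L, 1024L)
  }
  if (length(hidden_dims) != 3L) stop("exactly three hidden layers are required")
  dims <- c(embedding_dim + target_dim, hidden_dims, target_dim)
  if (embedding_dim <= 0 || target_dim <= 0 || any(dims <= 0)) {
    stop("all layer dimensions must be positive")
  }
  params <- .local_seed(seed, {
    p <- list()
    for (l in 1:4) {
      d <- .init_dense(dims[l], dims[l + 1])
      p[[paste0("W", l)]] <- d$W
      p[[paste0("b", l)]] <- d$b
    }
    p
  })
  structure(list(target = target, embedding_dim = as.integer(embedding_dim),
                 target_dim = as.integer(target_dim),
                 hidden_dims = as.integer(hidden_dims),
                 dropout_rate = dropout_rate, seed = as.integer(seed),
                 params = params, trained = FALSE),
            class = "imputer_model")
}

#' @export
print.imputer_model <- function(x, ...) {
  cat(sprintf("<imputer_model> F_%s: %d -> %s -> %d%s\n", x$target,
              x$embedding_dim + x$target_dim,
              paste(x$hidden_dims, collapse = "/"), x$target_dim,
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

# Forward pass; when training=TRUE, dropout masks are drawn from the
# current RNG stream and the layer caches are returned for backprop.
.imputer_fwd <- function(model, X, training = FALSE) {
  p <- model$params
  dr <- model$dropout_rate
  cache <- list(X = X)
  A <- X
  for (l in 1:3) {
    Z <- .add_bias(A %*% p[[paste0("W", l)]], p[[paste0("b", l)]])
    H <- .relu(Z)
    if (training && dr > 0) {
      M <- .dropout_mask(nrow(H), ncol(H), dr)
      H <- H * M
      cache[[paste0("M", l)]] <- M
    }
    cache[[paste0("Z", l)]] <- Z
    cache[[paste0("H", l)]] <- H
    A <- H
  }
  out <- .sigmoid(.add_bias(A %*% p$W4, p$b4))
  cache$out <- out
  cache
}

.imputer_bwd <- function(model, cache, targets) {
  p <- model$params
  n <- nrow(targets)
  g <- list()
  # mean BCE over all cells; sigmoid + BCE collapses to (out - t) / N
  dZ4 <- (cache$out - targets) / (n * ncol(targets))
  g$W4 <- t(cache$H3) %*% dZ4
  g$b4 <- colSums(dZ4)
  dH <- dZ4 %*% t(p$W4)
  for (l in 3:1) {
    M <- cache[[paste0("M", l)]]
    if (!is.null(M)) dH <- dH * M
    dZ <- dH * (cache[[paste0("Z", l)]] > 0)
    Aprev <- if (l == 1) cache$X else cache[[paste0("H", l - 1)]]
    g[[paste0("W", l)]] <- t(Aprev) %*% dZ
    g[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1) dH <- dZ %*% t(p[[paste0("W", l)]])
  }
  g
}

#' Imputer training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param max_epochs maximum training epochs.
#' @param batch_size mini-batch size.
#' @param val_fraction fraction of training entities held out for early
#'   stopping (0 disables early stopping). Validation loss is computed
#'   zero-masked (input `[embedding; zeros]`), i.e. under the same
#'   conditions the imputer is used in, so early stopping tracks
#'   imputation quality rather than the trivial copy of the input row.
#' @param patience epochs without validation improvement before stopping.
#' @param weight_decay L2 penalty on the weight matrices (not biases);
#'   the small-sample regularizer that keeps the imputer from memorizing
#'   individual training rows.
#' @param ema_decay decay of the exponential moving average of the
#'   weights (per mini-batch); the averaged weights are what the trained
#'   model keeps, which substantially stabilizes the imputed rankings.
#'   Set to 0 to keep the raw final weights.
#' @param seed RNG seed for shuffling, dropout and the validation slice.
#' @return An object of class `imputer_train_config`.
#' @export
imputer_train_config <- function(learning_rate = 1e-3, max_epochs = 200L,
                                 batch_size = 64L, val_fraction = 0.1,
                                 patience = 10L, weight_decay = 1e-3,
                                 ema_decay = 0.995, seed = 1L) {
  stopifnot(learning_rate > 0, patience >= 1, batch_size >= 1,
            val_fraction >= 0, val_fraction < 1, weight_decay >= 0,
            ema_decay >= 0, ema_decay < 1)
  structure(list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), val_fraction = val_fraction,
                 patience = as.integer(patience), weight_decay = weight_decay,
                 ema_decay = ema_decay, seed = as.integer(seed)),
            class = "imputer_train_config")
}

#' Train an imputer on seen entities
#'
#' Training inputs are `[embedding_i; association_row_i]` with the same
#' association row as the reconstruction target (element-wise binary
#' cross-entropy on the sigmoid outputs). Each entity is used once
#' (duplicates in `entity_subset` are dropped). Dropout is active only
#' here, never at prediction time. With `val_fraction > 0` a held-out
#' slice of the entities drives early stopping; the best-validation
#' weights are restored.
#'
#' @param model an untrained or trained [build_imputer()] model.
#' @param embeddings [embedding_table()] covering `entity_subset`.
#' @param matrix the [hetero_matrix()] whose rows are reconstructed.
#' @param entity_subset ids of the entities to train on (training-fold
#'   entities only, so unseen test entities never leak in).
#' @param cfg an [imputer_train_config()].
#' @return The trained model, with a `history` element (data.frame of
#'   per-epoch train/validation loss).
#' @export
train_imputer <- function(model, embeddings, matrix, entity_subset,
                          cfg = imputer_train_config()) {
  entity_subset <- unique(as.character(entity_subset))
  if (length(entity_subset) == 0L) stop("entity subset is empty")
  pos <- registry_pos(embeddings$registry, entity_subset)
  E <- embeddings$values[pos, , drop = FALSE]
  R <- matrix$values[registry_pos(matrix$rows, entity_subset), , drop = FALSE]
  if (ncol(E) != model$embedding_dim || ncol(R) != model$target_dim) {
    stop("embedding/matrix widths do not match the imputer dimensions")
  }
  X <- cbind(E, R)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_auc = numeric(0))
  if (cfg$max_epochs == 0L) {
    model$history <- history
    return(model)
  }
  model <- .local_seed(cfg$seed, {
    n <- nrow(X)
    n_val <- floor(cfg$val_fraction * n)
    val_idx <- if (n_val >= 1) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    opt <- .adam_new(model$params)
    best <- list(metric = -Inf, params = model$params, epoch = 0L)
    stale <- 0L
    use_ema <- cfg$ema_decay > 0
    ema <- model$params
    raw <- model$params
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        Xb <- X[bi, , drop = FALSE]
        Tb <- R[bi, , drop = FALSE]
        model$params <- raw
        cache <- .imputer_fwd(model, Xb, training = TRUE)
        g <- .imputer_bwd(model, cache, Tb)
        if (cfg$weight_decay > 0) {
          for (k in c("W1", "W2", "W3", "W4")) {
            g[[k]] <- g[[k]] + cfg$weight_decay * raw[[k]]
          }
        }
        st <- .adam_step(opt, raw, g, cfg$learning_rate)
        opt <- st$state
        raw <- st$params
        if (use_ema) {
          for (k in names(ema)) {
            ema[[k]] <- cfg$ema_decay * ema[[k]] + (1 - cfg$ema_decay) * raw[[k]]
          }
        }
        pc <- pmin(pmax(cache$out, 1e-7), 1 - 1e-7)
        ep_loss <- ep_loss + -sum(Tb * log(pc) + (1 - Tb) * log(1 - pc))
      }
      ep_loss <- ep_loss / (length(tr_idx) * ncol(R))
      model$params <- if (use_ema) ema else raw
      vl <- NA_real_
      va <- NA_real_
      if (length(val_idx) > 0) {
        # zero-masked validation: score the slice the way impute() will;
        # the selection metric is ranking quality (pooled AUC), since the
        # imputed vectors are consumed as relative scores, with BCE as
        # the fallback when the slice is single-class
        Xv <- cbind(E[val_idx, , drop = FALSE],
                    matrix(0, length(val_idx), model$target_dim))
        out <- .imputer_fwd(model, Xv)$out
        truth_v <- as.vector(R[val_idx, , drop = FALSE])
        vl <- bce_loss(as.vector(out), truth_v)
        metric <- if (all(truth_v == 0) || all(truth_v == 1)) -vl
                  else {
                    va <- roc_auc(as.vector(out), truth_v)
                    va
                  }
        if (metric > best$metric + 1e-9) {
          best <- list(metric = metric, params = model$params, epoch = epoch)
          stale <- 0L
        } else {
          stale <- stale + 1L
        }
      }
      history[nrow(history) + 1L, ] <- list(epoch, ep_loss, vl, va)
      if (length(val_idx) > 0 && stale >= cfg$patience) break
    }
    if (length(val_idx) > 0 && is.finite(best$metric)) model$params <- best$params
    model
  })
  model$trained <- TRUE
  model$history <- history
  model
}

#' Fit an ensemble of imputers
#'
#' Trains `n_models` imputers that differ only in their weight
#' initialization (seeds `cfg$seed`, `cfg$seed + 1000`, ...) and returns
#' an object whose [impute()] output is the average of the members'
#' predictions — a variance reduction that stabilizes the imputed
#' rankings at small sample sizes. With `n_models = 1` this is plain
#' [train_imputer()].
#'
#' @param target association block, see [build_imputer()].
#' @param embeddings,matrix,entity_subset,cfg as in [train_imputer()].
#' @param n_models ensemble size.
#' @param hidden_dims,dropout_rate forwarded to [build_imputer()].
#' @return An `imputer_model` (single) or `imputer_ensemble` (list of
#'   trained members).
#' @export
fit_imputer <- function(target, embeddings, matrix, entity_subset,
                        cfg = imputer_train_config(), n_models = 1L,
                        hidden_dims = NULL, dropout_rate = 0.5) {
  stopifnot(n_models >= 1)
  members <- lapply(seq_len(n_models), function(j) {
    cj <- cfg
    cj$seed <- cfg$seed + (j - 1L) * 1000L
    m <- build_imputer(target, embeddings$dim, ncol(matrix$values),
                       hidden_dims = hidden_dims, seed = cj$seed,
                       dropout_rate = dropout_rate)
    train_imputer(m, embeddings, matrix, entity_subset, cj)
  })
  if (n_models == 1L) return(members[[1L]])
  structure(list(target = target, members = members,
                 embedding_dim = members[[1]]$embedding_dim,
                 target_dim = members[[1]]$target_dim),
            class = "imputer_ensemble")
}

#' @export
print.imputer_ensemble <- function(x, ...) {
  cat(sprintf("<imputer_ensemble> F_%s, %d members\n", x$target,
              length(x$members)))
  invisible(x)
}

#' Impute an association vector from an embedding
#'
#' Runs the zero-masked forward pass: the input is
#' `[embedding; zeros(target_dim)]`, dropout is disabled, and the sigmoid
#' outputs in `[0, 1]` are returned as-is (not thresholded) for use as the
#' entity's feature block.
#'
#' @param model a trained [build_imputer()] model or a [fit_imputer()]
#'   ensemble (member predictions are averaged).
#' @param embedding numeric vector (one entity) or matrix (one entity per
#'   row) of width `embedding_dim`.
#' @return A vector (or matrix) of predicted association values of width
#'   `target_dim`.
#' @export
impute <- function(model, embedding) {
  if (inherits(model, "imputer_ensemble")) {
    preds <- lapply(model$members, impute, embedding = embedding)
    return(Reduce(`+`, preds) / length(preds))
  }
  E <- if (is.matrix(embedding)) embedding else matrix(embedding, nrow = 1)
  if (ncol(E) != model$embedding_dim) {
    stop(sprintf("embedding width %d does not match imputer embedding_dim %d",
                 ncol(E), model$embedding_dim))
  }
  X <- cbind(E, matrix(0, nrow(E), model$target_dim))
  out <- .imputer_fwd(model, X)$out
  rownames(out) <- rownames(E)
  if (is.matrix(embedding)) out else as.vector(out)
}

#' Held-out reconstruction AUC of an imputer
#'
#' Scores every (entity, column) cell of the held-out rows with the
#' zero-masked imputer and ranks them against the true binary cells.
#' Rows whose true values are single-class (all 0 or all 1) have no
#' defined per-row AUC and are excluded from the per-row table with a
#' warning; the pooled AUC uses all cells.
#'
#' @param model a trained imputer.
#' @param embeddings [embedding_table()] covering `held_out`.
#' @param matrix the true [hetero_matrix()].
#' @param held_out ids of held-out entities (disjoint from training ids).
#' @return A list: `auc` (pooled over all held-out cells), `per_row`
#'   (data.frame id/auc), `excluded` (ids with undefined per-row AUC).
#' @export
reconstruction_auc <- function(model, embeddings, matrix, held_out) {
  held_out <- unique(as.character(held_out))
  if (length(held_out) == 0L) stop("held_out is empty")
  E <- embeddings$values[registry_pos(embeddings$registry, held_out), , drop = FALSE]
  truth <- matrix$values[registry_pos(matrix$rows, held_out), , drop = FALSE]
  scores <- impute(model, E)
  per <- vapply(seq_along(held_out), function(i) {
    y <- truth[i, ]
    if (all(y == 0) || all(y == 1)) return(NA_real_)
    roc_auc(scores[i, ], y)
  }, numeric(1))
  excluded <- held_out[is.na(per)]
  if (length(excluded)) {
    warning(sprintf("%d held-out row(s) are single-class; per-row AUC undefined",
                    length(excluded)))
  }
  pooled <- if (all(truth == 0) || all(truth == 1)) NA_real_
            else roc_auc(as.vector(scores), as.vector(truth))
  list(auc = pooled,
       per_row = data.frame(id = held_out[!is.na(per)], auc = per[!is.na(per)],
                            stringsAsFactors = FALSE),
       excluded = excluded)
}
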