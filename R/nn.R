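# Internal dense-network primitives shared by the imputers and the
# residual DTI model: seeded initialization, layer normalization with
# exact backward passes, Adam, and dropout. All forward/backward code is
# batched: X is n_samples x n_features, weights are in x out so the
# forward pass is a single BLAS call X %*% W.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Uniform fan-in initialization: U(-1/sqrt(n_in), 1/sqrt(n_in)).
.init_dense <- function(n_in, n_out) {
  r <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out),
       b = numeric(n_out))
}

.relu <- function(x) pmax(x, 0)

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Column-broadcast: add bias vector b (length = ncol) to each row of X.
.add_bias <- function(X, b) X + rep(b, each = nrow(X))

# Layer normalization over the feature axis with population (biased)
# variance. Returns the output plus the cache needed for the backward pass.
.ln_fwd <- function(Z, gain, bias, eps) {
  n <- nrow(Z)
  mu <- rowMeans(Z)
  zc <- Z - mu
  v <- rowMeans(zc * zc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- zc * inv_sd
  Y <- .add_bias(xhat * rep(gain, each = n), bias)
  list(Y = Y, xhat = xhat, inv_sd = inv_sd)
}

.ln_bwd <- function(dY, cache, gain) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dxhat <- dY * rep(gain, each = n)
  dZ <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv_sd
  list(dZ = dZ, dgain = colSums(dY * xhat), dbias = colSums(dY))
}

# Inverted dropout: mask scaled by 1/(1-p) so inference needs no rescaling.
.dropout_mask <- function(n, m, p) {
  matrix((stats::runif(n * m) >= p) / (1 - p), n, m)
}

# Adam optimizer over a flat named list of numeric arrays.
.adam_new <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = lapply(params, function(p) array(0, dim = if (is.matrix(p)) dim(p) else length(p))),
       v = lapply(params, function(p) array(0, dim = if (is.matrix(p)) dim(p) else length(p))),
       t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

.adam_step <- function(state, params, grads, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + state$eps)
  }
  list(state = state, params = params)
}

# Deterministic per-id integer for synthetic embedding providers: a small
# string hash folded with the provider seed, kept below 2^31.
.id_hash <- function(id, seed) {
  h <- 0
  for (code in utf8ToInt(id)) h <- (h * 131 + code) %% 2147480009
  as.integer((h + as.numeric(seed) * 7919) %% 2147480009)
}

#' Binary cross-entropy loss
#'
#' Mean over samples of `-t*log(p) - (1-t)*log(1-p)` with probabilities
#' clamped to `[1e-7, 1 - 1e-7]` for numerical safety.
#'
#' @param probabilities numeric vector of predicted probabilities.
#' @param labels 0/1 vector of the same length.
#' @return The mean binary cross-entropy (a scalar).
#' @export
bce_loss <- function(probabilities, labels) {
  if (length(probabilities) != length(labels)) {
    stop("probabilities and labels must have equal length")
  }
  p <- pmin(pmax(probabilities, 1e-7), 1 - 1e-7)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}
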