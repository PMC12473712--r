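#' @name nn-internals
#' @title Internal 1-D CNN engine
#' @description Minimal trainable layer stack used by the classifier
#'   architectures: valid 1-D convolution (im2col + matrix product), ReLU,
#'   width-2 max pooling, global average pooling, additive temporal
#'   attention pooling, dense layers, softmax cross-entropy, and Adam.
#'   Activations are arrays shaped (batch, length, channels); everything is
#'   vectorized over the batch, and all randomness (weight init, shuffling)
#'   comes from explicit seeds so runs are bit-reproducible.
#' @keywords internal
NULL

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

layer_conv <- function(filters, kernel, in_channels) {
  list(type = "conv", k = kernel, filters = filters,
       W = matrix(glorot_uniform(kernel * in_channels, filters,
                                 kernel * in_channels * filters),
                  kernel * in_channels, filters),
       b = numeric(filters))
}

layer_relu <- function() list(type = "relu")
layer_pool <- function() list(type = "pool")
layer_gap <- function() list(type = "gap")

layer_attn <- function(in_channels) {
  list(type = "attn",
       w = glorot_uniform(in_channels, 1L, in_channels),
       b = 0)
}

layer_dense <- function(units, in_units) {
  list(type = "dense", units = units,
       W = matrix(glorot_uniform(in_units, units, in_units * units),
                  in_units, units),
       b = numeric(units))
}

# ---- forward passes ------------------------------------------------------

im2col <- function(X, k) {
  d <- dim(X)  # (B, L, C)
  Lout <- d[2L] - k + 1L
  out <- matrix(0, d[1L] * Lout, k * d[3L])
  for (j in seq_len(k)) {
    out[, ((j - 1L) * d[3L] + 1L):(j * d[3L])] <-
      matrix(X[, j:(j + Lout - 1L), , drop = FALSE], d[1L] * Lout, d[3L])
  }
  out
}

fwd_conv <- function(layer, X) {
  d <- dim(X)
  Lout <- d[2L] - layer$k + 1L
  if (Lout < 1L) stop("input too short for kernel size ", layer$k)
  Xcol <- im2col(X, layer$k)
  Y <- Xcol %*% layer$W
  Y <- Y + rep(layer$b, each = nrow(Y))
  list(out = array(Y, c(d[1L], Lout, layer$filters)),
       cache = list(Xcol = Xcol, dims = d, Lout = Lout))
}

bwd_conv <- function(layer, cache, dY) {
  d <- cache$dims
  dYm <- matrix(dY, d[1L] * cache$Lout, layer$filters)
  dW <- crossprod(cache$Xcol, dYm)
  db <- colSums(dYm)
  dXcol <- tcrossprod(dYm, layer$W)
  dX <- array(0, d)
  C <- d[3L]
  for (j in seq_len(layer$k)) {
    dX[, j:(j + cache$Lout - 1L), ] <-
      dX[, j:(j + cache$Lout - 1L), , drop = FALSE] +
      array(dXcol[, ((j - 1L) * C + 1L):(j * C)], c(d[1L], cache$Lout, C))
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

fwd_relu <- function(layer, X) {
  list(out = pmax(X, 0), cache = X > 0)
}

bwd_relu <- function(layer, cache, dY) {
  list(dX = dY * cache, grads = NULL)
}

fwd_pool <- function(layer, X) {
  d <- dim(X)
  Lout <- d[2L] %/% 2L
  A <- X[, seq(1L, 2L * Lout, by = 2L), , drop = FALSE]
  B <- X[, seq(2L, 2L * Lout, by = 2L), , drop = FALSE]
  mask <- A >= B  # ties take the earlier sample
  list(out = pmax(A, B), cache = list(mask = mask, dims = d, Lout = Lout))
}

bwd_pool <- function(layer, cache, dY) {
  d <- cache$dims
  dX <- array(0, d)
  dX[, seq(1L, 2L * cache$Lout, by = 2L), ] <- dY * cache$mask
  dX[, seq(2L, 2L * cache$Lout, by = 2L), ] <- dY * !cache$mask
  list(dX = dX, grads = NULL)
}

fwd_gap <- function(layer, X) {
  d <- dim(X)
  out <- colSums(aperm(X, c(2L, 1L, 3L))) / d[2L]
  list(out = out, cache = d)  # out is (B, C)
}

bwd_gap <- function(layer, cache, dY) {
  d <- cache
  dX <- array(0, d)
  g <- dY / d[2L]
  for (l in seq_len(d[2L])) dX[, l, ] <- g
  list(dX = dX, grads = NULL)
}

fwd_attn <- function(layer, X) {
  d <- dim(X)  # (B, T, F)
  s <- matrix(matrix(X, d[1L] * d[2L], d[3L]) %*% layer$w + layer$b,
              d[1L], d[2L])
  s <- s - apply(s, 1L, max)
  alpha <- exp(s)
  alpha <- alpha / rowSums(alpha)
  out <- matrix(0, d[1L], d[3L])
  for (t in seq_len(d[2L])) {
    out <- out + alpha[, t] * matrix(X[, t, ], d[1L], d[3L])
  }
  list(out = out, cache = list(X = X, alpha = alpha, dims = d))
}

bwd_attn <- function(layer, cache, dY) {
  d <- cache$dims
  X <- cache$X; alpha <- cache$alpha
  dalpha <- matrix(0, d[1L], d[2L])
  dX <- array(0, d)
  for (t in seq_len(d[2L])) {
    xt <- matrix(X[, t, ], d[1L], d[3L])
    dalpha[, t] <- rowSums(dY * xt)
    dX[, t, ] <- alpha[, t] * dY
  }
  ds <- alpha * (dalpha - rowSums(alpha * dalpha))
  dw <- numeric(d[3L])
  for (t in seq_len(d[2L])) {
    xt <- matrix(X[, t, ], d[1L], d[3L])
    dw <- dw + colSums(xt * ds[, t])
    dX[, t, ] <- dX[, t, ] + outer(ds[, t], layer$w)
  }
  list(dX = dX, grads = list(w = dw, b = sum(ds)))
}

fwd_dense <- function(layer, X) {
  Y <- X %*% layer$W
  Y <- Y + rep(layer$b, each = nrow(Y))
  list(out = Y, cache = X)
}

bwd_dense <- function(layer, cache, dY) {
  list(dX = tcrossprod(dY, layer$W),
       grads = list(W = crossprod(cache, dY), b = colSums(dY)))
}

FWD <- list(conv = fwd_conv, relu = fwd_relu, pool = fwd_pool,
            gap = fwd_gap, attn = fwd_attn, dense = fwd_dense)
BWD <- list(conv = bwd_conv, relu = bwd_relu, pool = bwd_pool,
            gap = bwd_gap, attn = bwd_attn, dense = bwd_dense)

forward_layers <- function(layers, X) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- FWD[[layers[[i]]$type]](layers[[i]], X)
    X <- r$out
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

backward_layers <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- BWD[[layers[[i]]$type]](layers[[i]], caches[[i]], dY)
    dY <- r$dX
    grads[i] <- list(r$grads)  # [[<- would drop NULL entries
  }
  list(dX = dY, grads = grads)
}

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

# mean cross-entropy and its gradient w.r.t. logits; a saturated wrong
# prediction yields an infinite loss, which the training loop treats as
# divergence
softmax_ce <- function(logits, y_idx) {
  P <- softmax_rows(logits)
  B <- nrow(P)
  loss <- -mean(log(P[cbind(seq_len(B), y_idx)]))
  dL <- P
  dL[cbind(seq_len(B), y_idx)] <- dL[cbind(seq_len(B), y_idx)] - 1
  list(loss = loss, dlogits = dL / B)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    ps <- intersect(names(l), c("W", "b", "w"))
    if (l$type %in% c("relu", "pool", "gap")) return(NULL)
    st <- lapply(ps, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
    names(st) <- ps
    st
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

n_params_layers <- function(layers) {
  sum(vapply(layers, function(l) {
    ps <- intersect(names(l), c("W", "b", "w"))
    sum(vapply(ps, function(p) length(l[[p]]), 1L))
  }, 1L))
}
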