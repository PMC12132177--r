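# Internal dense-network machinery: an MLP with ReLU hidden layers, a
# two-layer graph convolution, and an Adam optimizer over named lists of
# parameter matrices.  Everything is plain vectorised linear algebra so that
# training is deterministic given the RNG seed.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# He-scaled initialisation; widths = c(d_in, hidden..., 1)
mlp_init <- function(widths) {
  layers <- vector("list", length(widths) - 1L)
  for (k in seq_along(layers)) {
    d_in <- widths[k]; d_out <- widths[k + 1L]
    layers[[k]] <- list(
      W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
      b = rep(0, d_out))
  }
  layers
}

# forward pass; returns scalar-head output (n) and per-layer caches
mlp_forward <- function(layers, X) {
  L <- length(layers)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (k in seq_len(L)) {
    Z <- A[[k]] %*% layers[[k]]$W
    Z <- sweep(Z, 2L, layers[[k]]$b, `+`)
    A[[k + 1L]] <- if (k < L) relu(Z) else Z
  }
  list(out = drop(A[[L + 1L]]), acts = A)
}

# backprop; dout = dL/d(out) (length n); returns grads per layer and dX
mlp_backward <- function(layers, acts, dout) {
  L <- length(layers)
  grads <- vector("list", L)
  dA <- matrix(dout, ncol = 1L)
  for (k in rev(seq_len(L))) {
    if (k < L) dA <- dA * (acts[[k + 1L]] > 0)  # relu mask on hidden outputs
    grads[[k]] <- list(W = crossprod(acts[[k]], dA), b = colSums(dA))
    dA <- dA %*% t(layers[[k]]$W)
  }
  list(grads = grads, dX = dA)
}

# Graph convolution with one-hot input features H0 = I:
#   H_k = relu(Ahat H_{k-1} W_k) for k < K, last layer linear.
# Ahat is the symmetric-normalized adjacency with self-loops.

gcn_init <- function(n_nodes, widths) {
  dims <- c(n_nodes, widths)
  lapply(seq_along(widths), function(k) {
    matrix(stats::rnorm(dims[k] * dims[k + 1L], sd = sqrt(2 / dims[k])),
           dims[k], dims[k + 1L])
  })
}

gcn_forward_cache <- function(Ahat, Ws) {
  K <- length(Ws)
  Hs <- vector("list", K + 1L)
  M <- vector("list", K)       # M[[k]] = Ahat %*% H_{k-1}, reused in backprop
  Hs[[1L]] <- diag(nrow(Ahat))
  for (k in seq_len(K)) {
    M[[k]] <- Ahat %*% Hs[[k]]
    Z <- M[[k]] %*% Ws[[k]]
    Hs[[k + 1L]] <- if (k < K) relu(Z) else Z
  }
  list(H = Hs[[K + 1L]], Hs = Hs, M = M)
}

# dH: gradient wrt final node embeddings (nodes x dim_out); Ahat symmetric
gcn_backward_cache <- function(Ahat, Ws, cache, dH) {
  K <- length(Ws)
  grads <- vector("list", K)
  dZ <- dH
  for (k in rev(seq_len(K))) {
    if (k < K) dZ <- dZ * (cache$Hs[[k + 1L]] > 0)
    grads[[k]] <- crossprod(cache$M[[k]], dZ)
    if (k > 1L) dZ <- Ahat %*% (dZ %*% t(Ws[[k]]))
  }
  grads
}

# ---- Adam over arbitrarily nested lists of numeric arrays ----

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"), v = lapply(out, `[[`, "v"),
                    t = t))
}
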