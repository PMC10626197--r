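# Minimal neural-network engine: MLP with ReLU, optional FiLM conditioning and
# dropout, a symmetric bilinear pair-combination layer, and Adam. All forward /
# backward passes are dense base-R matrix algebra; randomness is taken from the
# caller's RNG state so that training is reproducible from a single seed.

# He-initialised MLP. dims = c(inputDim, hidden..., outputDim).
# film: if TRUE, per-hidden-layer FiLM maps linear in the lC cell features,
# initialised at zero so that gamma = 1, beta = 0 (identity) at the start.
.mlpInit <- function(dims, lC = 0, film = FALSE) {
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (i in seq_len(L)) {
    W[[i]] <- matrix(stats::rnorm(dims[i] * dims[i + 1], sd = sqrt(2 / dims[i])),
                     dims[i], dims[i + 1])
    b[[i]] <- rep(0, dims[i + 1])
  }
  mlp <- list(W = W, b = b)
  if (film && lC > 0 && L > 1) {
    mlp$gW <- lapply(seq_len(L - 1L), function(i) matrix(0, lC, dims[i + 1]))
    mlp$bW <- lapply(seq_len(L - 1L), function(i) matrix(0, lC, dims[i + 1]))
  }
  mlp
}

# Forward pass. X: n x d. C: n x lC cell features or NULL. dropout: NULL or
# list(input=, layer=) with keep-prob scaling; masks drawn from current RNG.
.mlpForward <- function(mlp, X, C = NULL, dropout = NULL, training = FALSE) {
  L <- length(mlp$W)
  film <- !is.null(mlp$gW) && !is.null(C)
  cache <- list(H = vector("list", L + 1L), U = vector("list", L),
                G = vector("list", L), mask = vector("list", L + 1L),
                C = C, training = training, dropout = dropout)
  H <- X
  if (training && !is.null(dropout) && dropout$input > 0) {
    m <- matrix(stats::rbinom(length(H), 1, 1 - dropout$input), nrow(H)) / (1 - dropout$input)
    cache$mask[[L + 1L]] <- m
    H <- H * m
  }
  cache$H[[1L]] <- H
  for (i in seq_len(L)) {
    U <- H %*% mlp$W[[i]]
    U <- sweep(U, 2, mlp$b[[i]], `+`)
    if (i < L) {
      if (film && i <= length(mlp$gW)) {
        G <- 1 + C %*% mlp$gW[[i]]
        U <- G * U + C %*% mlp$bW[[i]]
        cache$G[[i]] <- G
      }
      cache$U[[i]] <- U
      H <- pmax(U, 0)
      if (training && !is.null(dropout) && dropout$layer > 0) {
        m <- matrix(stats::rbinom(length(H), 1, 1 - dropout$layer), nrow(H)) / (1 - dropout$layer)
        cache$mask[[i]] <- m
        H <- H * m
      }
    } else {
      cache$U[[i]] <- U
      H <- U
    }
    cache$H[[i + 1L]] <- H
  }
  list(out = H, cache = cache)
}

# Backward pass. dOut: gradient w.r.t. the MLP output (n x outDim).
# Returns grads mirroring the mlp structure, plus dX.
.mlpBackward <- function(mlp, cache, dOut) {
  L <- length(mlp$W)
  film <- !is.null(mlp$gW) && !is.null(cache$C)
  grads <- mlp
  dH <- dOut
  for (i in rev(seq_len(L))) {
    if (i == L) {
      dU <- dH
    } else {
      if (!is.null(cache$mask[[i]])) dH <- dH * cache$mask[[i]]
      dM <- dH * (cache$U[[i]] > 0)
      if (film && i <= length(mlp$gW)) {
        G <- cache$G[[i]]
        # U_pre = affine output before FiLM; recover it from M = G*U_pre + beta
        Upre <- cache$H[[i]] %*% mlp$W[[i]]
        Upre <- sweep(Upre, 2, mlp$b[[i]], `+`)
        grads$gW[[i]] <- t(cache$C) %*% (dM * Upre)
        grads$bW[[i]] <- t(cache$C) %*% dM
        dU <- dM * G
      } else {
        dU <- dM
      }
    }
    grads$W[[i]] <- t(cache$H[[i]]) %*% dU
    grads$b[[i]] <- colSums(dU)
    dH <- dU %*% t(mlp$W[[i]])
  }
  if (!is.null(cache$mask[[L + 1L]])) dH <- dH * cache$mask[[L + 1L]]
  list(grads = grads, dX = dH)
}

# Symmetric bilinear combination: z_i = e1' S_i e2 with S_i = (W_i + W_i')/2.
# Unconstrained W_i are stored; symmetrisation at evaluation guarantees exact
# permutation invariance of the prediction.
.bilinearForward <- function(Wlist, E1, E2) {
  k <- length(Wlist)
  Z <- matrix(0, nrow(E1), k)
  S <- vector("list", k)
  for (i in seq_len(k)) {
    S[[i]] <- (Wlist[[i]] + t(Wlist[[i]])) / 2
    Z[, i] <- rowSums((E1 %*% S[[i]]) * E2)
  }
  list(Z = Z, S = S)
}

.bilinearBackward <- function(Wlist, S, E1, E2, dZ) {
  k <- length(Wlist)
  dE1 <- matrix(0, nrow(E1), ncol(E1))
  dE2 <- dE1
  gW <- vector("list", k)
  for (i in seq_len(k)) {
    g <- dZ[, i]
    dE1 <- dE1 + (E2 %*% S[[i]]) * g
    dE2 <- dE2 + (E1 %*% S[[i]]) * g
    gW[[i]] <- 0.5 * (t(E1) %*% (g * E2) + t(E2) %*% (g * E1))
  }
  list(dE1 = dE1, dE2 = dE2, gW = gW)
}

# Adam on a nested parameter list, via flatten/relist (structure preserved).
.adamInit <- function(params) {
  flat <- unlist(params, use.names = FALSE)
  list(m = numeric(length(flat)), v = numeric(length(flat)), t = 0L)
}

.adamStep <- function(params, grads, state, lr, weightDecay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  p <- unlist(params, use.names = FALSE)
  g <- unlist(grads, use.names = FALSE)
  if (weightDecay > 0) g <- g + weightDecay * p
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  p <- p - lr * mhat / (sqrt(vhat) + eps)
  list(params = utils::relist(p, skeleton = params), state = state)
}
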