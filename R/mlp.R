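# Minimal dense-network engine: fully-connected layers with batch
# normalization between layers, swish activation on hidden and output
# layers, Gaussian weight init, and exact backprop. Written directly on
# base-R matrix ops (BLAS); this is all the generators and the
# discriminator need.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

sigmoid <- function(x) 1 / (1 + exp(-x))
swish <- function(x) x * sigmoid(x)
swish_grad <- function(x) {
  s <- sigmoid(x)
  s + x * s * (1 - s)
}

# A network is a list of layers. Hidden layers: dense -> batchnorm -> swish.
# Final layer: dense -> swish ("swish") or plain dense ("linear").
mlp_new <- function(sizes, out_activation = c("swish", "linear"),
                    use_bn = TRUE) {
  out_activation <- match.arg(out_activation)
  stopifnot(length(sizes) >= 2L)
  nl <- length(sizes) - 1L
  layers <- vector("list", nl)
  for (i in seq_len(nl)) {
    d_in <- sizes[i]; d_out <- sizes[i + 1]
    layer <- list(
      W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(1 / d_in)), d_in, d_out),
      b = numeric(d_out),
      kind = if (i < nl) "hidden" else out_activation,
      bn = i < nl && use_bn
    )
    if (layer$bn) {
      layer$gamma <- rep(1, d_out); layer$beta <- numeric(d_out)
      layer$rmean <- numeric(d_out); layer$rvar <- rep(1, d_out)
    }
    layers[[i]] <- layer
  }
  structure(list(layers = layers, sizes = sizes), class = "vt_mlp")
}

bcast <- function(v, M) matrix(v, M, length(v), byrow = TRUE)

# Forward pass; returns output, per-layer caches for backprop, and (in
# training mode) the net with updated batch-norm running statistics.
mlp_forward <- function(net, X, training = FALSE) {
  M <- nrow(X)
  caches <- vector("list", length(net$layers))
  A <- X
  for (i in seq_along(net$layers)) {
    L <- net$layers[[i]]
    Z <- A %*% L$W + bcast(L$b, M)
    cache <- list(X = A, Z = Z)
    if (isTRUE(L$bn)) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(Z^2) - mu^2
        v[v < 0] <- 0
        net$layers[[i]]$rmean <- BN_MOMENTUM * L$rmean + (1 - BN_MOMENTUM) * mu
        net$layers[[i]]$rvar <- BN_MOMENTUM * L$rvar + (1 - BN_MOMENTUM) * v
      } else {
        mu <- L$rmean; v <- L$rvar
      }
      xhat <- (Z - bcast(mu, M)) / bcast(sqrt(v + BN_EPS), M)
      Y <- xhat * bcast(L$gamma, M) + bcast(L$beta, M)
      cache$xhat <- xhat; cache$var <- v; cache$Y <- Y
    } else {
      Y <- Z
      cache$Y <- Y
    }
    A <- if (L$kind == "linear") Y else swish(Y)
    caches[[i]] <- cache
  }
  list(out = A, caches = caches, net = net)
}

# Backprop given the gradient of the loss wrt the network output.
# Returns parameter gradients (aligned with layers) and the gradient wrt
# the network input.
mlp_backward <- function(net, caches, dOut, training = FALSE) {
  grads <- vector("list", length(net$layers))
  dA <- dOut
  for (i in rev(seq_along(net$layers))) {
    L <- net$layers[[i]]
    cache <- caches[[i]]
    M <- nrow(cache$X)
    dY <- if (L$kind == "linear") dA else dA * swish_grad(cache$Y)
    g <- list()
    if (isTRUE(L$bn)) {
      g$dgamma <- colSums(dY * cache$xhat)
      g$dbeta <- colSums(dY)
      inv_sd <- 1 / sqrt(cache$var + BN_EPS)
      dxhat <- dY * bcast(L$gamma, M)
      if (training) {
        m1 <- colMeans(dxhat)
        m2 <- colMeans(dxhat * cache$xhat)
        dZ <- (dxhat - bcast(m1, M) - cache$xhat * bcast(m2, M)) *
          bcast(inv_sd, M)
      } else {
        dZ <- dxhat * bcast(inv_sd, M)
      }
    } else {
      dZ <- dY
    }
    g$dW <- crossprod(cache$X, dZ)
    g$db <- colSums(dZ)
    grads[[i]] <- g
    dA <- tcrossprod(dZ, L$W)
  }
  list(grads = grads, dX = dA)
}

# Plain SGD update.
mlp_sgd_step <- function(net, grads, lr) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    net$layers[[i]]$W <- net$layers[[i]]$W - lr * g$dW
    net$layers[[i]]$b <- net$layers[[i]]$b - lr * g$db
    if (isTRUE(net$layers[[i]]$bn)) {
      net$layers[[i]]$gamma <- net$layers[[i]]$gamma - lr * g$dgamma
      net$layers[[i]]$beta <- net$layers[[i]]$beta - lr * g$dbeta
    }
  }
  net
}

adam_init <- function(net) {
  state <- lapply(net$layers, function(L) {
    s <- list(mW = L$W * 0, vW = L$W * 0, mb = L$b * 0, vb = L$b * 0)
    if (isTRUE(L$bn)) {
      s$mg <- L$gamma * 0; s$vg <- L$gamma * 0
      s$mB <- L$beta * 0; s$vB <- L$beta * 0
    }
    s
  })
  list(t = 0L, layers = state)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(param, grad, m, v) {
    m <- beta1 * m + (1 - beta1) * grad
    v <- beta2 * v + (1 - beta2) * grad^2
    param <- param - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(param = param, m = m, v = v)
  }
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]; s <- state$layers[[i]]
    r <- upd(net$layers[[i]]$W, g$dW, s$mW, s$vW)
    net$layers[[i]]$W <- r$param; s$mW <- r$m; s$vW <- r$v
    r <- upd(net$layers[[i]]$b, g$db, s$mb, s$vb)
    net$layers[[i]]$b <- r$param; s$mb <- r$m; s$vb <- r$v
    if (isTRUE(net$layers[[i]]$bn)) {
      r <- upd(net$layers[[i]]$gamma, g$dgamma, s$mg, s$vg)
      net$layers[[i]]$gamma <- r$param; s$mg <- r$m; s$vg <- r$v
      r <- upd(net$layers[[i]]$beta, g$dbeta, s$mB, s$vB)
      net$layers[[i]]$beta <- r$param; s$mB <- r$m; s$vB <- r$v
    }
    state$layers[[i]] <- s
  }
  list(net = net, state = state)
}

# Number of trainable parameters.
mlp_n_params <- function(net) {
  sum(vapply(net$layers, function(L) {
    n <- length(L$W) + length(L$b)
    if (isTRUE(L$bn)) n <- n + length(L$gamma) + length(L$beta)
    n
  }, 0))
}
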