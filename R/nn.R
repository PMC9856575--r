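# Minimal feed-forward network machinery (Glorot-uniform init, Adam,
# inverted dropout) used by the MLP and the two CNN variants. Written in
# plain matrix algebra: at the scales this package targets for testing the
# network families, this is fast enough and keeps the dependency footprint
# at zero.

glorot_uniform <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  r <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -r, r), dim = dims)
}

adam_new <- function(params) {
  lapply(params, function(p) {
    list(m = array(0, dim = dim(p) %||% length(p)),
         v = array(0, dim = dim(p) %||% length(p)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(param, grad, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  param <- param - lr * mhat / (sqrt(vhat) + eps)
  list(param = param, state = state)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

dropout_mask <- function(dim, p) {
  if (p <= 0) return(NULL)
  array((stats::runif(prod(dim)) >= p) / (1 - p), dim = dim)
}

one_hot <- function(y01, n_classes = 2L) {
  m <- matrix(0, length(y01), n_classes)
  m[cbind(seq_along(y01), y01 + 1L)] <- 1
  m
}

# ---- multilayer perceptron -------------------------------------------------

# All-sigmoid four-layer MLP (hidden sizes `hidden`, 2 output units),
# binary cross-entropy loss, Adam, inverted dropout on hidden activations.
mlp_fit <- function(x, y01, hidden = c(1024L, 512L, 256L), lr = 0.001,
                    epochs = 50L, dropout = 0.15, batch_size = 32L) {
  dims <- c(ncol(x), hidden, 2L)
  nl <- length(dims) - 1L
  W <- lapply(seq_len(nl), function(l) glorot_uniform(dims[l], dims[l + 1L]))
  b <- lapply(seq_len(nl), function(l) numeric(dims[l + 1L]))
  opt_w <- adam_new(W)
  opt_b <- adam_new(b)
  t <- 0L
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    for (batch in batch_indices(n, batch_size)) {
      xb <- x[batch, , drop = FALSE]
      yb <- one_hot(y01[batch])
      # forward
      a <- vector("list", nl + 1L)
      masks <- vector("list", nl)
      a[[1L]] <- xb
      for (l in seq_len(nl)) {
        z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
        act <- sigmoid(z)
        if (l < nl && dropout > 0) {
          masks[[l]] <- dropout_mask(dim(act), dropout)
          act <- act * masks[[l]]
        }
        a[[l + 1L]] <- act
      }
      # backward (sigmoid + BCE: dL/dz = a - y at the output)
      dz <- (a[[nl + 1L]] - yb) / length(batch)
      t <- t + 1L
      for (l in rev(seq_len(nl))) {
        dw <- crossprod(a[[l]], dz)
        dbv <- colSums(dz)
        if (l > 1L) {
          da <- tcrossprod(dz, W[[l]])
          if (!is.null(masks[[l - 1L]])) da <- da * masks[[l - 1L]]
          ah <- a[[l]]
          dz <- da * ah * (1 - ah)
        }
        up <- adam_step(W[[l]], dw, opt_w[[l]], lr, t)
        W[[l]] <- up$param
        opt_w[[l]] <- up$state
        up <- adam_step(b[[l]], dbv, opt_b[[l]], lr, t)
        b[[l]] <- up$param
        opt_b[[l]] <- up$state
      }
    }
  }
  list(W = W, b = b, dims = dims)
}

mlp_forward <- function(fit, x) {
  a <- x
  nl <- length(fit$W)
  for (l in seq_len(nl)) {
    a <- sigmoid(sweep(a %*% fit$W[[l]], 2, fit$b[[l]], "+"))
  }
  a
}

mlp_predict <- function(fit, x) {
  scores <- mlp_forward(fit, x)
  argmax01(scores)
}

# argmax over the 2 output units; ties resolved to the lower class index
# (which.max returns the first maximum).
argmax01 <- function(scores) {
  apply(scores, 1, which.max) - 1L
}

batch_indices <- function(n, batch_size) {
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / batch_size))
}
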