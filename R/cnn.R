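# Convolutional network building blocks (im2col-style 1-D and 2-D "same"
# convolutions, max pooling with argmax routing, ReLU) plus the two fixed
# architectures: a vector-input network (three length-9 conv layers, one
# 2x1 max pool, four-layer fully connected head) and a matrix-input network
# (three 3x3 conv layers each followed by 2x2 max pooling, same head).

relu <- function(z) pmax(z, 0)

# ---- 1-D convolution (batch, length, channels) -----------------------------

conv1d_forward <- function(A, W, b) {
  n <- dim(A)[1]; L <- dim(A)[2]; cin <- dim(A)[3]
  k <- dim(W)[1]; cout <- dim(W)[3]
  pad <- (k - 1L) %/% 2L
  Apad <- array(0, c(n, L + k - 1L, cin))
  Apad[, pad + seq_len(L), ] <- A
  M <- matrix(0, n * L, k * cin)
  for (t in seq_len(k)) {
    M[, (t - 1L) * cin + seq_len(cin)] <-
      matrix(Apad[, t:(t + L - 1L), , drop = FALSE], n * L, cin)
  }
  Wm <- matrix(aperm(W, c(2, 1, 3)), k * cin, cout)
  out <- sweep(M %*% Wm, 2, b, "+")
  list(out = array(out, c(n, L, cout)), M = M, Wm = Wm,
       dims = c(n, L, cin, k))
}

conv1d_backward <- function(cache, dOut) {
  n <- cache$dims[1]; L <- cache$dims[2]
  cin <- cache$dims[3]; k <- cache$dims[4]
  cout <- ncol(cache$Wm)
  dOm <- matrix(dOut, n * L, cout)
  dWm <- crossprod(cache$M, dOm)
  dW <- aperm(array(dWm, c(cin, k, cout)), c(2, 1, 3))
  db <- colSums(dOm)
  dM <- tcrossprod(dOm, cache$Wm)
  pad <- (k - 1L) %/% 2L
  dApad <- array(0, c(n, L + k - 1L, cin))
  for (t in seq_len(k)) {
    dApad[, t:(t + L - 1L), ] <- dApad[, t:(t + L - 1L), , drop = FALSE] +
      array(dM[, (t - 1L) * cin + seq_len(cin)], c(n, L, cin))
  }
  list(dA = dApad[, pad + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

maxpool1d_forward <- function(A) {
  n <- dim(A)[1]; L <- dim(A)[2]; ch <- dim(A)[3]
  L2 <- L %/% 2L
  c1 <- A[, seq(1L, 2L * L2, by = 2L), , drop = FALSE]
  c2 <- A[, seq(2L, 2L * L2, by = 2L), , drop = FALSE]
  m <- pmax(c1, c2)
  list(out = m, first = c1 >= c2, L = L, ch = ch, n = n, L2 = L2)
}

maxpool1d_backward <- function(cache, dOut) {
  dA <- array(0, c(cache$n, cache$L, cache$ch))
  dA[, seq(1L, 2L * cache$L2, by = 2L), ] <- dOut * cache$first
  dA[, seq(2L, 2L * cache$L2, by = 2L), ] <- dOut * !cache$first
  dA
}

# ---- 2-D convolution (batch, rows, cols, channels) -------------------------

conv2d_forward <- function(A, W, b) {
  n <- dim(A)[1]; J <- dim(A)[2]; N <- dim(A)[3]; cin <- dim(A)[4]
  ky <- dim(W)[1]; kx <- dim(W)[2]; cout <- dim(W)[4]
  py <- (ky - 1L) %/% 2L; px <- (kx - 1L) %/% 2L
  Apad <- array(0, c(n, J + ky - 1L, N + kx - 1L, cin))
  Apad[, py + seq_len(J), px + seq_len(N), ] <- A
  M <- matrix(0, n * J * N, ky * kx * cin)
  t <- 0L
  for (dy in seq_len(ky)) {
    for (dx in seq_len(kx)) {
      t <- t + 1L
      M[, (t - 1L) * cin + seq_len(cin)] <-
        matrix(Apad[, dy:(dy + J - 1L), dx:(dx + N - 1L), , drop = FALSE],
               n * J * N, cin)
    }
  }
  Wm <- matrix(aperm(W, c(3, 2, 1, 4)), ky * kx * cin, cout)
  out <- sweep(M %*% Wm, 2, b, "+")
  list(out = array(out, c(n, J, N, cout)), M = M, Wm = Wm,
       dims = c(n, J, N, cin, ky, kx))
}

conv2d_backward <- function(cache, dOut) {
  d <- cache$dims
  n <- d[1]; J <- d[2]; N <- d[3]; cin <- d[4]; ky <- d[5]; kx <- d[6]
  cout <- ncol(cache$Wm)
  dOm <- matrix(dOut, n * J * N, cout)
  dWm <- crossprod(cache$M, dOm)
  dW <- aperm(array(dWm, c(cin, kx, ky, cout)), c(3, 2, 1, 4))
  db <- colSums(dOm)
  dM <- tcrossprod(dOm, cache$Wm)
  py <- (ky - 1L) %/% 2L; px <- (kx - 1L) %/% 2L
  dApad <- array(0, c(n, J + ky - 1L, N + kx - 1L, cin))
  t <- 0L
  for (dy in seq_len(ky)) {
    for (dx in seq_len(kx)) {
      t <- t + 1L
      blk <- array(dM[, (t - 1L) * cin + seq_len(cin)], c(n, J, N, cin))
      dApad[, dy:(dy + J - 1L), dx:(dx + N - 1L), ] <-
        dApad[, dy:(dy + J - 1L), dx:(dx + N - 1L), , drop = FALSE] + blk
    }
  }
  list(dA = dApad[, py + seq_len(J), px + seq_len(N), , drop = FALSE],
       dW = dW, db = db)
}

maxpool2d_forward <- function(A) {
  n <- dim(A)[1]; J <- dim(A)[2]; N <- dim(A)[3]; ch <- dim(A)[4]
  J2 <- J %/% 2L; N2 <- N %/% 2L
  ro <- seq(1L, 2L * J2, by = 2L); re <- ro + 1L
  co <- seq(1L, 2L * N2, by = 2L); ce <- co + 1L
  c11 <- A[, ro, co, , drop = FALSE]; c12 <- A[, ro, ce, , drop = FALSE]
  c21 <- A[, re, co, , drop = FALSE]; c22 <- A[, re, ce, , drop = FALSE]
  m <- pmax(c11, c12, c21, c22)
  m11 <- c11 == m
  m12 <- (c12 == m) & !m11
  m21 <- (c21 == m) & !m11 & !m12
  m22 <- !m11 & !m12 & !m21
  list(out = m, masks = list(m11, m12, m21, m22), J = J, N = N, ch = ch,
       n = n, J2 = J2, N2 = N2)
}

maxpool2d_backward <- function(cache, dOut) {
  dA <- array(0, c(cache$n, cache$J, cache$N, cache$ch))
  ro <- seq(1L, 2L * cache$J2, by = 2L); re <- ro + 1L
  co <- seq(1L, 2L * cache$N2, by = 2L); ce <- co + 1L
  dA[, ro, co, ] <- dOut * cache$masks[[1L]]
  dA[, ro, ce, ] <- dOut * cache$masks[[2L]]
  dA[, re, co, ] <- dOut * cache$masks[[3L]]
  dA[, re, ce, ] <- dOut * cache$masks[[4L]]
  dA
}

# ---- fully connected head (sigmoid x3 + softmax, cross-entropy) ------------

fcn_init <- function(p_in, hidden = c(1024L, 512L, 256L)) {
  dims <- c(p_in, hidden, 2L)
  nl <- length(dims) - 1L
  list(W = lapply(seq_len(nl), function(l) glorot_uniform(dims[l], dims[l + 1L])),
       b = lapply(seq_len(nl), function(l) numeric(dims[l + 1L])))
}

fcn_forward <- function(fcn, x, dropout = 0, train = FALSE) {
  nl <- length(fcn$W)
  a <- vector("list", nl + 1L)
  masks <- vector("list", nl)
  a[[1L]] <- x
  for (l in seq_len(nl)) {
    z <- sweep(a[[l]] %*% fcn$W[[l]], 2, fcn$b[[l]], "+")
    if (l < nl) {
      act <- sigmoid(z)
      if (train && dropout > 0) {
        masks[[l]] <- dropout_mask(dim(act), dropout)
        act <- act * masks[[l]]
      }
    } else {
      act <- softmax_rows(z)
    }
    a[[l + 1L]] <- act
  }
  list(a = a, masks = masks)
}

# returns gradient w.r.t. the head input plus parameter gradients
fcn_backward <- function(fcn, fwd, y_onehot) {
  nl <- length(fcn$W)
  a <- fwd$a
  dz <- (a[[nl + 1L]] - y_onehot) / nrow(y_onehot)  # softmax + CE
  dW <- vector("list", nl)
  db <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    dW[[l]] <- crossprod(a[[l]], dz)
    db[[l]] <- colSums(dz)
    da <- tcrossprod(dz, fcn$W[[l]])
    if (l > 1L) {
      if (!is.null(fwd$masks[[l - 1L]])) da <- da * fwd$masks[[l - 1L]]
      ah <- a[[l]]
      dz <- da * ah * (1 - ah)
    } else {
      dz <- da  # gradient w.r.t. head input
    }
  }
  list(dx = dz, dW = dW, db = db)
}

# ---- vector-input CNN ------------------------------------------------------

cnn1_fit <- function(x, y01, n_filters = 32L, kernel = 9L, lr = 0.001,
                     epochs = 50L, dropout = 0.15, batch_size = 32L,
                     hidden = c(1024L, 512L, 256L)) {
  L <- ncol(x)
  cin <- c(1L, n_filters, n_filters)
  Wc <- lapply(1:3, function(l) {
    glorot_uniform(kernel * cin[l], n_filters,
                   dims = c(kernel, cin[l], n_filters))
  })
  bc <- lapply(1:3, function(l) numeric(n_filters))
  p_head <- (L %/% 2L) * n_filters
  fcn <- fcn_init(p_head, hidden)
  params <- c(Wc, bc, fcn$W, fcn$b)
  opt <- adam_new(params)
  t <- 0L
  for (ep in seq_len(epochs)) {
    for (batch in batch_indices(nrow(x), batch_size)) {
      nb <- length(batch)
      a <- array(x[batch, , drop = FALSE], c(nb, L, 1L))
      caches <- vector("list", 3L)
      for (l in 1:3) {
        cc <- conv1d_forward(a, Wc[[l]], bc[[l]])
        caches[[l]] <- cc
        a <- relu(cc$out)
      }
      pc <- maxpool1d_forward(a)
      flat <- matrix(pc$out, nb, p_head)
      fwd <- fcn_forward(fcn, flat, dropout, train = TRUE)
      bk <- fcn_backward(fcn, fwd, one_hot(y01[batch]))
      dpool <- array(bk$dx, c(nb, pc$L2, n_filters))
      da <- maxpool1d_backward(pc, dpool)
      dWc <- vector("list", 3L)
      dbc <- vector("list", 3L)
      for (l in 3:1) {
        da <- da * (relu(caches[[l]]$out) > 0)
        gr <- conv1d_backward(caches[[l]], da)
        dWc[[l]] <- gr$dW
        dbc[[l]] <- gr$db
        da <- gr$dA
      }
      t <- t + 1L
      upd <- nn_update(c(Wc, bc, fcn$W, fcn$b),
                       c(dWc, dbc, bk$dW, bk$db), opt, lr, t)
      opt <- upd$opt
      Wc <- upd$params[1:3]
      bc <- upd$params[4:6]
      nh <- length(fcn$W)
      fcn$W <- upd$params[7:(6 + nh)]
      fcn$b <- upd$params[(7 + nh):(6 + 2L * nh)]
    }
  }
  list(Wc = Wc, bc = bc, fcn = fcn, L = L, n_filters = n_filters,
       p_head = p_head)
}

cnn1_predict <- function(fit, x) {
  nb <- nrow(x)
  a <- array(x, c(nb, fit$L, 1L))
  for (l in 1:3) a <- relu(conv1d_forward(a, fit$Wc[[l]], fit$bc[[l]])$out)
  pc <- maxpool1d_forward(a)
  flat <- matrix(pc$out, nb, fit$p_head)
  argmax01(fcn_forward(fit$fcn, flat)$a[[length(fit$fcn$W) + 1L]])
}

# ---- matrix-input CNN ------------------------------------------------------

cnn2_fit <- function(x, y01, n_filters = 32L, kernel = c(3L, 3L),
                     lr = 0.001, epochs = 50L, dropout = 0.15,
                     batch_size = 32L, hidden = c(1024L, 512L, 256L)) {
  J <- dim(x)[2]; N <- dim(x)[3]
  cin <- c(1L, n_filters, n_filters)
  Wc <- lapply(1:3, function(l) {
    glorot_uniform(prod(kernel) * cin[l], n_filters,
                   dims = c(kernel[1], kernel[2], cin[l], n_filters))
  })
  bc <- lapply(1:3, function(l) numeric(n_filters))
  dj <- J; dn <- N
  for (s in 1:3) { dj <- dj %/% 2L; dn <- dn %/% 2L }
  if (dj < 1L || dn < 1L) stop("input matrix too small for three 2x2 poolings")
  p_head <- dj * dn * n_filters
  fcn <- fcn_init(p_head, hidden)
  opt <- adam_new(c(Wc, bc, fcn$W, fcn$b))
  t <- 0L
  for (ep in seq_len(epochs)) {
    for (batch in batch_indices(dim(x)[1], batch_size)) {
      nb <- length(batch)
      a <- array(x[batch, , , drop = FALSE], c(nb, J, N, 1L))
      ccache <- vector("list", 3L)
      pcache <- vector("list", 3L)
      for (l in 1:3) {
        cc <- conv2d_forward(a, Wc[[l]], bc[[l]])
        ccache[[l]] <- cc
        pc <- maxpool2d_forward(relu(cc$out))
        pcache[[l]] <- pc
        a <- pc$out
      }
      flat <- matrix(a, nb, p_head)
      fwd <- fcn_forward(fcn, flat, dropout, train = TRUE)
      bk <- fcn_backward(fcn, fwd, one_hot(y01[batch]))
      da <- array(bk$dx, dim(a))
      dWc <- vector("list", 3L)
      dbc <- vector("list", 3L)
      for (l in 3:1) {
        da <- maxpool2d_backward(pcache[[l]], da)
        da <- da * (relu(ccache[[l]]$out) > 0)
        gr <- conv2d_backward(ccache[[l]], da)
        dWc[[l]] <- gr$dW
        dbc[[l]] <- gr$db
        da <- gr$dA
      }
      t <- t + 1L
      upd <- nn_update(c(Wc, bc, fcn$W, fcn$b),
                       c(dWc, dbc, bk$dW, bk$db), opt, lr, t)
      opt <- upd$opt
      Wc <- upd$params[1:3]
      bc <- upd$params[4:6]
      nh <- length(fcn$W)
      fcn$W <- upd$params[7:(6 + nh)]
      fcn$b <- upd$params[(7 + nh):(6 + 2L * nh)]
    }
  }
  list(Wc = Wc, bc = bc, fcn = fcn, J = J, N = N, p_head = p_head,
       n_filters = n_filters)
}

cnn2_predict <- function(fit, x) {
  nb <- dim(x)[1]
  a <- array(x, c(nb, fit$J, fit$N, 1L))
  for (l in 1:3) {
    a <- maxpool2d_forward(relu(conv2d_forward(a, fit$Wc[[l]],
                                               fit$bc[[l]])$out))$out
  }
  flat <- matrix(a, nb, fit$p_head)
  argmax01(fcn_forward(fit$fcn, flat)$a[[length(fit$fcn$W) + 1L]])
}

nn_update <- function(params, grads, opt, lr, t) {
  for (i in seq_along(params)) {
    up <- adam_step(params[[i]], grads[[i]], opt[[i]], lr, t)
    params[[i]] <- up$param
    opt[[i]] <- up$state
  }
  list(params = params, opt = opt)
}
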