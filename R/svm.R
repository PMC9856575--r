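# Support vector machine with Gaussian RBF kernel, trained by sequential
# minimal optimization (simplified SMO: random second working-set choice,
# KKT tolerance stopping). Self-contained because no SVM library is
# assumed to be present at run time.

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

smo_fit <- function(K, y, C, tol = 1e-3, max_passes = 10L,
                    max_iter = 10000L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  passes <- 0L
  iter <- 0L
  fcache <- function() as.vector(K %*% (alpha * y)) + b
  while (passes < max_passes && iter < max_iter) {
    iter <- iter + 1L
    changed <- 0L
    f <- fcache()
    for (i in seq_len(n)) {
      ei <- f[i] - y[i]
      if ((y[i] * ei < -tol && alpha[i] < C) ||
          (y[i] * ei > tol && alpha[i] > 0)) {
        j <- sample.int(n - 1L, 1L)
        if (j >= i) j <- j + 1L
        ej <- f[j] - y[j]
        ai_old <- alpha[i]
        aj_old <- alpha[j]
        if (y[i] != y[j]) {
          lo <- max(0, aj_old - ai_old)
          hi <- min(C, C + aj_old - ai_old)
        } else {
          lo <- max(0, ai_old + aj_old - C)
          hi <- min(C, ai_old + aj_old)
        }
        if (lo >= hi) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (ei - ej) / eta
        aj <- min(hi, max(lo, aj))
        if (abs(aj - aj_old) < 1e-5) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        b1 <- b - ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        alpha[i] <- ai
        alpha[j] <- aj
        b_new <- if (ai > 0 && ai < C) b1
                 else if (aj > 0 && aj < C) b2
                 else (b1 + b2) / 2
        f <- f + y[i] * (ai - ai_old) * K[, i] +
          y[j] * (aj - aj_old) * K[, j] + (b_new - b)
        b <- b_new
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

svm_fit <- function(x, y01, C, gamma, inner_folds = 3L, tol = 1e-3,
                    max_passes = 10L) {
  y <- ifelse(y01 == 1L, 1, -1)
  if (identical(gamma, "scale")) {
    # 1 / (p * mean feature variance), i.e. 1/p on standardized features
    gamma <- 1 / (ncol(x) * max(mean(apply(x, 2, stats::var)), 1e-12))
  }
  # grid search with stratified inner CV when C or gamma has > 1 candidate
  if (length(C) > 1L || length(gamma) > 1L) {
    grid <- expand.grid(C = C, gamma = gamma)
    folds <- stratified_folds(y01, inner_folds)
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(folds, function(te) {
        tr <- setdiff(seq_along(y), te)
        fit <- svm_fit(x[tr, , drop = FALSE], y01[tr], grid$C[g],
                       grid$gamma[g], tol = tol, max_passes = max_passes)
        mean(svm_predict(fit, x[te, , drop = FALSE]) == y01[te])
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(acc)  # first max: smaller C, then smaller gamma
    C <- grid$C[best]
    gamma <- grid$gamma[best]
  }
  K <- rbf_kernel(x, x, gamma)
  fit <- smo_fit(K, y, C, tol = tol, max_passes = max_passes)
  sv <- fit$alpha > 1e-8
  list(x = x[sv, , drop = FALSE], coef = (fit$alpha * y)[sv], b = fit$b,
       C = C, gamma = gamma)
}

svm_predict <- function(fit, xnew) {
  score <- if (nrow(fit$x) == 0L) {
    rep(fit$b, nrow(xnew))
  } else {
    as.vector(rbf_kernel(xnew, fit$x, fit$gamma) %*% fit$coef) + fit$b
  }
  as.integer(score > 0)  # ties (score == 0) go to the lower class index
}

# Stratified k-fold index sets over the current RNG stream.
stratified_folds <- function(y, k) {
  folds <- vector("list", k)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    bin <- factor(rep_len(seq_len(k), length(idx)), levels = seq_len(k))
    part <- split(idx, bin)
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], part[[f]])
  }
  lapply(folds, sort)
}
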