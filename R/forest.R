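# Random forest of entropy-split CART trees with per-split feature
# subsampling (mtry) and bootstrap resampling, built from scratch since no
# tree library is assumed present. Binary classification only; class
# labels are 0/1 internally, ties in votes go to class 0.

entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# vectorized binary entropy from class counts (0 log 0 := 0)
xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

entropy2_counts <- function(c0, c1) {
  tot <- c0 + c1
  p0 <- ifelse(tot > 0, c0 / tot, 0)
  -(xlog2(p0) + xlog2(1 - p0))
}

# Best split of one node over a feature subset; returns NULL when no split
# improves the entropy criterion under the min-leaf constraint.
best_split <- function(x, y, feats, min_leaf) {
  n <- length(y)
  parent <- entropy(tabulate(y + 1L, 2L))
  best <- NULL
  best_gain <- 1e-12
  for (f in feats) {
    v <- x[, f]
    ord <- order(v)
    vs <- v[ord]
    cum1 <- cumsum(y[ord])
    tot1 <- cum1[n]
    # candidate cut between consecutive distinct values
    cand <- which(diff(vs) > 0)
    cand <- cand[cand >= min_leaf & (n - cand) >= min_leaf]
    if (length(cand) == 0L) next
    nl <- cand
    l1 <- cum1[cand]
    hl <- entropy2_counts(nl - l1, l1)
    hr <- entropy2_counts((n - nl) - (tot1 - l1), tot1 - l1)
    gain <- parent - (nl * hl + (n - nl) * hr) / n
    i <- which.max(gain)
    if (gain[i] > best_gain) {
      best_gain <- gain[i]
      best <- list(feature = f,
                   threshold = (vs[cand[i]] + vs[cand[i] + 1L]) / 2)
    }
  }
  best
}

grow_tree <- function(x, y, mtry, min_split, min_leaf, max_depth,
                      depth = 0L) {
  n <- length(y)
  n1 <- sum(y)
  if (n1 == 0L || n1 == n || n < min_split || depth >= max_depth) {
    return(list(leaf = TRUE, class = as.integer(n1 > n - n1)))
  }
  feats <- sample.int(ncol(x), min(mtry, ncol(x)))
  sp <- best_split(x, y, feats, min_leaf)
  if (is.null(sp)) {
    return(list(leaf = TRUE, class = as.integer(n1 > n - n1)))
  }
  left <- x[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_tree(x[left, , drop = FALSE], y[left], mtry, min_split,
                        min_leaf, max_depth, depth + 1L),
       right = grow_tree(x[!left, , drop = FALSE], y[!left], mtry,
                         min_split, min_leaf, max_depth, depth + 1L))
}

tree_predict <- function(tree, x) {
  out <- integer(nrow(x))
  route <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) {
      out[idx] <<- node$class
      return()
    }
    left <- x[idx, node$feature] <= node$threshold
    route(node$left, idx[left])
    route(node$right, idx[!left])
  }
  route(tree, seq_len(nrow(x)))
  out
}

rf_fit <- function(x, y01, n_trees = 10L, max_depth = 475L, min_split = 3L,
                   min_leaf = 1L, mtry = NULL) {
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  trees <- lapply(seq_len(n_trees), function(t) {
    boot <- sample.int(nrow(x), replace = TRUE)
    grow_tree(x[boot, , drop = FALSE], y01[boot], mtry, min_split,
              min_leaf, max_depth)
  })
  list(trees = trees, n_trees = n_trees)
}

rf_predict <- function(fit, xnew) {
  votes <- Reduce(`+`, lapply(fit$trees, tree_predict, x = xnew))
  as.integer(votes > fit$n_trees / 2)  # tie -> class 0
}

# k-nearest neighbour with Euclidean metric; majority vote among the k
# nearest training points, vote ties to the lower class index, distance
# ties broken by training-set order (stable).
knn_fit <- function(x, y01, k = 20L) {
  list(x = x, y = y01, k = min(k, nrow(x)))
}

knn_predict <- function(fit, xnew) {
  d2 <- outer(rowSums(xnew^2), rowSums(fit$x^2), "+") -
    2 * tcrossprod(xnew, fit$x)
  vapply(seq_len(nrow(xnew)), function(i) {
    nn <- order(d2[i, ])[seq_len(fit$k)]
    as.integer(sum(fit$y[nn]) > fit$k / 2)  # tie -> class 0
  }, integer(1))
}
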