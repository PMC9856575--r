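#' Single-trial ERP ensemble
#'
#' Container for the epoched single trials (1-ERPs) of one
#' (subject, channel, class) cell: an `n_trials x N` matrix of voltages
#' (microvolts) at sampling rate `fs`.
#'
#' @param trials numeric matrix, one trial per row, all entries finite.
#' @param fs sampling rate in Hz.
#' @param subject,channel,class optional labels carried through the
#'   pipeline and into accuracy records.
#' @return object of class `"trial_ensemble"`.
#' @export
trial_ensemble <- function(trials, fs, subject = NA, channel = NA,
                           class = NA) {
  trials <- as.matrix(trials)
  if (nrow(trials) < 1L) stop("ensemble must contain at least one trial")
  if (!all(is.finite(trials))) stop("trials contain non-finite entries")
  if (!is.numeric(fs) || fs <= 0) stop("'fs' must be positive")
  structure(
    list(trials = trials, fs = fs,
         labels = list(subject = subject, channel = channel, class = class)),
    class = "trial_ensemble"
  )
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf(
    "<trial_ensemble> %d trials x %d samples @ %g Hz (subject %s, channel %s, class %s)\n",
    nrow(x$trials), ncol(x$trials), x$fs,
    x$labels$subject, x$labels$channel, x$labels$class))
  invisible(x)
}

#' Generate an m-subsample-averaged (m-SA) ERP ensemble
#'
#' Repeats `n_out` times: draw a subsample of `m` distinct trials without
#' replacement, average them into one m-ERP, and replace the subsample
#' before the next draw. Distinct m-ERPs may therefore share source trials
#' (that is what lets the ensemble grow beyond `n_trials / m`), but no
#' single m-ERP ever uses the same trial twice. The source-trial indices of
#' every m-ERP are recorded so train/test exclusivity can be audited.
#'
#' `m` may be a vector (recycled to `n_out`) to build mixed-m ensembles.
#'
#' @param ensemble a [trial_ensemble()].
#' @param m averaging parameter(s), each in `[1, n_trials]`.
#' @param n_out number of m-ERPs to generate.
#' @param seed optional integer seed for reproducibility.
#' @param unique_subsamples if `TRUE`, redraw on duplicated subsamples
#'   (off by default; duplicates are accepted as an inherent property of
#'   the resampling scheme).
#' @return object of class `"merp_ensemble"`: list with `merps`
#'   (`n_out x N` matrix), `m`, `source_indices` (list of integer vectors),
#'   `fs`, `labels`.
#' @export
msa_generate <- function(ensemble, m, n_out, seed = NULL,
                         unique_subsamples = FALSE) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  omega0 <- nrow(ensemble$trials)
  if (n_out < 1L) stop("'n_out' must be >= 1")
  m <- as.integer(rep_len(m, n_out))
  if (any(m < 1L) || any(m > omega0)) {
    stop(sprintf("invalid averaging parameter: need 1 <= m <= %d", omega0))
  }
  if (!is.null(seed)) set.seed(seed)
  src <- vector("list", n_out)
  seen <- character(0)
  for (i in seq_len(n_out)) {
    repeat {
      idx <- sort(sample.int(omega0, m[i], replace = FALSE))
      key <- paste(idx, collapse = ",")
      if (!unique_subsamples || !(key %in% seen)) break
    }
    seen <- c(seen, key)
    src[[i]] <- idx
  }
  merps <- t(vapply(src, function(idx) {
    colMeans(ensemble$trials[idx, , drop = FALSE])
  }, numeric(ncol(ensemble$trials))))
  structure(
    list(merps = merps, m = m, source_indices = src, fs = ensemble$fs,
         labels = ensemble$labels),
    class = "merp_ensemble"
  )
}

#' @export
print.merp_ensemble <- function(x, ...) {
  cat(sprintf("<merp_ensemble> %d m-ERPs x %d samples, m in {%s}\n",
              nrow(x$merps), ncol(x$merps),
              paste(sort(unique(x$m)), collapse = ", ")))
  invisible(x)
}

#' Partition trial indices into cross-validation folds
#'
#' Randomly permutes `1:n_trials` and splits into `k` disjoint folds
#' covering all indices. When `k` does not divide `n_trials` the fold sizes
#' differ by at most one (the first `n_trials %% k` folds get the extra
#' trial).
#'
#' @param n_trials number of trials.
#' @param k number of folds, `1 <= k <= n_trials`.
#' @param seed optional integer seed.
#' @return list of `k` integer index vectors.
#' @export
partition_folds <- function(n_trials, k, seed = NULL) {
  if (k < 1L) stop("'k' must be >= 1")
  if (k > n_trials) stop("'k' cannot exceed the number of trials")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n_trials)
  sizes <- rep(n_trials %/% k, k) + c(rep(1L, n_trials %% k),
                                      rep(0L, k - n_trials %% k))
  unname(split(perm, rep(seq_len(k), times = sizes)))
}

#' Build one cross-validated m-SA run
#'
#' Implements the leakage-free protocol: for every fold, training m-ERPs
#' are generated exclusively from the trials of the `k - 1` training folds
#' and test m-ERPs exclusively from the held-out fold, so no single trial
#' contributes to both sides. Defaults mirror the design in which each
#' class contributes as many m-ERPs as it has source trials in the
#' respective partition (e.g. 195 trials, 5 folds, m = 4 gives 156 training
#' and 39 test 4-ERPs per class per fold).
#'
#' @param ensembles named list of per-class [trial_ensemble()] objects
#'   (same trial length).
#' @param m averaging parameter (scalar or vector, see [msa_generate()]).
#' @param k number of folds, `>= 2`.
#' @param n_train,n_test m-ERPs generated per class per fold; `NULL`
#'   (default) uses the source-trial counts of the respective partitions.
#' @param seed integer master seed; per-(class, fold, role) substreams are
#'   derived deterministically.
#' @return object of class `"run_plan"`: list with `folds` (per class, the
#'   fold index sets), `fold_data` (per fold: `train` and `test` named
#'   lists of `merp_ensemble`s whose `source_indices` refer to the original
#'   ensembles), `m`, `k`, `seed`.
#' @export
build_run <- function(ensembles, m, k, n_train = NULL, n_test = NULL,
                      seed = 1L) {
  if (is.null(names(ensembles)) || any(names(ensembles) == "")) {
    stop("'ensembles' must be a named list of per-class trial ensembles")
  }
  if (k < 2L) stop("protocol requires k >= 2 folds (no held-out data otherwise)")
  ns <- vapply(ensembles, function(e) ncol(e$trials), integer(1))
  if (length(unique(ns)) != 1L) stop("trial lengths differ across classes")
  folds <- lapply(seq_along(ensembles), function(ci) {
    partition_folds(nrow(ensembles[[ci]]$trials), k,
                    seed = derive_seed(seed, 1L, ci))
  })
  names(folds) <- names(ensembles)
  max_m <- max(as.integer(m))
  fold_data <- lapply(seq_len(k), function(f) {
    tr <- lapply(seq_along(ensembles), function(ci) {
      idx <- sort(unlist(folds[[ci]][-f], use.names = FALSE))
      subsample_merps(ensembles[[ci]], idx, m,
                      if (is.null(n_train)) length(idx) else n_train,
                      derive_seed(seed, 2L, ci, f), "train")
    })
    te <- lapply(seq_along(ensembles), function(ci) {
      idx <- sort(folds[[ci]][[f]])
      if (max_m > length(idx)) {
        stop("averaging parameter m exceeds the held-out fold size")
      }
      subsample_merps(ensembles[[ci]], idx, m,
                      if (is.null(n_test)) length(idx) else n_test,
                      derive_seed(seed, 3L, ci, f), "test")
    })
    names(tr) <- names(te) <- names(ensembles)
    list(train = tr, test = te)
  })
  structure(list(folds = folds, fold_data = fold_data, m = m, k = k,
                 seed = seed),
            class = "run_plan")
}

# m-SA restricted to a subset of trials; source indices are mapped back to
# the original ensemble's numbering for leakage audits.
subsample_merps <- function(ensemble, idx, m, n_out, seed, origin) {
  sub <- trial_ensemble(ensemble$trials[idx, , drop = FALSE], ensemble$fs,
                        ensemble$labels$subject, ensemble$labels$channel,
                        ensemble$labels$class)
  me <- msa_generate(sub, m, n_out, seed = seed)
  me$source_indices <- lapply(me$source_indices, function(s) idx[s])
  me$origin <- origin
  me
}

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer hash (multiplicative congruential walk modulo
#' 2^31 - 1) of a master seed and a tuple of stream labels. Used so that
#' every run / class / fold of an experiment draws from its own
#' reproducible substream.
#'
#' @param master integer master seed.
#' @param ... integer stream labels.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  mod <- 2147483647
  s <- as.double(abs(as.integer(master)) %% mod)
  for (k in c(...)) {
    s <- (s * 48271 + as.double(k) + 1) %% mod
  }
  as.integer(s)
}
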