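#' Run a cross-validated scalogram-approach comparison
#'
#' Orchestrates the full protocol for one (subject, channel) binary
#' dataset: for every run, the single trials of each class are freshly
#' partitioned into `k_folds` folds; per fold, m-subsample-averaged
#' ERPs are generated separately from the training and held-out trials
#' (no single-trial leakage); one power scalogram is computed per m-ERP;
#' the S/Z/V/V-bar feature sets are extracted from that same scalogram
#' instance; and every requested classifier is trained and evaluated on
#' identical training/test splits. The per-run accuracy of a
#' (classifier, approach) pair is the pooled fraction of correctly
#' classified test m-ERPs across the folds.
#'
#' The matrix-input family (`cnn2`) is evaluated only on the `S` and `Z`
#' approaches, whose scalograms are equal-row matrices.
#'
#' @param class_a,class_b per-class [trial_ensemble()]s (equal trial
#'   length and sampling rate).
#' @param specs named list of [classifier_spec()]s (names become the
#'   classifier labels in the records).
#' @param grid a [frequency_grid()].
#' @param params a [wavelet_params()].
#' @param approaches subset of `c("S", "Z", "V", "Vbar")`.
#' @param m averaging parameter (default 4).
#' @param k_folds folds per run (default 5; must be `>= 2`).
#' @param n_runs number of runs (default 50).
#' @param master_seed integer seed; all fold partitions and subsample
#'   draws derive from it.
#' @param n_train,n_test m-ERPs per class per fold (default: the source
#'   trial counts of the respective partitions).
#' @param kind scalogram kind (default `"power"`).
#' @param verbose print per-run progress.
#' @return data frame of class `"accuracy_records"` with columns
#'   `subject`, `channel`, `approach`, `classifier`, `run`, `accuracy`.
#' @seealso [summarize_records()], [relative_improvement()],
#'   [confidence_interval()]
#' @export
run_experiment <- function(class_a, class_b, specs, grid,
                           params = wavelet_params(),
                           approaches = c("S", "Z", "V", "Vbar"),
                           m = 4L, k_folds = 5L, n_runs = 50L,
                           master_seed = 1L, n_train = NULL, n_test = NULL,
                           kind = "power", verbose = FALSE) {
  approaches <- match.arg(approaches, c("S", "Z", "V", "Vbar"),
                          several.ok = TRUE)
  if (k_folds < 2L) {
    stop("protocol requires k_folds >= 2 (a single fold leaves no held-out data)")
  }
  if (is.null(names(specs)) || any(names(specs) == "")) {
    stop("'specs' must be a named list of classifier specifications")
  }
  stopifnot(inherits(class_a, "trial_ensemble"),
            inherits(class_b, "trial_ensemble"))
  if (ncol(class_a$trials) != ncol(class_b$trials) ||
      class_a$fs != class_b$fs) {
    stop("class ensembles must share trial length and sampling rate")
  }
  fs <- class_a$fs
  n <- ncol(class_a$trials)
  coi <- compute_coi(grid, n, fs, params)
  mask <- coi_mask(coi)
  sel_v <- as.vector(t(mask)) > 0
  records <- list()
  for (run in seq_len(n_runs)) {
    rp <- build_run(list(a = class_a, b = class_b), m, k_folds,
                    n_train = n_train, n_test = n_test,
                    seed = derive_seed(master_seed, 7L, run))
    correct <- list()
    total <- list()
    for (fold in seq_len(k_folds)) {
      fd <- rp$fold_data[[fold]]
      xtr <- rbind(fd$train$a$merps, fd$train$b$merps)
      xte <- rbind(fd$test$a$merps, fd$test$b$merps)
      ytr <- rep(c("a", "b"), c(nrow(fd$train$a$merps),
                                nrow(fd$train$b$merps)))
      yte <- rep(c("a", "b"), c(nrow(fd$test$a$merps),
                                nrow(fd$test$b$merps)))
      gtr <- cwt_scalogram_batch(xtr, fs, grid, params, kind)
      gte <- cwt_scalogram_batch(xte, fs, grid, params, kind)
      ftr <- feature_sets(gtr, mask, sel_v, approaches)
      fte <- feature_sets(gte, mask, sel_v, approaches)
      for (cl in names(specs)) {
        spec <- specs[[cl]]
        for (app in approaches) {
          if (spec$family == "cnn2" && app %in% c("V", "Vbar")) next
          if (spec$family == "cnn2") {
            xtr_in <- rowmajor_to_array(ftr[[app]], grid$J, n)
            xte_in <- rowmajor_to_array(fte[[app]], grid$J, n)
          } else {
            xtr_in <- ftr[[app]]
            xte_in <- fte[[app]]
          }
          model <- train_classifier(build_classifier(spec),
                                    xtr_in, ytr, approach = app)
          pred <- predict(model, xte_in, approach = app)
          key <- paste(cl, app, sep = ".")
          correct[[key]] <- (correct[[key]] %||% 0L) + sum(pred == yte)
          total[[key]] <- (total[[key]] %||% 0L) + length(yte)
        }
      }
    }
    for (key in names(correct)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
      records[[length(records) + 1L]] <- data.frame(
        subject = class_a$labels$subject, channel = class_a$labels$channel,
        approach = parts[2L], classifier = parts[1L], run = run,
        accuracy = correct[[key]] / total[[key]])
    }
    if (verbose) {
      message(sprintf("run %d/%d done", run, n_runs))
    }
  }
  out <- do.call(rbind, records)
  class(out) <- c("accuracy_records", "data.frame")
  out
}

# Assemble per-approach inputs from a list of scalograms sharing one COI:
# vector approaches become n x p matrices, cnn2 approaches (S, Z) become
# n x J x N arrays. All approaches reuse the identical scalogram objects.
feature_sets <- function(gs, mask, sel_v, approaches) {
  n <- length(gs)
  s_mat <- t(vapply(gs, function(g) as.vector(t(g)), numeric(length(mask))))
  out <- list()
  if ("S" %in% approaches) out$S <- s_mat
  if ("Z" %in% approaches) {
    zm <- s_mat
    zm[, !sel_v] <- 0
    out$Z <- zm
  }
  if ("V" %in% approaches) out$V <- s_mat[, sel_v, drop = FALSE]
  if ("Vbar" %in% approaches) out$Vbar <- s_mat[, !sel_v, drop = FALSE]
  out
}

# Inverse of the row-major flattening: n x (J*N) feature matrix back to an
# n x J x N array of scalograms.
rowmajor_to_array <- function(x, J, N) {
  aperm(array(x, c(nrow(x), N, J)), c(1, 3, 2))
}

#' Relative improvement of one approach over another
#'
#' `Gamma_{B,A} = (alpha_B - alpha_A) / alpha_A * 100`, the percent
#' accuracy gain of approach B over approach A.
#'
#' @param alpha_b,alpha_a accuracies (any common scale, e.g. percent);
#'   `alpha_a` must be positive.
#' @return relative improvement in percent.
#' @examples
#' relative_improvement(70.95, 58.33)  # 21.64
#' @export
relative_improvement <- function(alpha_b, alpha_a) {
  if (any(alpha_a <= 0)) {
    stop("relative improvement is undefined for alpha_a <= 0")
  }
  (alpha_b - alpha_a) / alpha_a * 100
}

#' Student-t confidence interval for a mean accuracy
#'
#' @param accuracies numeric vector (`>= 2` values).
#' @param level confidence level (default 0.95).
#' @return named vector `c(low, high)`: mean plus/minus the t-quantile
#'   times the standard error.
#' @export
confidence_interval <- function(accuracies, level = 0.95) {
  n <- length(accuracies)
  if (n < 2L) stop("need at least two values for a confidence interval")
  mu <- mean(accuracies)
  se <- stats::sd(accuracies) / sqrt(n)
  q <- stats::qt((1 + level) / 2, df = n - 1L)
  c(low = mu - q * se, high = mu + q * se)
}

#' Summarize accuracy records into an approach-by-classifier table
#'
#' Each cell is the mean accuracy of one (classifier, approach) pair over
#' all its records (runs, and subjects/channels when present). The
#' `Global Average` row is the mean of the vector-input families
#' (`svm`, `rf`, `knn`, `mlp`, `cnn1`); the matrix-input `cnn2` family is
#' excluded from it (and flagged), since it cannot be evaluated on the
#' cropped approach.
#'
#' @param records an `"accuracy_records"` data frame (see
#'   [run_experiment()]); accuracies may be fractions or percent.
#' @param percent convert fractional accuracies to percent (default
#'   `TRUE` when all accuracies are `<= 1`).
#' @return object of class `"summary_table"`: data frame, one row per
#'   classifier plus `Global Average`, one column per approach. Raw cell
#'   values are kept at full precision; printing rounds to 2 decimals.
#' @export
summarize_records <- function(records, percent = NULL) {
  if (!all(c("approach", "classifier", "accuracy") %in% names(records))) {
    stop("records need columns approach, classifier, accuracy")
  }
  if (is.null(percent)) percent <- all(records$accuracy <= 1)
  acc <- records$accuracy * if (percent) 100 else 1
  cells <- stats::aggregate(
    acc, by = list(classifier = records$classifier,
                   approach = records$approach), FUN = mean)
  classifiers <- unique(records$classifier)
  approaches <- unique(records$approach)
  tab <- matrix(NA_real_, length(classifiers), length(approaches),
                dimnames = list(classifiers, approaches))
  for (i in seq_len(nrow(cells))) {
    tab[cells$classifier[i], cells$approach[i]] <- cells$x[i]
  }
  if (anyNA(tab)) {
    missing_cells <- which(is.na(tab), arr.ind = TRUE)
    warning("missing cells (not imputed): ",
            paste(rownames(tab)[missing_cells[, 1]],
                  colnames(tab)[missing_cells[, 2]],
                  sep = "/", collapse = ", "))
  }
  vec_fams <- intersect(rownames(tab), c("svm", "rf", "knn", "mlp", "cnn1"))
  global <- colMeans(tab[vec_fams, , drop = FALSE])
  out <- as.data.frame(rbind(tab, `Global Average` = global))
  attr(out, "vector_families") <- vec_fams
  attr(out, "excluded") <- setdiff(rownames(tab), vec_fams)
  class(out) <- c("summary_table", "data.frame")
  out
}

#' @export
print.summary_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(lapply(x, round, digits = digits),
                     row.names = rownames(x), check.names = FALSE)
  print(y)
  excl <- attr(x, "excluded")
  if (length(excl)) {
    cat("* Global Average excludes:", paste(excl, collapse = ", "), "\n")
  }
  invisible(x)
}
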