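#' Classifier specification
#'
#' Describes one of the six supported classifier families together with its
#' hyperparameters, input form and training seed. Defaults follow the
#' reference configuration used for the scalogram comparison experiments:
#'
#' * `svm`: Gaussian RBF kernel; `C` and `gamma` may be vectors, in which
#'   case the best pair is picked by an exhaustive grid search with
#'   stratified inner cross-validation on the training data only
#'   (defaults: `C = c(0.1, 1, 10, 100)`, `gamma = 10^(-4:-1)`,
#'   `inner_folds = 3`); `gamma = "scale"` resolves to
#'   `1 / (p * mean feature variance)`.
#' * `rf`: 10 entropy-split trees, maximum depth 475, minimum 3 samples to
#'   split, minimum leaf size 1, `mtry = floor(sqrt(p))` features per
#'   split, bootstrap resampling.
#' * `knn`: Euclidean metric, `k = 20`.
#' * `mlp`: fully connected 1024/512/256/2 all-sigmoid network, Adam with
#'   learning rate 0.001, 50 epochs, dropout 0.15, batch size 32.
#' * `cnn1`: vector input treated as a one-channel sequence; three
#'   length-9 32-filter ReLU "same" convolution layers, one 2x1 max pool
#'   (stride 2), then a 1024/512/256/2 head (sigmoid/sigmoid/sigmoid/
#'   softmax); Adam 0.001, 50 epochs, dropout 0.15, batch 32.
#' * `cnn2`: matrix input (`J x N` scalogram); three 3x3 32-filter ReLU
#'   "same" convolution layers, each followed by 2x2 max pooling
#'   (stride 2), then the same head and training options.
#'
#' `cnn2` requires equal-row matrix input and therefore cannot consume the
#' ragged V (or complement) representations; attempting to do so is an
#' error rather than a silent fallback.
#'
#' @param family one of `"svm"`, `"rf"`, `"knn"`, `"mlp"`, `"cnn1"`,
#'   `"cnn2"`.
#' @param hyperparameters named list overriding the family defaults.
#' @param input_form `"vector"` or `"matrix"`; defaults to `"matrix"` for
#'   `cnn2` and `"vector"` otherwise.
#' @param seed integer seed controlling every random element of training
#'   (grid-search folds, bootstrap draws, weight initialization, dropout,
#'   batch shuffling).
#' @param standardize fit a per-feature standardizer on the training set
#'   and apply it at prediction time (default `TRUE`).
#' @return object of class `"classifier_spec"`.
#' @export
classifier_spec <- function(family = c("svm", "rf", "knn", "mlp", "cnn1",
                                       "cnn2"),
                            hyperparameters = list(), input_form = NULL,
                            seed = 1L, standardize = TRUE) {
  family <- match.arg(family)
  defaults <- switch(family,
    svm = list(C = c(0.1, 1, 10, 100), gamma = 10^seq(-4, -1),
               inner_folds = 3L, tol = 1e-3, max_passes = 10L),
    rf = list(n_trees = 10L, max_depth = 475L, min_split = 3L,
              min_leaf = 1L, mtry = NULL, criterion = "entropy"),
    knn = list(k = 20L, metric = "euclidean"),
    mlp = list(hidden = c(1024L, 512L, 256L), lr = 0.001, epochs = 50L,
               dropout = 0.15, batch_size = 32L),
    cnn1 = list(n_filters = 32L, kernel = 9L, hidden = c(1024L, 512L, 256L),
                lr = 0.001, epochs = 50L, dropout = 0.15, batch_size = 32L),
    cnn2 = list(n_filters = 32L, kernel = c(3L, 3L),
                hidden = c(1024L, 512L, 256L), lr = 0.001, epochs = 50L,
                dropout = 0.15, batch_size = 32L)
  )
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameters for family '", family, "': ",
         paste(unknown, collapse = ", "))
  }
  hp <- utils::modifyList(defaults, hyperparameters)
  if (is.null(input_form)) input_form <- if (family == "cnn2") "matrix" else "vector"
  input_form <- match.arg(input_form, c("vector", "matrix"))
  if (family == "cnn2" && input_form != "matrix") {
    stop("cnn2 requires matrix input (equal-row scalograms)")
  }
  structure(list(family = family, hyperparameters = hp,
                 input_form = input_form, seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

#' Build an untrained classifier from a specification
#'
#' @param spec a [classifier_spec()].
#' @return object of class `"coi_classifier"` with `fitted = NULL`.
#' @export
build_classifier <- function(spec) {
  if (!inherits(spec, "classifier_spec")) spec <- do.call(classifier_spec, spec)
  structure(list(spec = spec, fitted = NULL, scaler = NULL,
                 fingerprint = NULL, levels = NULL),
            class = "coi_classifier")
}

#' @export
print.coi_classifier <- function(x, ...) {
  cat(sprintf("<coi_classifier> family %s (%s input), %s\n", x$spec$family,
              x$spec$input_form,
              if (is.null(x$fitted)) "untrained" else "trained"))
  invisible(x)
}

#' Train a classifier
#'
#' Fits the model configured by the spec on a training set. Vector-input
#' families take an `n x p` feature matrix; `cnn2` takes an
#' `n x J x N` array (or list of equal-dimension matrices). Training is
#' fully determined by `spec$seed`. The feature layout (dimensions plus the
#' scalogram approach tag, when given) is fingerprinted, and prediction
#' later refuses inputs with a different layout.
#'
#' @param model a [build_classifier()] result (an untrained or re-trainable
#'   `"coi_classifier"`).
#' @param x training features.
#' @param y class labels (two distinct values; the first sorted level is
#'   the tie-break class).
#' @param approach optional approach tag (`"S"`, `"Z"`, `"V"`, `"Vbar"`)
#'   recorded in the fingerprint; `cnn2` rejects `"V"`/`"Vbar"`.
#' @return the trained `"coi_classifier"`.
#' @export
train_classifier <- function(model, x, y, approach = NULL) {
  if (inherits(model, "classifier_spec")) model <- build_classifier(model)
  spec <- model$spec
  lev <- sort(unique(as.character(y)))
  if (length(lev) < 2L) stop("training set contains a single class")
  if (length(lev) > 2L) stop("only binary classification is supported")
  y01 <- as.integer(as.character(y) == lev[2L])
  if (spec$family == "cnn2") {
    if (!is.null(approach) && approach %in% c("V", "Vbar")) {
      stop("unsupported input: cnn2 requires equal-row matrices and cannot ",
           "consume the ragged ", approach, " representation")
    }
    x <- as_input_array(x)
    if (length(y01) != dim(x)[1]) stop("x and y sizes disagree")
    set.seed(spec$seed)
    scaler <- NULL
    if (spec$standardize) {
      flat <- matrix(x, dim(x)[1])
      scaler <- fit_standardizer(flat)
      x <- array(apply_standardizer(scaler, flat), dim(x))
    }
    hp <- spec$hyperparameters
    fitted <- cnn2_fit(x, y01, n_filters = hp$n_filters, kernel = hp$kernel,
                       lr = hp$lr, epochs = hp$epochs, dropout = hp$dropout,
                       batch_size = hp$batch_size, hidden = hp$hidden)
    fp <- list(approach = approach, dims = dim(x)[-1])
  } else {
    x <- as.matrix(x)
    if (length(y01) != nrow(x)) stop("x and y sizes disagree")
    set.seed(spec$seed)
    scaler <- NULL
    if (spec$standardize) {
      scaler <- fit_standardizer(x)
      x <- apply_standardizer(scaler, x)
    }
    hp <- spec$hyperparameters
    fitted <- switch(spec$family,
      svm = svm_fit(x, y01, C = hp$C, gamma = hp$gamma,
                    inner_folds = hp$inner_folds, tol = hp$tol,
                    max_passes = hp$max_passes),
      rf = rf_fit(x, y01, n_trees = hp$n_trees, max_depth = hp$max_depth,
                  min_split = hp$min_split, min_leaf = hp$min_leaf,
                  mtry = hp$mtry),
      knn = knn_fit(x, y01, k = hp$k),
      mlp = mlp_fit(x, y01, hidden = hp$hidden, lr = hp$lr,
                    epochs = hp$epochs, dropout = hp$dropout,
                    batch_size = hp$batch_size),
      cnn1 = cnn1_fit(x, y01, n_filters = hp$n_filters, kernel = hp$kernel,
                      lr = hp$lr, epochs = hp$epochs, dropout = hp$dropout,
                      batch_size = hp$batch_size, hidden = hp$hidden)
    )
    fp <- list(approach = approach, dims = ncol(x))
  }
  model$fitted <- fitted
  model$scaler <- scaler
  model$fingerprint <- fp
  model$levels <- lev
  model
}

#' Predict class labels
#'
#' @param object a trained `"coi_classifier"`.
#' @param newdata features with the same layout as the training set.
#' @param approach optional approach tag checked against the training
#'   fingerprint.
#' @param ... unused.
#' @return vector of predicted labels (training levels).
#' @export
predict.coi_classifier <- function(object, newdata, approach = NULL, ...) {
  if (is.null(object$fitted)) stop("classifier has not been trained")
  fp <- object$fingerprint
  if (!is.null(approach) && !is.null(fp$approach) &&
      !identical(approach, fp$approach)) {
    stop("feature layout mismatch: model was trained on approach ",
         fp$approach, ", got ", approach)
  }
  if (object$spec$family == "cnn2") {
    x <- as_input_array(newdata)
    if (!identical(as.integer(dim(x)[-1]), as.integer(fp$dims))) {
      stop("feature layout mismatch: input dimensions differ from training")
    }
    if (!is.null(object$scaler)) {
      flat <- apply_standardizer(object$scaler, matrix(x, dim(x)[1]))
      x <- array(flat, dim(x))
    }
    y01 <- cnn2_predict(object$fitted, x)
  } else {
    x <- as.matrix(newdata)
    if (ncol(x) != fp$dims) {
      stop("feature layout mismatch: input dimensions differ from training")
    }
    if (!is.null(object$scaler)) x <- apply_standardizer(object$scaler, x)
    y01 <- switch(object$spec$family,
      svm = svm_predict(object$fitted, x),
      rf = rf_predict(object$fitted, x),
      knn = knn_predict(object$fitted, x),
      mlp = mlp_predict(object$fitted, x),
      cnn1 = cnn1_predict(object$fitted, x)
    )
  }
  object$levels[y01 + 1L]
}

#' Classification accuracy on a test set
#'
#' @param model a trained `"coi_classifier"`.
#' @param x,y test features and labels.
#' @param approach optional approach tag checked against the fingerprint.
#' @return fraction of correctly classified items in `[0, 1]`.
#' @export
evaluate_classifier <- function(model, x, y, approach = NULL) {
  n <- if (is.matrix(x) || inherits(x, "array")) dim(x)[1] else length(x)
  if (is.list(x) && !is.data.frame(x)) n <- length(x)
  if (n == 0L || length(y) == 0L) stop("empty test set")
  pred <- predict(model, x, approach = approach)
  mean(pred == as.character(y))
}

as_input_array <- function(x) {
  if (is.list(x) && !is.array(x)) {
    dims <- lapply(x, dim)
    if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
      stop("matrix inputs must share dimensions")
    }
    arr <- array(0, c(length(x), dims[[1L]]))
    for (i in seq_along(x)) arr[i, , ] <- x[[i]]
    arr
  } else if (length(dim(x)) == 3L) {
    x
  } else {
    stop("cnn2 expects an n x J x N array or a list of equal-size matrices")
  }
}

# Per-feature location/scale fitted on the training set only; constant
# features keep scale 1 so they map to exactly 0.
fit_standardizer <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

apply_standardizer <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$mu, "-"), 2, scaler$sd, "/")
}
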