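#' Scalogram feature vectors: S, Z, V and V-bar
#'
#' The four feature representations derived from a same-mode `J x N`
#' scalogram `G` and its cone of influence:
#'
#' * `s_vector(G)`: the whole scalogram, rows concatenated in ascending band
#'   (storage) order — length `J * N`. The standard representation; mixes
#'   accurate and edge-artifact coefficients.
#' * `z_vector(G, coi)`: the same layout with out-of-COI entries set to
#'   exactly zero — length `J * N`.
#' * `v_vector(G, coi)`: only the in-COI entries, each row's accurate
#'   segment concatenated — length `NV = sum(Nf)`.
#' * `vbar_vector(G, coi)`: the out-of-COI complement — length
#'   `J * N - NV`. Useful as a negative control: these coefficients should
#'   carry no reliable discriminatory information.
#'
#' `v_vector` and `vbar_vector` partition the positions of `s_vector`; their
#' `layout` matrices record the `(band, time)` provenance of every entry in
#' 0-based coordinates.
#'
#' @param G `J x N` nonnegative scalogram matrix (a `"scalogram"` or plain
#'   matrix; a `"cwt_result"` is also accepted).
#' @param coi a [coi_boundary()] matching `G`'s dimensions.
#' @return object of class `"feature_vector"`: list with `values` (numeric),
#'   `layout` (integer matrix, columns `band`, `time`, 0-based) and
#'   `approach` (`"S"`, `"Z"`, `"V"` or `"Vbar"`).
#' @examples
#' g <- matrix(1:6, 2, 3, byrow = TRUE)
#' s_vector(g)$values  # 1 2 3 4 5 6
#' @name scalogram_features
NULL

feature_vector <- function(values, layout, approach) {
  structure(list(values = as.numeric(values), layout = layout,
                 approach = approach),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> approach %s, length %d\n",
              x$approach, length(x$values)))
  invisible(x)
}

as_scalogram_matrix <- function(G) {
  if (inherits(G, "cwt_result")) G <- G$G
  if (!is.matrix(G)) stop("G must be a (J x N) same-mode scalogram matrix")
  if (any(!is.finite(G)) || any(G < 0)) {
    stop("scalogram entries must be finite and nonnegative")
  }
  G
}

row_major_layout <- function(J, N) {
  cbind(band = rep(seq_len(J) - 1L, each = N),
        time = rep.int(seq_len(N) - 1L, J))
}

check_feature_shapes <- function(G, coi) {
  if (nrow(G) != nrow(coi) || ncol(G) != attr(coi, "N")) {
    stop("scalogram and COI boundary dimensions disagree")
  }
}

#' @rdname scalogram_features
#' @export
s_vector <- function(G) {
  G <- as_scalogram_matrix(G)
  feature_vector(as.vector(t(G)), row_major_layout(nrow(G), ncol(G)), "S")
}

#' @rdname scalogram_features
#' @export
z_vector <- function(G, coi) {
  G <- as_scalogram_matrix(G)
  check_feature_shapes(G, coi)
  z <- G * coi_mask(coi)
  fv <- s_vector(z)
  fv$approach <- "Z"
  fv
}

#' @rdname scalogram_features
#' @export
v_vector <- function(G, coi) {
  G <- as_scalogram_matrix(G)
  check_feature_shapes(G, coi)
  if (sum(coi$Nf) == 0L) {
    stop("empty feature set: no scalogram coefficients lie inside the COI")
  }
  pick <- coi_mask(coi) > 0
  sel <- as.vector(t(pick))
  full <- s_vector(G)
  feature_vector(full$values[sel], full$layout[sel, , drop = FALSE], "V")
}

#' @rdname scalogram_features
#' @export
vbar_vector <- function(G, coi) {
  G <- as_scalogram_matrix(G)
  check_feature_shapes(G, coi)
  pick <- coi_mask(coi) > 0
  if (all(pick)) {
    stop("empty feature set: the COI covers the entire scalogram")
  }
  sel <- !as.vector(t(pick))
  full <- s_vector(G)
  feature_vector(full$values[sel], full$layout[sel, , drop = FALSE], "Vbar")
}
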