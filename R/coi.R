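#' Cone-of-influence boundary
#'
#' Constructs a COI description directly from per-band in-COI coefficient
#' counts. Most users should call [compute_coi()], which derives the counts
#' from the wavelet footprints; this constructor exists for externally
#' supplied or published coefficient counts.
#'
#' Coordinates are 0-based and intervals half-open: band `f` of a same-mode
#' `J x N` scalogram is accurate on columns `n_start(f) <= n < n_end(f)`.
#'
#' @param Nf integer vector of in-COI counts per band (ascending band
#'   frequency order, matching the scalogram rows), each in `[0, N]` and
#'   non-decreasing with frequency.
#' @param N signal length in samples.
#' @param frequencies optional band center frequencies (Hz).
#' @param footprint optional per-band kernel footprint lengths `Lf`.
#' @return object of class `"coi_boundary"`: data frame with columns
#'   `frequency`, `footprint`, `n_start`, `n_end`, `Nf`, plus attribute `N`.
#' @seealso [compute_coi()], [quality_rho()], [quality_beta()], [coi_mask()]
#' @export
coi_boundary <- function(Nf, N, frequencies = NULL, footprint = NULL) {
  Nf <- as.integer(Nf)
  N <- as.integer(N)
  if (N < 0L || any(Nf < 0L) || any(Nf > N)) {
    stop("each Nf must lie in [0, N]")
  }
  if (is.unsorted(Nf) && is.unsorted(rev(Nf))) {
    stop("Nf must be monotone in band order ",
         "(lower frequencies have wider footprints, hence fewer accurate ",
         "coefficients)")
  }
  j <- length(Nf)
  if (is.null(footprint)) footprint <- N - Nf + 1L
  # centered placement of the valid interval in same-mode coordinates
  off <- (footprint - 1L) %/% 2L
  n_start <- ifelse(Nf > 0L, off, 0L)
  n_end <- ifelse(Nf > 0L, n_start + Nf, 0L)
  out <- data.frame(
    frequency = if (is.null(frequencies)) rep(NA_real_, j) else frequencies,
    footprint = as.integer(footprint),
    n_start = as.integer(n_start),
    n_end = as.integer(n_end),
    Nf = Nf
  )
  structure(out, class = c("coi_boundary", "data.frame"), N = N)
}

#' Delineate the cone of influence of a same-mode scalogram
#'
#' For each band the truncated wavelet kernel has footprint `Lf` samples;
#' a same-mode coefficient is accurate exactly when that footprint lies
#' entirely inside the observation window, i.e. when the coefficient also
#' appears in the valid-mode convolution output. This gives
#' `Nf = max(0, N - Lf + 1)` accurate coefficients per band, occupying the
#' centered half-open column interval `[(Lf-1)/2, N - (Lf-1)/2)` in 0-based
#' same-mode coordinates. Bands whose footprint exceeds the signal get
#' `Nf = 0`.
#'
#' @param grid a [frequency_grid()].
#' @param N signal length in samples (`>= 1`).
#' @param fs sampling rate in Hz (converts the footprint from seconds to
#'   samples).
#' @param params a [wavelet_params()]; the truncation rule sets the
#'   footprint and hence the COI extent.
#' @return a [coi_boundary()] object, one row per band.
#' @examples
#' g <- frequency_grid(4, 30, n_bands = 12)
#' compute_coi(g, N = 200, fs = 200)
#' @export
compute_coi <- function(grid, N, fs, params = wavelet_params()) {
  N <- as.integer(N)
  if (N < 1L) stop("N must be >= 1")
  lf <- vapply(grid$frequencies, function(f) {
    2L * band_halfwidth_samples(f, fs, params) + 1L
  }, integer(1))
  nf <- pmax(0L, N - lf + 1L)
  coi_boundary(nf, N, frequencies = grid$frequencies, footprint = lf)
}

#' @export
print.coi_boundary <- function(x, ...) {
  cat(sprintf("<coi_boundary> %d bands, N = %d, %d / %d coefficients in COI\n",
              nrow(x), attr(x, "N"), sum(x$Nf), nrow(x) * attr(x, "N")))
  NextMethod()
}

#' Binary in-COI mask
#'
#' @param coi a [coi_boundary()].
#' @return `J x N` 0/1 matrix with ones exactly at in-COI positions.
#' @export
coi_mask <- function(coi) {
  n <- attr(coi, "N")
  m <- matrix(0, nrow(coi), n)
  for (f in seq_len(nrow(coi))) {
    if (coi$Nf[f] > 0L) m[f, (coi$n_start[f] + 1L):coi$n_end[f]] <- 1
  }
  m
}

#' Scalogram coverage ratio rho
#'
#' Fraction of the `J x N` same-mode scalogram coefficients that lie inside
#' the cone of influence: `rho = sum(Nf) / (J * N)`. Higher is better; rho
#' approaches 1 as the signal grows long relative to the wavelet footprints.
#'
#' @param coi a [coi_boundary()] computed for a `J x N` scalogram.
#' @param J,N optional overrides of the scalogram dimensions (default taken
#'   from `coi`).
#' @return fraction in `[0, 1]`.
#' @examples
#' quality_rho(coi_boundary(c(0, 2, 4), N = 4))  # 6/12
#' @export
quality_rho <- function(coi, J = nrow(coi), N = attr(coi, "N")) {
  if (J * N == 0) stop("invalid input: J * N must be positive")
  sum(coi$Nf) / (J * N)
}

#' Scalogram power-capture ratio beta
#'
#' Fraction of the total scalogram power that lies inside the cone of
#' influence: `beta = sum(|W|^2 in COI) / sum(|W|^2)`. A 0/0 ratio (an
#' all-zero coefficient matrix) is defined as 0 with a warning.
#'
#' @param W complex `J x N` same-mode coefficient matrix (or a
#'   `"cwt_result"`).
#' @param coi a [coi_boundary()] with matching dimensions.
#' @return fraction in `[0, 1]`.
#' @export
quality_beta <- function(W, coi) {
  if (inherits(W, "cwt_result")) W <- W$W
  if (!is.matrix(W)) stop("W must be a same-mode (J x N) coefficient matrix")
  if (nrow(W) != nrow(coi) || ncol(W) != attr(coi, "N")) {
    stop("invalid input: W and coi dimensions disagree")
  }
  pow <- Mod(W)^2
  total <- sum(pow)
  if (total == 0) {
    warning("total power is zero; defining beta = 0")
    return(0)
  }
  sum(pow * coi_mask(coi)) / total
}
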