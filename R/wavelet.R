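#' Analytic Morlet wavelet parameters
#'
#' Bundles the tunable constants of the analytic Morlet wavelet
#' \deqn{\Psi(t) = A\, e^{-t^2 / 2\sigma^2}\, e^{j 2 \pi f_0 t}}
#' used throughout the scalogram pipeline. The per-band envelope width is
#' tied to the band center frequency through the `cycles` parameter:
#' `sigma_f = cycles / (2 * pi * f)`, so every band wavelet carries the same
#' number of oscillation cycles under its Gaussian envelope. `A` is always
#' chosen numerically so that the discrete wavelet energy
#' `sum(|Psi|^2) * dt` equals one (unit-energy normalization, which is the
#' discrete counterpart of the `1/sqrt(a)` scale prefactor of the CWT).
#'
#' The Gaussian envelope has infinite support, so a truncation rule decides
#' the finite kernel footprint (and hence the cone of influence):
#' * `"peak2"` (default): truncate where the envelope falls to 2% of its
#'   peak, `|t| <= sigma * sqrt(2 * log(50))`;
#' * `"inv_e"`: truncate at the 1/e envelope point, `|t| <= sigma * sqrt(2)`;
#' * `"half_footprint"`: half of the 2%-of-peak footprint;
#' * `"energy95"`: the symmetric interval containing 95% of the wavelet
#'   energy, `|t| <= qnorm(0.975) * sigma / sqrt(2)`.
#'
#' @param cycles positive number of cycles under the envelope (`f0 * sigma
#'   = cycles / (2 * pi)`); default 6, the conventional analytic Morlet.
#' @param truncation footprint rule, see Details.
#' @param normalization only `"unit-energy"` is supported.
#' @return object of class `"wavelet_params"`.
#' @export
wavelet_params <- function(cycles = 6,
                           truncation = c("peak2", "inv_e", "half_footprint",
                                          "energy95"),
                           normalization = "unit-energy") {
  truncation <- match.arg(truncation)
  normalization <- match.arg(normalization, "unit-energy")
  if (!is.numeric(cycles) || length(cycles) != 1L || !is.finite(cycles) ||
      cycles <= 0) {
    stop("'cycles' must be a single positive number")
  }
  structure(
    list(cycles = cycles, truncation = truncation,
         normalization = normalization),
    class = "wavelet_params"
  )
}

# Envelope sigma (seconds) for a band centered at frequency f (Hz).
band_sigma <- function(f, params) params$cycles / (2 * pi * f)

# Half-width (seconds) of the truncated kernel support for envelope sigma.
truncation_halfwidth <- function(sigma, params) {
  switch(params$truncation,
    peak2 = sigma * sqrt(2 * log(50)),
    inv_e = sigma * sqrt(2),
    half_footprint = sigma * sqrt(2 * log(50)) / 2,
    energy95 = stats::qnorm(0.975) * sigma / sqrt(2)
  )
}

#' Sample an analytic Morlet wavelet on a time grid
#'
#' Evaluates `A * exp(-t^2 / (2 * sigma^2)) * exp(1i * 2 * pi * f0 * t)` on
#' the supplied (uniform, zero-centered) time grid, with `sigma` derived
#' from `params$cycles` and `f0`, and `A` set so the discrete energy
#' `sum(|Psi|^2) * dt` is exactly one.
#'
#' @param time_grid numeric vector of sample times (seconds), uniformly
#'   spaced and symmetric about 0.
#' @param params a [wavelet_params()] object.
#' @param f0 center frequency in Hz, `> 0`.
#' @return complex vector of wavelet samples.
#' @examples
#' fs <- 200
#' psi <- morlet(seq(-1, 1, by = 1 / fs), wavelet_params(), f0 = 10)
#' sum(Mod(psi)^2) / fs  # 1
#' @export
morlet <- function(time_grid, params = wavelet_params(), f0) {
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0) || f0 <= 0) {
    stop("'f0' must be a single positive frequency (Hz)")
  }
  if (length(time_grid) < 1L) stop("'time_grid' must be non-empty")
  if (length(time_grid) > 1L) {
    dt <- diff(time_grid)
    if (any(abs(dt - dt[1L]) > 1e-9 * abs(dt[1L]))) {
      stop("'time_grid' must be uniformly spaced")
    }
    dt <- dt[1L]
  } else {
    dt <- 1
  }
  sigma <- band_sigma(f0, params)
  if (sigma <= 0) stop("envelope sigma must be positive")
  env <- exp(-time_grid^2 / (2 * sigma^2))
  psi <- env * exp(1i * 2 * pi * f0 * time_grid)
  a <- 1 / sqrt(sum(Mod(psi)^2) * dt)
  a * psi
}

#' Frequency grid for the scalogram
#'
#' Builds the list of `J` band center frequencies the CWT is evaluated on.
#' Frequencies must lie in `(0, fs/2]`; the Nyquist check itself happens at
#' transform time (`fs` is a property of the signal, not the grid).
#'
#' @param f_min,f_max band range in Hz, `0 < f_min <= f_max`.
#' @param n_bands explicit band count `J`; when given, frequencies are
#'   spaced per `spacing` between `f_min` and `f_max` inclusive.
#' @param voices_per_octave used instead of `n_bands` for logarithmic grids:
#'   number of bands per frequency doubling (default 12).
#' @param spacing `"logarithmic"` (default) or `"linear"`.
#' @return object of class `"frequency_grid"` with fields `frequencies`
#'   (ascending), `J`, `spacing`, `voices_per_octave`.
#' @examples
#' frequency_grid(2, 40, n_bands = 20)
#' @export
frequency_grid <- function(f_min, f_max, n_bands = NULL,
                           voices_per_octave = 12,
                           spacing = c("logarithmic", "linear")) {
  spacing <- match.arg(spacing)
  if (!is.finite(f_min) || !is.finite(f_max) || f_min <= 0 || f_max < f_min) {
    stop("need 0 < f_min <= f_max")
  }
  if (is.null(n_bands)) {
    if (spacing == "linear") {
      stop("'n_bands' is required for a linear grid")
    }
    n_oct <- log2(f_max / f_min)
    n_bands <- max(1L, as.integer(floor(n_oct * voices_per_octave)) + 1L)
  }
  n_bands <- as.integer(n_bands)
  if (n_bands < 1L) stop("J must be >= 1")
  freqs <- if (n_bands == 1L) {
    f_min
  } else if (spacing == "logarithmic") {
    exp(seq(log(f_min), log(f_max), length.out = n_bands))
  } else {
    seq(f_min, f_max, length.out = n_bands)
  }
  structure(
    list(frequencies = freqs, J = n_bands, spacing = spacing,
         voices_per_octave = if (spacing == "logarithmic") voices_per_octave
                             else NA_real_),
    class = "frequency_grid"
  )
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> J = %d bands, %s spacing, %.4g-%.4g Hz\n",
              x$J, x$spacing, min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

# Discrete band kernels for cross-correlation of the signal with the band
# wavelet: h = Conj(rev(psi)). For the analytic Morlet (even envelope) this
# equals psi itself, but the reversal+conjugation is kept so the code stays
# correct for any symmetric-envelope analytic wavelet.
band_kernels <- function(grid, fs, params) {
  lapply(grid$frequencies, function(f) {
    k <- band_halfwidth_samples(f, fs, params)
    psi <- morlet((-k:k) / fs, params, f0 = f)
    Conj(rev(psi))
  })
}

# Kernel half-width in samples; footprint length is 2*k + 1 (always odd).
band_halfwidth_samples <- function(f, fs, params) {
  tw <- truncation_halfwidth(band_sigma(f, params), params)
  max(0L, as.integer(floor(tw * fs)))
}

#' Continuous wavelet transform and scalogram of a signal
#'
#' Computes, for each band frequency of `grid`, the mode-convolution of the
#' signal with the (conjugated, time-reversed) unit-energy analytic Morlet
#' wavelet of that band, and the corresponding scalogram (`|W|` amplitude or
#' `|W|^2` power).
#'
#' For `mode = "same"` the coefficient rows all have the signal length `N`
#' and the result is a `J x N` matrix — the standard (S-) scalogram. For
#' `"full"`/`"valid"` the per-band footprints differ, so rows are returned
#' as ragged lists. Valid-mode rows contain exactly the coefficients inside
#' the cone of influence (see [compute_coi()]).
#'
#' @param x numeric signal vector (`N >= 2`, all finite).
#' @param fs sampling rate in Hz.
#' @param grid a [frequency_grid()]; all frequencies must be `<= fs/2`.
#' @param params a [wavelet_params()].
#' @param mode convolution mode, as in [convolve_mode()].
#' @param kind `"power"` (default) or `"amplitude"`.
#' @return list of class `"cwt_result"` with elements `W` (complex `J x N`
#'   matrix for `"same"`, otherwise list of rows), `G` (the scalogram, same
#'   shape, class `"scalogram"`), `grid`, `fs`, `mode`, `kind`, `params`.
#' @examples
#' g <- frequency_grid(4, 30, n_bands = 12)
#' res <- cwt_scalogram(sin(2 * pi * 10 * (0:199) / 200), fs = 200, grid = g)
#' dim(res$G)  # 12 x 200
#' @export
cwt_scalogram <- function(x, fs, grid, params = wavelet_params(),
                          mode = c("same", "full", "valid"),
                          kind = c("power", "amplitude")) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  check_signal(x, fs)
  if (any(grid$frequencies > fs / 2 + 1e-12)) {
    stop("aliasing: grid contains frequencies above fs/2")
  }
  kernels <- band_kernels(grid, fs, params)
  n <- length(x)
  if (mode == "valid" && any(lengths(kernels) > n)) {
    stop("valid-mode transform: some band footprints exceed the signal length")
  }
  rows <- lapply(kernels, function(h) convolve_mode(x, h, mode))
  if (mode == "same") {
    w <- do.call(rbind, rows)
  } else {
    w <- rows
  }
  g <- scalogram_from_w(w, kind)
  structure(
    list(W = w, G = structure(g, class = c("scalogram", class(g)),
                              kind = kind, frequencies = grid$frequencies),
         grid = grid, fs = fs, mode = mode, kind = kind, params = params),
    class = "cwt_result"
  )
}

scalogram_from_w <- function(w, kind) {
  f <- if (kind == "power") function(z) Mod(z)^2 else Mod
  if (is.list(w)) lapply(w, f) else f(w)
}

check_signal <- function(x, fs) {
  if (!is.numeric(x) || length(x) < 2L) stop("signal must have n >= 2 samples")
  if (!all(is.finite(x))) stop("signal contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive sampling rate")
  }
  invisible(TRUE)
}

# Batch same-mode scalograms for many equal-length signals via one matrix
# product per band bank. Equals row-by-row cwt_scalogram() (tested); used by
# the experiment harness where thousands of short epochs are transformed.
cwt_scalogram_batch <- function(X, fs, grid, params = wavelet_params(),
                                kind = "power") {
  stopifnot(is.matrix(X))
  n <- ncol(X)
  op <- same_mode_operator(grid, fs, params, n)
  wr <- op$re %*% t(X)  # (J*N) x n_signals
  wi <- op$im %*% t(X)
  pow <- wr^2 + wi^2
  if (kind == "amplitude") pow <- sqrt(pow)
  # column s holds the row-major-stacked J x N scalogram of signal s
  lapply(seq_len(nrow(X)), function(s) {
    g <- matrix(pow[, s], nrow = grid$J, ncol = n, byrow = TRUE)
    structure(g, class = c("scalogram", class(g)), kind = kind,
              frequencies = grid$frequencies)
  })
}

# Dense linear operator mapping a length-n signal to the row-major stacked
# same-mode CWT coefficients; split into real and imaginary parts.
same_mode_operator <- function(grid, fs, params, n) {
  kernels <- band_kernels(grid, fs, params)
  blocks <- lapply(kernels, function(h) {
    l <- length(h)
    off <- (l - 1L) %/% 2L
    # same-output row r (1-based), signal col k: full index i = r + off,
    # kernel tap i - k + 1 when within 1..l
    idx <- outer(seq_len(n) + off, seq_len(n), function(i, k) i - k + 1L)
    tap <- idx >= 1L & idx <= l
    m <- matrix(0 + 0i, n, n)
    m[tap] <- h[idx[tap]]
    m
  })
  big <- do.call(rbind, blocks)
  list(re = Re(big), im = Im(big))
}
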