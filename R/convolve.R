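#' Linear convolution with explicit output-mode semantics
#'
#' Computes the linear (acyclic) convolution of a signal `x` with a kernel
#' `h` and returns one of the three standard output slices:
#'
#' * `"full"`: all `N + L - 1` terms of the convolution sum, including the
#'   partial-overlap terms at both ends;
#' * `"same"`: the centered length-`N` slice of the full output, aligned so
#'   that output sample `n` (0-based) corresponds to the kernel centered at
#'   input sample `n`. For even-length kernels the center tap is taken at
#'   offset `floor((L - 1) / 2)`;
#' * `"valid"`: only the `N - L + 1` complete-overlap terms, i.e. the terms
#'   whose convolution window lies entirely inside the signal.
#'
#' The `same` output is what standard scalogram pipelines use: it preserves
#' the signal length but its first and last `floor(L/2)`-ish samples are
#' edge-affected because the convolution window hangs over the signal
#' boundary (implicit zero padding). The `valid` output contains exactly the
#' accurate coefficients, which is what delineates the cone of influence
#' (see [compute_coi()]).
#'
#' @param x numeric or complex vector, length `N >= 1`.
#' @param h numeric or complex kernel, length `L >= 1`.
#' @param mode one of `"full"`, `"same"`, `"valid"`.
#' @return numeric (or complex, if either input is complex) vector of length
#'   `N + L - 1`, `N`, or `N - L + 1` according to `mode`.
#' @examples
#' convolve_mode(c(1, 2, 3), c(1, 1), "full")  # 1 3 5 3
#' convolve_mode(c(1, 2, 3), c(1, 1), "valid") # 3 5
#' @seealso [cwt_scalogram()], [compute_coi()]
#' @export
convolve_mode <- function(x, h, mode = c("full", "same", "valid")) {
  mode <- match.arg(mode)
  n <- length(x)
  l <- length(h)
  if (n < 1L || l < 1L) stop("x and h must be non-empty")
  if (mode == "valid" && l > n) {
    stop("valid-mode convolution is empty: kernel is longer than the signal")
  }
  full <- conv_full_fft(x, h)
  switch(mode,
    full = full,
    same = full[seq_len(n) + (l - 1L) %/% 2L],
    valid = full[l:n]
  )
}

# FFT-based full linear convolution; keeps complex output only when an
# input is complex.
conv_full_fft <- function(x, h) {
  n_out <- length(x) + length(h) - 1L
  nf <- stats::nextn(n_out, 2L)
  xf <- stats::fft(c(x, rep(0, nf - length(x))))
  hf <- stats::fft(c(h, rep(0, nf - length(h))))
  out <- stats::fft(xf * hf, inverse = TRUE)[seq_len(n_out)] / nf
  if (is.complex(x) || is.complex(h)) out else Re(out)
}
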