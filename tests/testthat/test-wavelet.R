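test_that("morlet wavelet: peak, symmetry, unit energy, parameter errors", {
  fs <- 250
  tg <- seq(-1.5, 1.5, by = 1 / fs)
  for (f0 in c(3, 8, 21)) {
    psi <- morlet(tg, wavelet_params(), f0 = f0)
    center <- which(tg == 0)
    # complex exponential is 1 at t = 0: value is the real envelope peak
    expect_equal(Im(psi[center]), 0)
    expect_equal(Re(psi[center]), max(Mod(psi)))
    # even envelope
    expect_equal(Mod(psi), rev(Mod(psi)))
    # discrete unit energy
    expect_equal(sum(Mod(psi)^2) / fs, 1, tolerance = 1e-6)
  }
  expect_error(morlet(tg, wavelet_params(), f0 = -2), "positive")
  expect_error(wavelet_params(cycles = 0), "positive")
})

test_that("frequency grid construction and validation", {
  g <- frequency_grid(2, 32, voices_per_octave = 4)
  expect_equal(g$J, 17)  # 4 octaves * 4 voices + 1
  expect_true(all(diff(g$frequencies) > 0))
  g2 <- frequency_grid(5, 25, n_bands = 6, spacing = "linear")
  expect_equal(g2$frequencies, seq(5, 25, length.out = 6))
  expect_error(frequency_grid(-1, 10, n_bands = 3), "f_min")
  expect_error(frequency_grid(10, 5, n_bands = 3), "f_min")
})

test_that("cwt_scalogram: shape, zero signal, aliasing guard", {
  g <- frequency_grid(2, 40, n_bands = 108)
  x <- rnorm(200)
  res <- cwt_scalogram(x, fs = 200, grid = g)
  expect_equal(dim(res$G), c(108L, 200L))
  expect_equal(dim(res$W), c(108L, 200L))
  zero <- cwt_scalogram(rep(0, 200), fs = 200, grid = g)
  expect_true(all(zero$G == 0))
  expect_error(cwt_scalogram(x, fs = 50, grid = g), "aliasing")
})

test_that("a grid-frequency sinusoid peaks at the nearest band inside the COI", {
  g <- frequency_grid(8, 30, n_bands = 8)
  fs <- 200
  fstar <- g$frequencies[5]
  x <- sin(2 * pi * fstar * (0:199) / fs)
  res <- cwt_scalogram(x, fs, g)
  coi <- compute_coi(g, 200, fs)
  mean_pow <- vapply(seq_len(8), function(f) {
    mean(res$G[f, (coi$n_start[f] + 1):coi$n_end[f]])
  }, numeric(1))
  expect_equal(which.max(mean_pow), 5L)
})

test_that("scalogram kinds: power equals amplitude squared; doubling input quadruples power", {
  g <- frequency_grid(5, 30, n_bands = 6)
  x <- rnorm(120)
  pw <- cwt_scalogram(x, 100, g, kind = "power")$G
  am <- cwt_scalogram(x, 100, g, kind = "amplitude")$G
  expect_true(all(pw >= 0) && all(am >= 0))
  expect_equal(unclass(pw), unclass(am)^2, ignore_attr = TRUE)
  pw2 <- cwt_scalogram(2 * x, 100, g, kind = "power")$G
  expect_equal(unclass(pw2), 4 * unclass(pw), ignore_attr = TRUE)
})

test_that("batch scalogram path equals the per-signal reference path", {
  g <- frequency_grid(4, 45, n_bands = 9)
  set.seed(5)
  xs <- matrix(rnorm(6 * 150), 6)
  batch <- cwt_scalogram_batch(xs, 128, g)
  for (i in c(1, 4, 6)) {
    single <- cwt_scalogram(xs[i, ], 128, g)$G
    expect_equal(unclass(batch[[i]]), unclass(single), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("COI: counts, monotonicity, valid-convolution equivalence", {
  g <- frequency_grid(8, 30, n_bands = 8)
  fs <- 200
  n <- 200L
  coi <- compute_coi(g, n, fs)
  # footprints shrink and Nf grows with frequency
  expect_true(all(diff(coi$Nf) >= 0))
  expect_true(all(diff(coi$footprint) <= 0))
  expect_equal(coi$Nf, pmax(0L, n - coi$footprint + 1L))
  # same-mode coefficients inside the COI match valid-mode outputs exactly
  set.seed(2)
  x <- rnorm(n)
  same <- cwt_scalogram(x, fs, g, mode = "same")
  valid <- cwt_scalogram(x, fs, g, mode = "valid")
  for (f in seq_len(8)) {
    inside <- same$W[f, (coi$n_start[f] + 1):coi$n_end[f]]
    expect_equal(inside, valid$W[[f]], tolerance = 1e-9)
  }
})

test_that("COI handles pointlike and oversized footprints", {
  # footprint 1 keeps the whole row; footprint > N leaves nothing
  cb <- coi_boundary(Nf = c(0L, 10L), N = 10L, footprint = c(15L, 1L))
  expect_equal(cb$Nf, c(0L, 10L))
  expect_equal(cb$n_start[2], 0L)
  expect_equal(cb$n_end[2], 10L)
  # low-frequency bands with footprint > N are allowed and get Nf = 0
  g <- frequency_grid(0.5, 20, n_bands = 5)
  coi <- compute_coi(g, 64L, 64)
  expect_true(coi$Nf[1] == 0L)
  expect_true(all(coi$Nf >= 0L) && all(coi$Nf <= 64L))
})

test_that("N=10, Lf=4 gives Nf=7, matching the valid-convolution length", {
  cb <- coi_boundary(Nf = 7L, N = 10L, footprint = 4L)
  expect_equal(cb$Nf, 7L)
  expect_length(convolve_mode(rnorm(10), rnorm(4), "valid"), 7L)
  expect_equal(cb$n_end - cb$n_start, 7L)
})

test_that("rho: worked examples, bounds, and large-N limit", {
  expect_equal(quality_rho(coi_boundary(c(4, 2, 0)[3:1], N = 4)), 0.5)
  full <- coi_boundary(rep(12L, 3), N = 12L)
  expect_equal(quality_rho(full), 1)
  expect_error(quality_rho(coi_boundary(integer(0), N = 5)), "positive")
  # rho grows toward 1 as N grows with the grid fixed
  g <- frequency_grid(6, 30, n_bands = 6)
  rhos <- vapply(c(100L, 400L, 1600L), function(n) {
    quality_rho(compute_coi(g, n, 100))
  }, numeric(1))
  expect_true(all(diff(rhos) > 0))
  expect_gt(rhos[3], 0.95)
})

test_that("rho decreases when the maximum footprint grows (wider wavelets)", {
  g <- frequency_grid(6, 30, n_bands = 6)
  rho_narrow <- quality_rho(compute_coi(g, 200, 100, wavelet_params(cycles = 4)))
  rho_wide <- quality_rho(compute_coi(g, 200, 100, wavelet_params(cycles = 10)))
  expect_gt(rho_narrow, rho_wide)
})

test_that("beta: trivial cases and brute-force toy sum", {
  w <- matrix(complex(real = 1:6, imaginary = 6:1), 2, 3, byrow = TRUE)
  # COI covering everything
  expect_equal(quality_beta(w, coi_boundary(c(3L, 3L), N = 3L)), 1)
  # exclude one edge sample per row (footprint 3: valid interval [1, 2))
  coi <- coi_boundary(c(1L, 1L), N = 3L, footprint = c(3L, 3L))
  pow <- Mod(w)^2
  expect_equal(quality_beta(w, coi), sum(pow[, 2]) / sum(pow))
  # zero outside the COI -> beta = 1
  wz <- w
  wz[, c(1, 3)] <- 0
  expect_equal(quality_beta(wz, coi), 1)
  expect_warning(b0 <- quality_beta(matrix(0i, 2, 3), coi), "zero")
  expect_equal(b0, 0)
  expect_error(quality_beta(w, coi_boundary(c(2L, 2L), N = 4L)), "disagree")
})

test_that("truncation rules order footprints as documented", {
  f <- 10
  fs <- 200
  ks <- vapply(c("inv_e", "energy95", "half_footprint", "peak2"),
               function(rule) {
                 coiwave:::band_halfwidth_samples(f, fs, wavelet_params(truncation = rule))
               }, integer(1))
  expect_true(ks[["inv_e"]] <= ks[["peak2"]])
  expect_true(ks[["half_footprint"]] <= ks[["peak2"]])
  expect_true(ks[["energy95"]] <= ks[["inv_e"]])
})
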