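test_that("spec validation rejects impossible component layouts", {
  expect_error(class_template_spec(
    data.frame(frequency = 150, amplitude = 1, latency = 0.5,
               duration = 0.2), N = 200, fs = 200), "fs/2")
  expect_error(class_template_spec(
    data.frame(frequency = 10, amplitude = 1, latency = 0.05,
               duration = 0.5), N = 200, fs = 200), "fit inside")
  expect_error(class_template_spec(noise_sd = -1), ">= 0")
})

test_that("zero jitter and zero noise reproduce the template exactly", {
  comp <- data.frame(frequency = 8, amplitude = 2, latency = 0.5,
                     duration = 0.5, phase = 0.3)
  spec <- class_template_spec(comp, latency_jitter_sd = 0,
                              amplitude_jitter_sd = 0, noise_sd = 0,
                              N = 200, fs = 200, n_trials = 7)
  ens <- generate_trials(spec, seed = 1)
  tmpl <- template_signal(spec)
  for (i in 1:7) expect_equal(ens$trials[i, ], tmpl)
  # raised-cosine window: template vanishes outside the component support
  expect_equal(tmpl[1:40], rep(0, 40))
  expect_gt(max(abs(tmpl)), 1)
})

test_that("white noise ensemble matches its nominal variance", {
  spec <- class_template_spec(noise_sd = 1, N = 200, fs = 200,
                              n_trials = 500)
  ens <- generate_trials(spec, seed = 5)
  expect_equal(var(as.vector(ens$trials)), 1, tolerance = 0.05)
  expect_equal(mean(ens$trials), 0, tolerance = 0.05)
})

test_that("ensemble dimensions mirror the reference recording shape", {
  spec <- class_template_spec(n_trials = 195, N = 200, fs = 200)
  ens <- generate_trials(spec, seed = 1)
  expect_equal(dim(ens$trials), c(195L, 200L))
})

test_that("generation is seed-deterministic", {
  spec <- class_template_spec(
    data.frame(frequency = 11, amplitude = 1, latency = 0.4, duration = 0.3),
    N = 128, fs = 128, n_trials = 20)
  e1 <- generate_trials(spec, seed = 77)
  e2 <- generate_trials(spec, seed = 77)
  e3 <- generate_trials(spec, seed = 78)
  expect_equal(e1$trials, e2$trials)
  expect_false(isTRUE(all.equal(e1$trials, e3$trials)))
})

test_that("1/f noise option changes the spectrum but keeps reproducibility", {
  spec <- class_template_spec(noise_sd = 1, pink_weight = 1, N = 256,
                              fs = 128, n_trials = 4)
  e1 <- generate_trials(spec, seed = 3)
  e2 <- generate_trials(spec, seed = 3)
  expect_equal(e1$trials, e2$trials)
  # 1/f shaping boosts low-frequency power relative to white noise
  white <- generate_trials(class_template_spec(noise_sd = 1, N = 256,
                                               fs = 128, n_trials = 4),
                           seed = 3)
  pw <- function(m) {
    sp <- apply(m, 1, function(r) Mod(fft(r))^2)
    rowMeans(sp)
  }
  lowband <- 2:10
  highband <- 60:120
  ratio_pink <- sum(pw(e1$trials)[lowband]) / sum(pw(e1$trials)[highband])
  ratio_white <- sum(pw(white$trials)[lowband]) / sum(pw(white$trials)[highband])
  expect_gt(ratio_pink, 2 * ratio_white)
})

test_that("generate_dataset scales class differences by channel gain", {
  diff_c <- data.frame(frequency = 12, amplitude = 1, latency = 0.25,
                       duration = 0.3, phase = 0)
  spec_a <- class_template_spec(diff_c, latency_jitter_sd = 0,
                                amplitude_jitter_sd = 0, noise_sd = 0,
                                N = 64, fs = 128, n_trials = 3)
  spec_b <- class_template_spec(latency_jitter_sd = 0,
                                amplitude_jitter_sd = 0, noise_sd = 0,
                                N = 64, fs = 128, n_trials = 3)
  ds <- generate_dataset(spec_a, spec_b, gains = c(hi = 2, null = 0),
                         n_subjects = 2, seed = 1)
  expect_equal(names(ds), c("s1", "s2"))
  expect_equal(names(ds$s1), c("hi", "null"))
  # gain 0 removes the class difference entirely (noise-free check)
  expect_equal(ds$s1$null$a$trials, ds$s1$null$b$trials)
  # gain 2 doubles the differential amplitude
  gap_hi <- max(abs(colMeans(ds$s1$hi$a$trials) - colMeans(ds$s1$hi$b$trials)))
  expect_gt(gap_hi, 1.5)
  # 5 subjects x 8 channels x 2 classes = 40 binary datasets
  ds40 <- generate_dataset(spec_a, spec_b, gains = rep(1, 8),
                           n_subjects = 5, seed = 2)
  expect_equal(length(ds40) * length(ds40$s1), 40L)
})

test_that("in_coi_only_spec confines the class difference inside the COI", {
  grid <- test_grid()
  coi <- compute_coi(grid, 200L, 200)
  world <- test_world_specs(n_trials = 2L)
  # noise-free templates: difference vanishes (to leakage level) outside COI
  quiet <- function(spec) {
    spec$latency_jitter_sd <- 0
    spec$amplitude_jitter_sd <- 0
    spec$noise_sd <- 0
    spec
  }
  ta <- template_signal(quiet(world$spec_a))
  tb <- template_signal(quiet(world$spec_b))
  ga <- cwt_scalogram(ta, 200, grid)$G
  gb <- cwt_scalogram(tb, 200, grid)$G
  dv <- abs(v_vector(ga, coi)$values - v_vector(gb, coi)$values)
  dvb <- abs(vbar_vector(ga, coi)$values - vbar_vector(gb, coi)$values)
  expect_gt(max(dv), 0)
  # out-of-COI leakage power is at most 1% of the in-COI difference power
  expect_lt(sum(dvb^2) / sum(dv^2), 0.01)
  # infeasible COI is rejected (short epoch, slow bands)
  tiny_spec <- class_template_spec(
    data.frame(frequency = 3, amplitude = 1, latency = 0.5, duration = 0.3),
    N = 64L, fs = 64, n_trials = 2L)
  tiny <- compute_coi(frequency_grid(2, 4, n_bands = 3), 64L, 64)
  expect_error(in_coi_only_spec(tiny_spec, tiny_spec, tiny),
               "COI too small|in-COI")
})

test_that("m-ERP averaging yields the expected SNR gain on synthetic trials", {
  comp <- data.frame(frequency = 10, amplitude = 1, latency = 0.5,
                     duration = 0.5, phase = 0)
  spec <- class_template_spec(comp, latency_jitter_sd = 0,
                              amplitude_jitter_sd = 0, noise_sd = 1,
                              N = 200, fs = 200, n_trials = 100)
  ens <- generate_trials(spec, seed = 9)
  tmpl <- template_signal(spec)
  noise_power <- function(m) mean(sweep(m, 2, tmpl)^2)
  m <- 4
  me <- msa_generate(ens, m, n_out = 1000, seed = 10)
  gain <- noise_power(ens$trials) / noise_power(me$merps)
  expect_equal(gain, m, tolerance = 0.2)
})
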