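# Independent oracles and small fixture builders used across the suite.

# Direct convolution sum (O(N*L)), the reference for convolve_mode().
conv_oracle <- function(x, h) {
  n <- length(x)
  l <- length(h)
  vapply(seq_len(n + l - 1L), function(i) {
    ks <- max(1L, i - l + 1L):min(n, i)
    sum(x[ks] * h[i - ks + 1L])
  }, if (is.complex(x) || is.complex(h)) complex(1) else numeric(1))
}

# Small two-class linearly separable feature fixture.
toy_classes <- function(n_per_class = 20, p = 8, gap = 2.5, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * p), ncol = p),
             matrix(stats::rnorm(n_per_class * p, mean = gap), ncol = p))
  list(x = x, y = rep(c("a", "b"), each = n_per_class))
}

# Synthetic two-class epoch world used by the harness/acceptance tests:
# 1-s epochs at 200 Hz, a shared 10 Hz background, one differential
# component per class, white noise sd 1. The differential components are
# phase-locked (small latency jitter): the pipeline classifies scalograms
# of trial averages, i.e. evoked power, and a latency jitter sd of 0.02 s
# at ~25 Hz (a ~3 rad phase jitter) would scramble the phase-locked
# component away entirely. 0.003 s keeps the phase jitter below ~0.5 rad.
# The components are relocated inside the COI of the standard test grid by
# in_coi_only_spec().
test_grid <- function() frequency_grid(8, 40, n_bands = 14)

test_world_specs <- function(n_trials = 60L) {
  shared <- data.frame(frequency = 10, amplitude = 1, latency = 0.5,
                       duration = 0.6, phase = 0)
  diff_a <- data.frame(frequency = 20, amplitude = 1, latency = 0.5,
                       duration = 0.4, phase = 0)
  diff_b <- data.frame(frequency = 25, amplitude = 1, latency = 0.5,
                       duration = 0.4, phase = 0)
  # noise sd 2 against amplitude-1 components: single-trial component-band
  # SNR well below 1, the regime subsample averaging exists for (single
  # trials unclassifiable, m-ERPs classifiable but off ceiling)
  spec_a <- class_template_spec(diff_a, shared = shared,
                                latency_jitter_sd = 0.003, noise_sd = 2,
                                N = 200L, fs = 200, n_trials = n_trials)
  spec_b <- class_template_spec(diff_b, shared = shared,
                                latency_jitter_sd = 0.003, noise_sd = 2,
                                N = 200L, fs = 200, n_trials = n_trials)
  coi <- compute_coi(test_grid(), 200L, 200)
  in_coi_only_spec(spec_a, spec_b, coi)
}
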