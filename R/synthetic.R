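#' Specification of a synthetic ERP class template
#'
#' Describes how single trials of one class are synthesized: a deterministic
#' template — a sum of raised-cosine-windowed oscillatory components — plus
#' per-trial latency/amplitude jitter and additive noise. The defaults
#' mirror a typical epoched ERP recording setup: 200-sample epochs at
#' 200 Hz (1 s) and 195 trials per class.
#'
#' Raised-cosine (Hann) component windows are used deliberately: rectangular
#' onsets would inject broadband edges that confound tests of what lies
#' inside versus outside the cone of influence.
#'
#' @param components data frame with columns `frequency` (Hz, `< fs/2`),
#'   `amplitude` (microvolts), `latency` (s, window center), `duration`
#'   (s, full window width; the window must fit inside the epoch), `phase`
#'   (radians). May have zero rows (noise-only class).
#' @param shared optional data frame of the same shape marking components
#'   common to both classes (used by [generate_dataset()] to know which
#'   components carry the class difference).
#' @param latency_jitter_sd,amplitude_jitter_sd per-trial standard
#'   deviations of the component latency shift (s) and of the multiplicative
#'   amplitude factor (unit mean).
#' @param noise_sd white-noise standard deviation (microvolts).
#' @param pink_weight weight of an additional 1/f-shaped noise component
#'   (unit-variance, then scaled by `pink_weight * noise_sd`); default 0.
#' @param N,fs,n_trials epoch length (samples), sampling rate (Hz) and
#'   ensemble size.
#' @return object of class `"class_template_spec"`.
#' @export
class_template_spec <- function(components = empty_components(),
                                shared = NULL,
                                latency_jitter_sd = 0.02,
                                amplitude_jitter_sd = 0.1,
                                noise_sd = 1, pink_weight = 0,
                                N = 200L, fs = 200, n_trials = 195L) {
  components <- validate_components(components, N, fs)
  if (!is.null(shared)) shared <- validate_components(shared, N, fs)
  if (noise_sd < 0 || pink_weight < 0) stop("noise parameters must be >= 0")
  if (latency_jitter_sd < 0 || amplitude_jitter_sd < 0) {
    stop("jitter standard deviations must be >= 0")
  }
  structure(list(components = components, shared = shared,
                 latency_jitter_sd = latency_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 noise_sd = noise_sd, pink_weight = pink_weight,
                 N = as.integer(N), fs = fs, n_trials = as.integer(n_trials)),
            class = "class_template_spec")
}

empty_components <- function() {
  data.frame(frequency = numeric(0), amplitude = numeric(0),
             latency = numeric(0), duration = numeric(0),
             phase = numeric(0))
}

validate_components <- function(components, N, fs) {
  components <- as.data.frame(components)
  need <- c("frequency", "amplitude", "latency", "duration")
  if (!all(need %in% names(components))) {
    stop("components need columns frequency, amplitude, latency, duration")
  }
  if (is.null(components$phase)) components$phase <- 0
  if (nrow(components)) {
    if (any(components$frequency >= fs / 2)) {
      stop("component frequencies must be below fs/2")
    }
    epoch <- (N - 1) / fs
    if (any(components$latency - components$duration / 2 < -1e-9) ||
        any(components$latency + components$duration / 2 > epoch + 1e-9)) {
      stop("component windows must fit inside the epoch")
    }
  }
  components
}

# Deterministic template on the epoch time grid, with optional per-trial
# latency shifts and amplitude factors.
component_sum <- function(components, tgrid, lat_shift = 0, amp_fac = 1) {
  out <- numeric(length(tgrid))
  if (!nrow(components)) return(out)
  lat_shift <- rep_len(lat_shift, nrow(components))
  amp_fac <- rep_len(amp_fac, nrow(components))
  for (i in seq_len(nrow(components))) {
    co <- components[i, ]
    lat <- co$latency + lat_shift[i]
    rel <- tgrid - lat
    w <- ifelse(abs(rel) <= co$duration / 2,
                0.5 * (1 + cos(2 * pi * rel / co$duration)), 0)
    out <- out + co$amplitude * amp_fac[i] * w *
      cos(2 * pi * co$frequency * rel + co$phase)
  }
  out
}

#' Noise-free class template
#'
#' @param spec a [class_template_spec()].
#' @return numeric vector of `N` samples (all components, no jitter, no
#'   noise).
#' @export
template_signal <- function(spec) {
  tgrid <- (seq_len(spec$N) - 1L) / spec$fs
  component_sum(all_components(spec), tgrid)
}

all_components <- function(spec) {
  rbind(spec$shared %||% empty_components(), spec$components)
}

#' Generate a synthetic single-trial ensemble
#'
#' Each trial is the jittered component sum plus white (and optionally
#' 1/f-shaped) Gaussian noise. Identical spec and seed reproduce the
#' ensemble exactly.
#'
#' @param spec a [class_template_spec()].
#' @param seed optional integer seed.
#' @param subject,channel,class labels attached to the ensemble.
#' @return a [trial_ensemble()] of `n_trials x N`.
#' @export
generate_trials <- function(spec, seed = NULL, subject = NA, channel = NA,
                            class = NA) {
  if (!is.null(seed)) set.seed(seed)
  tgrid <- (seq_len(spec$N) - 1L) / spec$fs
  comps <- all_components(spec)
  nc <- nrow(comps)
  trials <- matrix(0, spec$n_trials, spec$N)
  for (tr in seq_len(spec$n_trials)) {
    lat <- if (nc) stats::rnorm(nc, 0, spec$latency_jitter_sd) else 0
    amp <- if (nc) 1 + stats::rnorm(nc, 0, spec$amplitude_jitter_sd) else 1
    sig <- component_sum(comps, tgrid, lat, amp)
    noise <- stats::rnorm(spec$N, 0, spec$noise_sd)
    if (spec$pink_weight > 0) {
      noise <- noise + spec$pink_weight * spec$noise_sd * pink_noise(spec$N)
    }
    trials[tr, ] <- sig + noise
  }
  trial_ensemble(trials, spec$fs, subject, channel, class)
}

# Unit-variance 1/f-shaped noise via spectral shaping of white noise.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  shaped <- Re(stats::fft(spec / sqrt(f), inverse = TRUE)) / n
  as.vector(scale(shaped))
}

#' Generate a multi-subject, multi-channel two-class dataset
#'
#' Builds `n_subjects x length(gains)` binary datasets. The class
#' difference at each channel is controlled by that channel's
#' discriminability gain: components listed in a spec's `components` slot
#' (the differential components) have their amplitudes multiplied by the
#' channel gain, while `shared` components are untouched. A gain of 0
#' removes the class difference entirely; the ground-truth channel ranking
#' is therefore the descending gain order.
#'
#' @param spec_a,spec_b [class_template_spec()]s for the two classes;
#'   their `shared` slots should hold the common background activity.
#' @param gains numeric vector of per-channel gains (names become channel
#'   names; defaults `ch1`, `ch2`, ...).
#' @param n_subjects number of subjects (default 1).
#' @param seed master seed; per-(subject, channel, class) substreams are
#'   derived with [derive_seed()].
#' @return nested list `dataset[[subject]][[channel]]` of named per-class
#'   [trial_ensemble()]s (`a`, `b`).
#' @export
generate_dataset <- function(spec_a, spec_b, gains, n_subjects = 1L,
                             seed = 1L) {
  if (length(gains) < 1L) stop("need at least one channel gain")
  chn <- names(gains) %||% paste0("ch", seq_along(gains))
  out <- list()
  for (s in seq_len(n_subjects)) {
    subj <- paste0("s", s)
    out[[subj]] <- list()
    for (c in seq_along(gains)) {
      mk <- function(spec, cls, tag) {
        sp <- spec
        if (nrow(sp$components)) {
          sp$components$amplitude <- sp$components$amplitude * gains[c]
        }
        generate_trials(sp, seed = derive_seed(seed, s, c, tag),
                        subject = subj, channel = chn[c], class = cls)
      }
      out[[subj]][[chn[c]]] <- list(a = mk(spec_a, "a", 1L),
                                    b = mk(spec_b, "b", 2L))
    }
  }
  out
}

#' Confine the class difference to the inside of the COI
#'
#' Rewrites the differential components of a spec pair so that their
#' time-frequency support lies inside the cone of influence: latencies are
#' moved to the epoch center, frequencies to a mid-grid band, and durations
#' clipped so that the component window, extended by the wavelet kernel
#' half-width of every band responding within one octave, stays inside the
#' in-COI column range of that band. Shared components are left untouched.
#'
#' With zero jitter and zero noise this construction makes the
#' out-of-COI (complement) coefficients of the two class templates agree
#' up to the small spectral leakage of the truncated wavelet kernels into
#' bands more than half an octave away (of order 1% relative power or
#' less), while the in-COI coefficients differ; with noise,
#' complement-trained classifiers should sit near chance level.
#'
#' @param spec_a,spec_b [class_template_spec()]s whose `components` slots
#'   hold the differential components.
#' @param coi a [coi_boundary()] computed for the specs' epoch geometry.
#' @param params the [wavelet_params()] the COI was computed with.
#' @return list with modified `spec_a`, `spec_b` and the chosen `frequency`
#'   and `duration`.
#' @export
in_coi_only_spec <- function(spec_a, spec_b, coi, params = wavelet_params()) {
  fs <- spec_a$fs
  N <- spec_a$N
  if (attr(coi, "N") != N) stop("COI and spec epoch lengths disagree")
  freqs <- coi$frequency
  if (all(is.na(freqs))) stop("COI must carry band frequencies")
  mid <- freqs[ceiling(nrow(coi) * 2 / 3)]  # upper-middle band: narrow kernel
  # the two classes keep distinct frequencies (a third-octave apart around
  # the mid band) so a frequency-coded class difference survives relocation
  f_a <- mid * 2^(-1 / 6)
  f_b <- mid * 2^(1 / 6)
  # bands responding strongly to the components (within half an octave)
  # must host the component window plus their kernel half-width inside
  # their in-COI column interval; farther bands are protected by the
  # wavelet's frequency selectivity instead (>= ~26 dB power attenuation)
  resp <- which(freqs >= f_a / sqrt(2) & freqs <= f_b * sqrt(2))
  lo <- 0; hi <- (N - 1) / fs
  for (f in resp) {
    if (coi$Nf[f] == 0L) {
      stop("COI too small to host any in-COI component at band ",
           signif(freqs[f], 3), " Hz")
    }
    k <- (coi$footprint[f] - 1L) %/% 2L
    lo <- max(lo, (coi$n_start[f] + k) / fs)
    hi <- min(hi, (coi$n_end[f] - 1L - k) / fs)
  }
  center <- (N - 1) / (2 * fs)
  max_dur <- 2 * min(center - lo, hi - center)
  if (max_dur < 2 / mid) {
    stop("COI too small to host any in-COI component ",
         "(available window shorter than two cycles)")
  }
  fix <- function(spec, f) {
    if (nrow(spec$components)) {
      spec$components$frequency <- f
      spec$components$latency <- center
      spec$components$duration <- pmin(spec$components$duration, max_dur)
    }
    spec
  }
  list(spec_a = fix(spec_a, f_a), spec_b = fix(spec_b, f_b),
       frequency = c(a = f_a, b = f_b), duration = max_dur)
}
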