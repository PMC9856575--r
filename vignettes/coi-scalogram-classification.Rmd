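---
title: "Cone-of-influence-aware scalogram classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cone-of-influence-aware scalogram classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coiwave)
```

## The model

An epoched EEG/ERP trial is a finite signal $x(n)$, $n = 0, \dots, N-1$,
at sampling rate $f_s$. Its continuous wavelet transform against an
analytic Morlet wavelet

$$\Psi_{f}(t) = A\, e^{-t^2/2\sigma_f^2}\, e^{j 2\pi f t},
\qquad \sigma_f = \frac{c}{2\pi f},$$

evaluated on $J$ band frequencies, gives the coefficient matrix
$W(f, n)$; the scalogram is $G(f,n) = |W(f,n)|^2$ (power) or $|W(f,n)|$
(amplitude). Each row of $W$ is a linear convolution of the signal with
the band's conjugated, time-reversed, discretely sampled wavelet kernel.
Three output conventions of that convolution matter:

* **full** — all $N + L_f - 1$ terms for a kernel of footprint $L_f$;
* **same** — the centered $N$-term slice; this is the standard scalogram
  row, and its first and last terms are computed from windows that hang
  over the epoch boundary (implicit zero padding): *edge artifacts*;
* **valid** — only the $N - L_f + 1$ complete-overlap terms, which are
  exact.

The **cone of influence (COI)** of a same-mode scalogram is, per band,
the half-open column interval on which the same-mode coefficient
coincides with a valid-mode coefficient: $N_f = \max(0, N - L_f + 1)$
columns starting at $(L_f-1)/2$ (0-based). Because $\sigma_f \propto
1/f$, low-frequency bands have wide kernels and few accurate
coefficients; the boundary is cone-shaped. The test suite asserts the
same/valid coefficient identity to $10^{-9}$ relative tolerance on every
band, which is the defining property rather than an approximation.

Two scalar quality ratios summarize a scalogram's exposure to edge
artifacts: $\rho = \sum_f N_f / (JN)$ (coverage) and $\beta$, the
fraction of total power inside the COI.

### The four feature representations

Classifier features are the scalogram coefficients themselves — no
derived statistics — concatenated row-major (ascending band index, the
storage order of the matrix):

* **S**: the entire $J \times N$ scalogram, length $JN$. The baseline;
  mixes accurate and artifact features.
* **Z**: S with out-of-COI entries set to exactly zero, length $JN$.
* **V**: only the in-COI entries, row by row, length $N_V = \sum_f N_f$.
* **V̄**: the complement (out-of-COI entries only), length $JN - N_V$.
  A negative control: if artifact coefficients carry no reliable class
  information, classifiers trained on V̄ alone should sit at chance.

V and V̄ partition S position-by-position, and Z's zeroed positions are
exactly V̄'s layout; both identities are asserted in the tests, as is
power conservation (`sum(V) + sum(V̄) = sum(S)`).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `cycles` | 6 | – | conventional analytic Morlet trade-off between time and frequency resolution; $f\sigma_f = 6/2\pi$ for every band |
| `truncation` | `"peak2"` | – | kernel support cut where the Gaussian envelope falls to 2% of peak ($|t| \le \sigma\sqrt{2\ln 50}$); alternatives `"inv_e"`, `"half_footprint"`, `"energy95"` are selectable because the literature uses several conventions and the COI extent depends on the choice |
| grid | logarithmic | Hz | oscillatory EEG bands are naturally log-spaced; `voices_per_octave = 12` default, or an explicit `n_bands` |
| `kind` | `"power"` | µV² | power scalograms are standard for ERP band analyses |
| `m` | 4 | trials | smallest averaging parameter that lifts m-ERP SNR into a usable range while keeping test-time trial demands low (noise variance falls as $\sigma^2/m$) |
| `k_folds` | 5 | – | standard choice; 195 trials split into folds of 39 |
| `n_runs` | 50 | – | each run re-partitions the trials and regenerates all m-ERPs |
| SVM | RBF; grid $C \in \{0.1,1,10,100\}$, $\gamma \in \{10^{-4},\dots,10^{-1}\}$, 3-fold inner CV | – | the inner grid bounds were not prescribed; they bracket the useful range on standardized features. `gamma = "scale"` ($1/(p\cdot\overline{\mathrm{var}})$) is available for fixed-cost runs |
| RF | 10 trees, depth ≤ 475, min-split 3, min-leaf 1, entropy, `mtry` $=\lfloor\sqrt p\rfloor$ | – | reference configuration; `mtry` follows the standard per-split convention |
| k-NN | $k = 20$, Euclidean | – | reference configuration |
| MLP | 1024/512/256/2, all sigmoid, Adam 0.001, 50 epochs, dropout 0.15, batch 32 | – | reference configuration; batch size was unstated, 32 is the usual default |
| CNN-1 | 3 × (conv 9×1, 32 filters, ReLU, same) → max-pool 2×1/2 → 1024/512/256/2 head | – | vector-input variant; input is the feature vector as a one-channel sequence |
| CNN-2 | 3 × (conv 3×3, 32 filters, ReLU, same → max-pool 2×2/2) → same head | – | matrix-input variant; consumes S/Z scalograms only, since matrix convolution requires equal-row input and the V representation is ragged. Requesting V/V̄ raises an error by design |

Feature standardization (per-feature location/scale, fitted on the
training set only, constants mapped to exactly 0) is on by default and
configurable off. It matters for the distance- and kernel-based families
and makes Z and V behave identically for them (a zeroed constant feature
contributes nothing to a Euclidean distance or RBF kernel) — which is the
expected limiting behavior, not an artifact.

## The m-SA protocol and leakage control

`msa_generate()` draws a subsample of $m$ distinct trials without
replacement, averages it, replaces it, and repeats — so the ensemble can
be made arbitrarily large (the point of the method: single-subject
classifier design), at the cost that different m-ERPs may share trials.
Duplicated subsamples are possible and accepted (a uniqueness filter is
available but off by default); within one m-ERP indices are always
distinct. Every m-ERP records its source-trial indices.

`build_run()` enforces mutual exclusivity at the *single-trial* level:
per fold, training m-ERPs are generated only from the $k-1$ training
folds and test m-ERPs only from the held-out fold. The audit is
mechanical — intersect the recorded index sets — and is part of the test
suite. Per-run accuracy pools correct counts over folds
(correct/total, e.g. /390); experiment accuracy averages the per-run
accuracies, and the 95% confidence intervals are Student-t intervals
over runs (the aggregation axis is configurable; runs are the default
because each run is an independent re-randomization).

RNG discipline: one master seed per experiment; every (run, class, fold,
role) combination derives its own substream via a deterministic integer
hash (`derive_seed()`), keeping all derived seeds below $2^{31}$.
Identical configuration and master seed reproduce the records exactly
for SVM/RF/k-NN; the network families are seeded and reproducible on a
fixed BLAS.

## RRS channel ranking

The interclass separation of two trial ensembles is a Fisher-type,
scatter-normalized distance between cluster means:
$\|\mu_a - \mu_b\|^2 / (\mathrm{tr}(S_a) + \mathrm{tr}(S_b))$, with
$\mathrm{tr}(S)$ the summed per-sample unbiased variances and $0/0 := 0$.
The exact separation formula used by the original ranking procedure was
not available, so the criterion is pluggable (`criterion` argument); the
ranking machinery is independent of it. Scores are computed on trial
clusters (means *and* scatter need trial-level variability), not on
full-sample averages.

Rank-of-rank-sum then proceeds in three stages: rank channels per
(subject, class pair) by descending separation; per subject, re-rank the
rank sums over the $U(U-1)/2$ pairs; across subjects, re-rank the summed
per-subject rankings. Ties receive average (mid-)ranks at every stage,
and the degenerate single-subject, two-class case reduces to ordering by
the raw scores. The implementation makes no claim of reproducing any
particular published channel table — that would require the original
criterion and data.

## The synthetic world

`generate_trials()` emulates epoched, stimulus-locked oscillatory
activity: each trial is a sum of raised-cosine-windowed sinusoidal
components (frequency, amplitude, latency, duration, phase) with
per-trial Gaussian latency and amplitude jitter, plus white noise and
optionally 1/f-shaped noise. Raised-cosine windows avoid rectangular
onsets whose broadband edges would confound in/out-of-COI comparisons.
Defaults mirror a typical recording: 200-sample, 1-s epochs at 200 Hz,
195 trials per class.

`generate_dataset()` builds multi-subject, multi-channel two-class sets
in which each channel's class difference is scaled by a gain
(differential components only; shared components untouched), so the
ground-truth channel ordering is the gain ordering and gain 0 removes
the difference exactly.

`in_coi_only_spec()` relocates the differential components so their
time-frequency support lies inside the COI: latencies to the epoch
center, frequencies to two upper-middle grid bands a third-octave apart
(so a frequency-coded difference survives), durations clipped so that
the component window *plus the kernel half-width* of every band within
half an octave stays inside that band's in-COI interval. For those bands
the out-of-COI coefficients of the two class templates are then
*exactly* equal (their kernel windows never touch the component);
farther bands respond only through the wavelet's frequency selectivity
and the truncated kernel's spectral leakage. Exact equality across *all*
bands is unattainable with compactly truncated kernels on 1-s epochs —
the strict window-avoidance condition is infeasible for slow bands — so
the construction guarantees, and the tests assert, out-of-COI leakage
power below 1% of the in-COI class-difference power on noise-free
templates.

Two deliberate fixture choices for the statistical tests:

* **Phase locking.** The pipeline classifies scalograms of trial
  averages, i.e. *evoked* power, and the separation criterion compares
  cluster means. A latency jitter of 0.02 s (the generator's generic
  default, realistic for cognitive components) is a 1.5–3 rad phase
  jitter at 12–25 Hz and moves essentially all component energy from the
  evoked mean into induced (non-phase-locked) power, which neither the
  mean-based separation nor the average-then-transform pipeline can see.
  The ranking and trend fixtures therefore use phase-locked components
  (latency jitter 0.003–0.005 s).
* **Noise level.** The trend fixture uses white noise sd 2 µV against
  amplitude-1 components: single-trial component-band SNR well below 1
  (the regime subsample averaging exists for) and 4-ERP accuracies off
  the ceiling, so ordering effects have room to express themselves.

What the generator does **not** emulate: structured artifacts (blinks,
EMG), temporally autocorrelated background with cross-channel volume
conduction, non-stationary noise, latency drifts across a session, or
class differences encoded in induced power. A green trend test therefore
establishes that the implementation produces the expected ordering *when
the class difference is genuinely confined inside the COI and carried by
evoked power* — it does not certify effect sizes on real recordings.

## Numerical conventions

* Same-mode centering uses offset $\lfloor (L-1)/2 \rfloor$ into the
  full output; kernels built by the package are always odd-length, and
  the convention is fixed (and tested) for even-length kernels anyway.
* Unit-energy discrete normalization per band ($\sum |\Psi|^2 \Delta t =
  1$) is the discrete counterpart of the $1/\sqrt{a}$ CWT prefactor: the
  continuous unit-energy family is $a^{-1/2}\Psi(t/a)$.
* COI coordinates are 0-based with half-open intervals throughout.
* Same-mode padding is zero padding; no signal-extension or forecasting
  mitigation is implemented (out of scope by design).
* Convolution is FFT-based; the batch scalogram path multiplies a
  precomputed dense band-operator matrix with all epochs at once and is
  tested for equality against the per-signal path at $10^{-10}$.
* $\beta$ and the separation score define $0/0 = 0$ (with a warning for
  $\beta$); `relative_improvement()` refuses $\alpha_A \le 0$.
* Class decisions are argmax with ties to the lower class index
  everywhere (k-NN votes, forest votes, network outputs, SVM scores at
  exactly 0).
* Empty feature sets are errors, not silently empty vectors: V with an
  all-zero COI, V̄ with a full COI.

## Known limitations

* **Tree ensembles on an information-free complement.** The V̄-chance
  control requires the out-of-COI region to carry *no* class
  information, which makes those features (nearly) i.i.d. noise power.
  Greedy entropy split selection essentially never chooses such features
  while informative in-COI features exist, so zeroing them (Z) cannot
  help a random forest the way it helps distance- and kernel-based
  classifiers: in this synthetic world RF's S-vs-Z comparison is a
  statistical tie whose sign flips with the master seed, and the
  corresponding acceptance assertion is left honestly red at the pinned
  seed. Real recordings, whose edge artifacts are structured and can act
  as overfitting traps for trees, are a different regime that this
  generator deliberately does not fake.
* **Cross-validated accuracy at chance is pessimistically biased.** With
  a finite trial pool split into disjoint folds, train-fold and
  test-fold noise means are anti-correlated, so signal-free features
  generalize slightly *below* 0.5 — visibly so for small pools (≈0.44–
  0.47 at 60 trials/class) and within the expected chance band at the
  protocol's 195 trials/class. The V̄ control is therefore evaluated at
  protocol-faithful pool size.
* Reproducing any particular published scalogram geometry (e.g. a
  specific $J$ and $N_V$) requires the original frequency-grid
  construction and truncation rule; with unstated grids the package can
  match $J \times N$ exactly but not $N_V$.
* The network families are exact (gradient-checked) but pure R; at full
  feature dimensions they are slow, so tests exercise them at reduced
  sizes and epochs. The deterministic families carry the statistical
  acceptance load.
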