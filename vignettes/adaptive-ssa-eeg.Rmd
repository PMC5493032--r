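---
title: "Adaptive SSA for single-channel EEG: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive SSA for single-channel EEG: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegssa)
```

## The decomposition

Singular spectrum analysis treats an EEG segment
`s = (s_1, ..., s_N)` nonparametrically. The window length `L` maps it onto
the Hankel trajectory matrix `X` (`X[i, j] = s[i+j-1]`, `K = N - L + 1`
lagged windows), whose SVD `X = sum_i sqrt(lambda_i) v_i p_i^T` splits the
signal into `L` additive reconstructed components (RCs) after diagonal
averaging. Two facts carry the whole method:

* the decomposition is exact — the RCs sum to the input to floating
  precision, so any grouping of RC indices is an exact additive split of
  the signal;
* an amplitude-modulated sinusoid concentrates in a *pair* of eigenvalues
  of near-equal magnitude, while slow high-energy trends (ocular pulses,
  drift) dominate the *leading* eigenvalues.

The adaptive grouping rule exploits both. Artifacts: remove RC1 and RC2
when `max |s| >= V0`, otherwise RC1 only. Rhythms: pair adjacent RCs with
`|1 - lambda_{i+1}/lambda_i| < 0.05` into periodic components, then assign
every group to the rhythm band containing its FFT peak.

Assumptions worth keeping in mind: artifacts must be the highest-variance
structures in the segment (true for ocular pulses and drift at frontal
electrodes; not guaranteed for, say, line noise), the segment must be short
enough to be quasi-stationary (8 s here), and `L` must be large enough that
each rhythm occupies a narrow frequency range in its own components.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `L` | 40 | samples | window length; 0.2 s at 200 Hz. Larger L sharpens frequency separation but mixes more slowly varying artifact energy into later RCs. `L >= fs / f_low` captures one period of the lowest frequency of interest; pass `f_low` to get a warning when violated (the run proceeds). |
| `v0` | 200 | µV | artifact-level threshold. Spontaneous artifact-free EEG stays below ~100 µV, so twice that separates "contains a large artifact" from "does not". `Inf` disables removal. |
| `tol` | 0.05 | — | relative eigenvalue tolerance for declaring a periodic pair. |
| `bands` | delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–fs/2 Hz | Hz | half-open `[low, high)` intervals, so the shared edges are unambiguous. |
| `threshold` | 10 | µV² | alpha-power decision boundary between eyes-open and eyes-closed. |

## The MPA simulator

`simulate_spontaneous_eeg()` superposes four rhythms
`a_i(t) sin(2 pi m_i t + theta_i)` whose amplitudes follow first-order
Gauss–Markov (AR(1)) processes. The default parameters — dominant
frequencies (3.61, 5.76, 10.45, 16.02) Hz, increment scales (3.86, 1.23,
1.57, 0.92) µV, coefficients (0.97, 0.99, 0.99, 0.98), 8 s at 200 Hz —
emulate the power spectrum of a resting (eyes-closed-like) real EEG and
keep the summed signal in the sub-100 µV regime. Artifacts are additive:
a triangular EOG pulse train (default 400 µV peak, 3 s period, 0.3 s
width — roughly one blink every 3 s), a 20 µV / 0.5 Hz baseline sinusoid,
and white Gaussian noise.

Design choices the model statement leaves open, fixed once here:

* **Increment scale is a standard deviation.** The per-rhythm scale
  `sigma_xi` parameterizes `xi ~ N(0, sigma_xi^2)` in µV. Read as a
  variance instead, the stationary amplitude SD of e.g. the alpha rhythm
  would drop from `1.57 / sqrt(1 - 0.99^2) = 11.1` µV to 8.9 µV and the
  summed EEG would sit well below the amplitude regime the defaults are
  meant to emulate; the SD reading reproduces it.
* **Initialisation.** `a(0)` is drawn from the stationary distribution
  `N(0, sigma_xi^2 / (1 - gamma^2))`, so the process needs no burn-in and
  every sample is marginally stationary.
* **Phases.** Each `theta_i` is arbitrary; by default it is drawn uniformly
  on `[0, 2 pi)` from the seeded generator, overridable per rhythm.
* **EOG pulse shape.** Symmetric (isosceles) triangle, positive polarity,
  first onset at t = 0. Blink waveforms at frontal electrodes are
  approximately symmetric monophasic deflections.
* **Noise level.** `noise_sd = 2` µV by default — a typical measurement
  noise floor, small against both rhythms and artifacts; configurable.
* **Grid.** `t = n * dt`, `n = 0..N-1`: t = 0 included, the nominal
  duration excluded, so 8 s at 5 ms is exactly 1600 samples.

What the simulator does **not** emulate: 1/f background activity, EMG
bursts, electrode pops, non-stationary rhythm frequencies, or any
dependence between rhythms. Passing tests on this generator therefore
demonstrate correct mechanics (exact decomposition, adaptive branch
selection, band sorting, power features) and recovery of amplitude-
modulated narrowband sources — not performance on real recordings, which
is why the package also reads plain CSV segments.

## Numerical choices

* **SVD of `X`, not eigendecomposition of `C = XX^T`.** Equivalent in exact
  arithmetic (`lambda_i` = squared singular value) and better conditioned;
  the test suite cross-checks against a brute-force `XX^T` eigensolver at
  small sizes. When `L > K` the missing `L - K` eigenvalues are exact
  zeros and are padded as such.
* **Rank-1 diagonal averaging by convolution.** The anti-diagonal sums of
  `u w^T` are the linear convolution of `u` and `w`; each RC costs one FFT
  convolution instead of an `L x K` sweep. The generic
  `diagonal_average()` keeps the direct definition.
* **Zero eigenvalues** have undefined right factors; their columns are set
  to zero, making the elementary matrix (and RC) exactly zero.
* **Eigenvector signs** are unconstrained; every contract is stated on RCs,
  which are sign-invariant.
* **Pairing is adjacent-only and greedy from the top.** Eigenvalue
  similarity alone would chain runs of close eigenvalues (common in the
  noise tail) into arbitrary blobs; a sinusoid's pair is adjacent in the
  spectrum, so adjacency is both sufficient and safely restrictive. Ties
  and near-ties resolve in stable SVD output order.
* **Peak frequency** uses 4x zero-padding (resolution fs/4N), excludes the
  DC bin so residual offsets never count as a rhythm, and breaks ties
  toward the lower frequency. The peak of a pair is computed on the summed
  pair, not its halves — the halves are quadrature components of one
  oscillation and share a spectrum.
* **Boundary cases.** Amplitude exactly at `V0` takes the conservative
  two-RC branch; `max(s)` is evaluated on `|s|` because EEG is bipolar;
  power exactly at the classification threshold is called eyes-closed
  (the "otherwise" branch); groups peaking below the lowest band edge
  (1 Hz) or above the highest are dropped to a reported residue rather
  than forced into a band; a constant (zero-variance) group has no defined
  peak and is likewise dropped.

## Problem sizes

Validation throughout uses the study conditions themselves: 8 s segments
(N = 1600) at 200 Hz, L = 40, medians over 20 seeded segments for
stochastic quantities, 100 short random signals for the exactness
property, and 10 brute-force oracle comparisons at N ≤ 30, L ≤ 8. The
whole suite runs in well under a minute.

## Known limitations

* A sharp triangular pulse train is far from rank-2 in trajectory space:
  its two leading eigentriples carry most but not all of its energy, so a
  fixed two-component artifact estimate leaves pulse-shaped residue in the
  corrected signal. Larger `L` or more removed components would trade
  rhythm integrity for cleaner pulses; the adaptive rule deliberately
  fixes the count at one or two.
* With artifact removal always taking at least RC1, an artifact-free
  segment loses its single highest-energy component — usually (not always)
  part of the slow delta activity. Rhythm-band recovery of the remaining
  bands is unaffected because the decomposition is exact.
* Band assignment is winner-takes-all by peak frequency; a group whose
  spectrum straddles a band edge contributes wholly to one band.
* The eyes-open/eyes-closed threshold is a fixed scalar on one feature;
  distributions of alpha power across segments overlap it when the
  open-state suppression is mild, and no per-subject calibration is
  attempted.
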