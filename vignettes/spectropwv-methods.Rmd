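---
title: "Estimating cf-PWV from pulse-wave spectrograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cf-PWV from pulse-wave spectrograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectropwv)
```

## The estimation problem

Carotid-to-femoral pulse wave velocity (cf-PWV, m/s) is the reference
index of central arterial stiffness, but its direct measurement needs two
simultaneous arterial recordings and a path-length estimate. This package
implements an indirect route: a *single* cardiac cycle of a peripheral
pulse wave — a photoplethysmogram (PPG) or a blood-pressure (BP) waveform
at the radial, digital or brachial site — is turned into a square
time–frequency image, image features are extracted, and a regression
model maps the features to cf-PWV. The premise is physiological: arterial
stiffening accelerates the reflected pressure wave, so the timing and
relative size of the reflected component reshape the single-cycle
waveform, and the spectrogram exposes that morphology jointly in time and
frequency.

The pipeline has five stages, each exposed as package functions:

1. waveforms (`synthesize_pulse()`, `generate_cohort()`,
   `read_database_csv()`), with optional SNR-controlled noise
   (`add_noise_snr()`);
2. square spectrogram images (`compute_spectrogram()`), scored by
   coefficient-of-variation quality indices (`quality_coefficients()`);
3. one of three feature families: Schrödinger-spectrum (SCSA) features
   (`scsa_features()`, 36 values), Laws' texture-energy features
   (`texture_features()`, 102 values), or central-moment features
   (`moment_features()`, 6 values);
4. greedy maximum-relevance minimum-redundancy ranking, F-test
   correlation quotient variant (`mrmr_rank()`, `choose_k()`);
5. a five-model regression harness (`pwv_fit()`), reporting held-out
   R² and RMSE.

`run_pipeline()` chains all stages under one root seed.

## The synthetic cohort: what it emulates, and what it does not

The generator stands in for an in-silico haemodynamic database of
virtual healthy adults. Its defaults reproduce that database's
descriptors: six age groups of equal size (729 subjects each, 4,374 in
total), one cardiac cycle per subject sampled at 500 Hz, heart rates
uniform on 66–86 bpm, and a latent cf-PWV whose distribution shifts
upward with age group (truncated normals with means linearly spaced over
6.5–12.5 m/s, sd 0.8 m/s, truncated to 4–16 m/s) — the standard
observation that central arteries stiffen with age.

Each waveform is a sum of three Gaussian lobes: a systolic lobe, a
reflected lobe and a broad diastolic lobe. The reflected lobe arrives
`2 * d_eff / cf_pwv` seconds after the systolic peak (round trip over an
effective reflection path, default `d_eff = 0.5` m) and its relative
amplitude grows linearly with cf-PWV, so morphology depends on the
target monotonically and with the physiologically correct sign. A small
seeded jitter (2% sd) of lobe timings and widths creates subject-level
variability beyond cf-PWV and heart rate. The lobe widths (22–25 ms
systolic, 35 ms reflected) are narrower than typical in-vivo upstrokes;
they are chosen so the reflected wave remains a distinct local maximum
over the physiological 5–14 m/s range, which lets tests verify the
delay–stiffness monotonicity by brute-force peak search.

What the generator does **not** emulate: wave-propagation physics (no
1-D arterial network is solved), site-specific transfer functions beyond
a small fixed extra delay, baseline drift, or measurement artifacts other
than additive Gaussian white noise. Consequently, passing the end-to-end
recovery tests shows that the feature extractors and the learning
harness can recover a latent stiffness parameter that monotonically
shapes waveform morphology at realistic noise levels — it does not show
performance on real arterial signals.

Noise is injected in the time domain before the spectrogram, as
electrical recording noise would be. The target SNR uses the signal
power of the *mean-removed* signal; otherwise the ~80 mmHg DC offset of
BP waves would make the stated SNRs (20/10/5 dB for BP, 65/45/30 dB for
PPG) vacuous. The noise is white; no high-pass shaping is applied.

## Spectrogram construction and quality scoring

The short-time Fourier transform uses a Hamming (default) or Kaiser
window with a configurable overlap percentage, one-sided frequencies,
and magnitude scale. Magnitude (not dB) is the default because the SCSA
stage requires a positive image. A single cycle of ~400–450 samples
cannot directly produce a 250×250 spectrogram, so the window length is
tied to the signal (`floor(length / 8)` by default) and the magnitude
image is bilinearly resampled to the requested square size
(20/50/100/166/250 grid; 250 is the standard operating point, 50 is used
in this package's own experiments — see *Problem sizes* below). The
resized image is min–max scaled to [0, 1]; a constant image maps to all
zeros so degenerate inputs stay well defined.

Candidate configurations are ranked by the mean coefficient-of-variation
quality indices: `Qf` averages sd/mean across frequency rows, `Qt`
across time columns, and `Qtf = Qf * Qt`. Standard deviations are
population (divisor N) throughout, and rows or columns with zero mean
contribute 0 rather than dividing by zero. The indices are computed on
the resized image, i.e. on the object every later stage consumes.

## Semi-classical signal analysis (SCSA)

SCSA represents a positive signal through the discrete negative spectrum
of the semi-classical Schrödinger operator `-h² d²/dx² - signal`. The
second derivative is discretized by the periodic Fourier pseudospectral
matrix on a unit grid (the convention of the SCSA literature; a
central-difference fallback is available via `method = "central"`). The
diagonal constants are the exact trigonometric-interpolation values
(−π²/3Δ² − 1/6 for even n, −π²/3Δ² + 1/12 for odd n), which makes the
assembled matrix agree to machine precision with the DFT route
`F⁻¹ diag(−ω²) F` used as the independent oracle in the tests. An
eigenvalue counts as a bound state when it is below
`−1e−10 · max|λ|`; without this tolerance the positive-semidefinite
zero-signal operator would spuriously report round-off eigenvalues.

For images the operator is separated: each row and each column is
decomposed independently and the reconstruction combines the two
families per pixel,

```
I(i,j) = [ h²/L_cl · Σ_{k,r} ((−β_ik) + (−ρ_jr))^γ ψ²_ik(j) φ²_jr(i) ]^(1/(1+γ)),
L_cl = Γ(γ+1) / (4π Γ(γ+2)).
```

The operating `h` is the image-level sampling bound `h_min`: per-row and
per-column values `T_s √(max) / π` are averaged pairwise and the maximum
over pixels is taken, the safest choice against aliasing. `T_s = 1`
after resizing, since the resized image has no physical axis. `γ` is
selected from the grid {0.5, 1, 2, 3, 4, 5} by maximizing SSIM between
the original and the reconstruction (both min–max scaled; Gaussian
11×11/σ=1.5 SSIM, window shrunk for tiny images), with ties broken by
PSNR and then by the smaller γ. Small `h` pairs with larger `γ`: the
reconstruction-convergence test therefore selects γ at the *finest* h of
its sweep before checking that the error falls monotonically as h is
halved from `h_min`.

The 36 features are 12 statistics on each of three κ-matrices
(`κ = (−λ)^γ`, sorted descending within each line and zero-padded): the
per-row matrix, the per-column matrix, and their element-wise sum after
zero-padded alignment (the ragged-spectrum combination is otherwise
undefined). Per matrix: three spectral invariants
`INV1 = 4h Σκ, INV2 = 16h³ Σκ³, INV3 = 256h⁷ Σκ⁷` (constants
configurable via `inv_consts`, defaults as conventionally printed),
`K1..K3` (mean of the rank-n κ), `E1..E3` (mean of the rank-n
eigenvalue magnitude `κ^(1/γ)`), `Rh = max κ / h`,
`MRh = median(κ over actual eigenvalues) / h`, and `Nh` (mean bound-state
count). Twelve per matrix is the composition that honors the published
total of 36; the mean and sd of κ are additionally emitted as a
diagnostics attribute outside the 36-vector. An image with no bound
state in any row or column yields the all-zero vector with an
`empty_spectrum` flag.

## Laws' texture energy

The bank is all 34 separable masks: 9 outer products of
{L3, E3, S3} and 25 of {L5, E5, S5, W5, R5}. Convolution is true
convolution (kernel flipped), same output size, with **replicate**
(nearest-edge) padding: with zero padding a constant image would show
spurious edge responses at the border, violating the defining property
that zero-sum masks produce exactly zero energy on flat images. The
filtered image is min–max normalized (flat output → all zeros), and the
energy image is the moving 15×15 sum of absolute values with zero
padding at the borders (the literal windowed sum; a divisor is exposed
for the moving-average variant). Per mask, three statistics — mean,
population sd, and mean of squares (`EN`; it is an energy although
customarily labeled entropy) — give 102 features. The implementation is
a shift-accumulate, bit-exact against a naive double-loop oracle
(FFT-based convolution is not, which is why none is used).

## Central moments

`μ_k = mean((I − mean(I))^k)` for k = 2, 3, 4, on the raw and the
min–max-normalized image: `F1 = log10(√μ2 + ε)`, `F2 = μ3`,
`F3 = log10(μ4 + ε)`, `F4 = √μ̂2`, `F5 = μ̂3`, `F6 = μ̂4`, with
`ε = 1e−12` keeping flat images finite. The raw third/fourth moments are
used, not standardized skewness/kurtosis; a `standardized = TRUE`
variant provides the classical normalization. F4–F6 are invariant to
positive affine intensity transforms by construction.

## Feature selection and learning

MRMR-FCQ ranks features greedily: the first pick maximizes the
univariate-regression F-statistic `F = r²(n−2)/(1−r²)` against cf-PWV;
each later pick maximizes `F / mean |ρ|` over the already-selected set.
The absolute Pearson correlation is used (a signed mean could flip the
score's sign), correlations with constants count as zero, and an
all-zero denominator is floored at 1e−12 so fully novel features keep
their relevance. Ties break by feature name, making the ranking fully
deterministic. The number of retained features can be fixed, left at
"all", or chosen by `choose_k()`, which scores each candidate count by
mean cross-validated R² across the model set with default
hyperparameters — cross-validation rather than the held-out test set, to
avoid leakage.

`pwv_fit()` splits 70/30 (training size exactly `floor(0.7 n)`,
apportioned across age groups by largest remainder so the cf-PWV range
stays balanced; an unstratified mode exists), ranks features on the
training rows only, standardizes with train-only mean and population sd
(σ floored at 1e−12 for constant features), and trains five models:
random forest, gradient boosting, a single-hidden-layer perceptron,
multiple linear regression, and RBF support-vector regression. Random
search draws hyperparameters from shipped default spaces; draw 1 is
always the library-default configuration and draws are a nested
sequence, so increasing the budget can only improve the best
cross-validated score. All stochastic components (split, folds, search,
model initialisation) derive named substreams from one root seed, making
every run bit-reproducible; permuting the test targets provably leaves
the fitted models unchanged.

## Problem sizes and numerical choices

The package's own experiments (tests and the acceptance script) run the
end-to-end study at 600 subjects (6 × 100), 50×50 spectrograms, and
search budget 1 (library defaults): a size at which the per-row/column
eigendecompositions (100 symmetric 50×50 solves per subject) remain
inexpensive while every qualitative claim — per-family held-out
R² ≥ 0.9 on the noise-free cohort and monotone degradation across the
stated SNRs — is testable. The full 4,374-subject cohort and 250×250
images are supported through the same functions. Small-instance oracle
checks use 8–20-pixel images, where dense eigensolves and double-loop
convolutions are exact references.

Degenerate-input rules adopted throughout: min–max of a constant image
is all zeros; zero-mean rows/columns contribute 0 to the quality
indices; an all-zero image has undefined `h_min` (error) but yields
all-zero SCSA features with a flag; R² is an explicit error for a
zero-variance target.

## Known limitations

- The waveform generator is a morphological surrogate, not a
  haemodynamic simulation; absolute performance numbers on it do not
  transfer to in-vivo data or to the original in-silico database.
- Reproducing the published per-model accuracy tables requires that
  external database; the package supports it through the CSV loader but
  does not bundle it.
- The separated (row/column) SCSA is an approximation of the full 2-D
  operator spectrum; the full eigenproblem is intentionally out of
  scope for cost.
- Single-cycle inputs only: multi-cycle recordings change the
  spectrogram structure and are not modelled.
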