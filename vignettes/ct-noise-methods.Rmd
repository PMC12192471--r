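---
title: "Methods: frequency-resolved CT noise analysis with ctnps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-resolved CT noise analysis with ctnps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Why a noise power spectrum

Iterative reconstruction (IR) in CT does not merely reduce image noise; it
changes its spatial correlation. Two images with identical noise SD can look
entirely different — fine grain versus "blotchy" low-frequency mottle —
and the difference matters for low-contrast detectability in the brain. The
noise power spectrum (NPS) resolves noise variance over spatial frequency
(1/mm) and is the standard descriptor of that texture. `ctnps` estimates it
from ensembles of repeated reconstructions, compares reconstruction methods
band-wise, and runs the accompanying observer-score and ROI statistics.

## The ensemble difference-image estimator

For an ensemble of `n_rep` reconstructions of one slice, the per-slice
estimator in `ensemble_power_map()` is

NPS(fx, fy) = (n/(n−1)) · mean_r |FT(I_r − Ī)|² · Δ²/N_pix,

with Δ the pixel size (mm) and N_pix the pixels per slice. Three numerical
choices deserve comment:

* **Each difference image is transformed separately** and the `n` power maps
  averaged. Averaging the difference images *before* transforming would give
  identically zero (they sum to zero by construction), so only this order of
  operations yields a spectrum.
* **Squared modulus.** We use |FT|²; with the `Δ²/N_pix` normalisation the
  white-noise closed form NPS = σ²Δ² holds exactly, and Parseval's identity
  links the curve back to per-pixel variance. A first-power modulus would
  break both.
* **`n/(n−1)` bias factor.** Subtracting the ensemble sample mean shrinks
  each difference image's variance by `(n−1)/n`; the factor undoes this, so
  estimates from `n = 5` and `n = 50` repetitions agree in expectation (a
  property the test suite checks).

The DC bin carries only the residual mean and is effectively zero; tests and
comparisons exclude it.

### From 2-d map to 1-d curve

`directional_spectrum()` samples the map along a straight line through DC at
a given angle by bilinear interpolation, at steps of one axis-frequency bin
(1/(N·Δ) 1/mm), out to the map boundary. Nearest-neighbour sampling was
rejected: on diagonal lines it aliases between adjacent bins. The default
18 angles (10°–180° in 10° steps) are averaged per frequency by
`angular_average()`. Beyond the axis Nyquist frequency `1/(2Δ)` only
near-diagonal lines reach; the returned `support_count` column records how
many angles contributed at each frequency so users can threshold sparsely
supported bins (with 0.429 mm pixels the axis Nyquist is 1.166 1/mm and
diagonals reach √2 times that, 1.649 1/mm). `cohort_nps()` finally takes an
unweighted mean over slices.

### Band comparison and crossovers

`band_integrals()` integrates a curve by the trapezoidal rule over
[0, 0.5088], (0.5088, 1.3084] and (1.3084, f_max] 1/mm — the default band
boundaries are the two frequencies where the SAFIRE-like and ADMIRE-like
noise textures exchange rank. Boundary points are inserted by linear
interpolation so the three bands partition the total integral to rounding
error. `relative_improvement()` is defined as 100·(reference − test)/reference
(no standard definition exists for this quantity; this one is positive
exactly where the test method has less noise, and its zero crossings are the
rank-exchange frequencies). `find_crossovers()` interpolates sign changes
linearly; runs of exact zeros collapse to their midpoint.

Monte-Carlo fluctuation of estimated spectra can flip the sign of a small
difference several times near a true crossing. The pipeline therefore
applies a centred moving average (`smooth_nps()`, default window 7 bins)
before crossover detection. The window is deliberately small: a moving mean
is exact on locally linear curves, so it does not displace a crossing, while
reducing per-bin noise by ~1/√7. `find_crossovers()` itself never smooths;
the choice is exposed as `smooth_window` in `run_config()`.

## The synthetic ensemble generator

The generator exists so the full pipeline can be exercised and validated
without clinical raw data. It emulates three things:

1. **Noise textures.** Target spectra come from the family
   NPS_t(f) = A·(f/f0)^p·exp(−(f/f0)^q) — three parameters spanning
   ramp-like high-frequency-weighted (FBP-like) and low-frequency-shifted
   (IR-like) textures. `synthesize_ensemble()` shapes white Gaussian fields
   in the frequency domain by √NPS_t/Δ, so the expected estimated NPS equals
   the target and per-pixel variance equals the 2-d integral of NPS_t
   (Parseval; verified to 3% in tests). Poisson sinogram simulation was
   rejected: it would require a reconstruction operator that is not part of
   this package's scope.
2. **Dose reduction.** `simulate_dose_reduction()` adds independent noise
   with the same spectral shape and variance σ²(1/fraction − 1), so total
   noise variance scales as 1/dose — a quantum-noise-only model. Detector
   electronic read-out noise, tube-current modulation and beam hardening are
   deliberately unmodelled; conclusions about very low doses, where
   electronic noise matters, are outside what passing tests demonstrate.
3. **Method ordering.** `default_method_profiles()` fixes q = 1.6
   (SAFIRE-like) and q = 2.6 (ADMIRE-like) with shared f0 = 1 mm⁻¹, and
   solves a 2×2 linear system in log space for the rise-exponent offset and
   amplitude ratio such that the two target curves cross *exactly* at the
   0.5088 and 1.3084 1/mm band boundaries. The FBP-like profile reuses the
   lower rise exponent with twice the ADMIRE-like amplitude, f0 = 1.3 and
   q = 2, which keeps it above both IR profiles by ≥2.5× in power up to the
   diagonal Nyquist limit. Amplitudes beyond these ordering constraints are
   free parameters; the ADMIRE-like amplitude of 3.9 HU²·mm² was chosen to
   give a realistic ~3 HU per-pixel noise SD for a smooth-kernel head
   reconstruction at full dose. Absolute spectral levels are therefore
   nominal: only orderings, crossings, ratios and closed-form identities are
   validated, not absolute clinical noise magnitudes.

The head phantom (`make_head_phantom()`) is a deterministic ellipse layout —
bone shell, brain background, paired thalamus-like gray-matter and frontal
periventricular white-matter regions at fixed HU — adequate as a carrier for
noise and for ROI sampling, not an anatomical model. Because the estimator
subtracts the ensemble mean, anatomy cancels exactly and no detrending
beyond that is attempted.

### Score and ROI table generators

`generate_roi_table()` draws per-subject HU values with a shared per-subject
offset: all methods reconstruct the same scan, so within-subject values must
be correlated. The intraclass correlation defaults to 0.8 — the paired
design implies strong correlation but no published value exists, so this is
a package choice, fixed once. `generate_likert_table()` reproduces each
ordinal summary cell (median/IQR/mean/SD over 21 readings) by exhaustive
search for an integer multiset matching mean and SD within 0.05, searching
the smallest support first (single value, then value pairs, then all value
triples, then four consecutive values — the widest printed SDs, e.g.
5.48 ± 0.93, have no two-value solution). Infeasible summaries (an SD no
integer multiset can achieve) return the nearest multiset with a warning.
Scores are assigned concordantly via one latent subject ranking so paired
tests see realistic positive correlation.

## The statistical battery

The battery mirrors the conventions of the commercial package such analyses
are usually run in:

* `lilliefors_ks()` — KS distance to a normal with estimated parameters;
  p-value from a seeded Monte-Carlo null (default 10,000 replicates) since
  the classical KS null does not apply with estimated parameters. The
  downstream screening threshold is p ≥ 0.01.
* `levene_test()` — classical mean-centred Levene (not the median-centred
  Brown–Forsythe variant).
* `oneway_anova()` / `oneway_anova_summary()` — the summary-statistic form
  reconstructs F from printed group means/SDs/sizes, which is how published
  tables are audited without raw data. The between-groups ANOVA is retained
  for the HU tables even though the design is paired — fidelity to the
  published analysis over statistical optimality.
* `bonferroni_pairwise()` — pooled-MS t comparisons; CI at t(df_within,
  α/(2m)), adjusted p = min(1, m·p); `sem = √(MS_within·2/n)`.
* `wilcoxon_signed_rank()` — zero differences dropped, midranks for ties,
  tie-corrected normal variance, no continuity correction. Exact enumeration
  (all 2ⁿ sign assignments) serves as the test oracle for n ≤ 12; with
  heavily tied small samples the normal approximation is intrinsically
  coarse, which the tests acknowledge by asserting the measured
  approximation accuracy rather than exact agreement.
* `rm_anova_gg()` — one-way repeated-measures ANOVA over the
  method × dose conditions (a 9-condition design with 21 subjects gives
  df = 8, 160). The published "mixed-effects" structure is unspecified;
  this is the simplest model consistent with those degrees of freedom.
  Greenhouse–Geisser ε comes from the contrast-projected condition
  covariance and is applied when Mauchly's test rejects sphericity at 0.05;
  ε is always reported, and k = 2 forces ε = 1. Partial η² uses the
  uncorrected sums of squares (the correction rescales both df equally).
* `effective_dose()` — DLP × 0.0021 mSv/(mGy·cm), the ICRP head
  coefficient; stored per record, not hard-coded, so other regions can be
  summarised.

α = 0.05 throughout. All Monte-Carlo machinery takes explicit seeds and
restores the caller's RNG state.

## Problem sizes and tolerances

The validation suite scales simulations to what the properties require:
Parseval and dose-scaling identities use ≥50 slices (3% tolerance);
white-noise and transfer-function recovery use 200 slices at 128² (5%);
crossover recovery runs the full pipeline at 120 slices × 5 repetitions of
128² slices, where the two recovered crossings land within ±0.02 1/mm of the
calibrated values across seeds (the acceptance check allows ±0.05); type-I
calibrations use 2,000 simulations against a 3σ binomial band. The 128²
matrix (rather than the protocol's 512²) changes only frequency resolution
(bins of 0.018 1/mm), not any of the identities being checked.

## Known limitations

* Axial-plane 2-d analysis only; no 3-d NPS, no MTF or NEQ.
* The generator's spectra are radially symmetric by construction; real
  scanner noise is mildly anisotropic, and the angular machinery exists
  precisely because one should not assume isotropy.
* Anatomical slice selection is replaced by an explicit slice-range
  configuration; no anatomy detection.
* No DICOM reader: ensembles are exchanged as NIfTI or a plain-text array
  dump with a JSON sidecar, dose records as CSV.
* Absolute NPS levels from the generator are nominal (see above); only
  relative structure is meaningful.
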