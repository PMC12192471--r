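# ctnps

Frequency-resolved noise analysis for repeated CT reconstructions.

Radiologists comparing reconstruction algorithms — classical filtered back
projection (FBP) against vendor iterative reconstruction (IR) families such
as SAFIRE and ADMIRE — need more than a single noise SD: IR does not just
lower noise, it reshapes its *texture*, shifting the noise power spectrum
(NPS) toward lower spatial frequencies. `ctnps` implements the ensemble
difference-image NPS estimator used to quantify that effect in unenhanced
head CT, the band-wise comparison machinery that locates where one
algorithm beats another, the accompanying statistical battery for ROI
Hounsfield-unit tables and ordinal image-quality scores, and effective-dose
bookkeeping. A seed-controlled synthetic generator of CT noise ensembles
makes the entire pipeline testable without clinical data.

## The estimator

Given `n` repeated reconstructions `I_1 … I_n` of the same slice (the
protocol uses `n = 5`), the ensemble mean is subtracted and each difference
image is Fourier transformed:

```
NPS(fx, fy) = n/(n-1) * (1/n) * sum_r | FT[ I_r - mean(I) ] |^2 * Δ² / N_pix
```

with pixel size `Δ` (mm) and `N_pix` pixels per slice; units are HU²·mm².
The `n/(n-1)` factor corrects the bias from subtracting the sample mean, and
the normalisation makes white noise of variance σ² come out flat at `σ²Δ²`
exactly. The 2-d power map is reduced to 1-d by sampling along 18 straight
lines through DC (10°–180° in 10° steps, bilinear interpolation), averaging
over angles (beyond the axis Nyquist `1/2Δ` only near-diagonal lines still
contribute; a per-frequency support count records how many), and averaging
over slices. Curves are compared by trapezoidal band integrals over
`[0, 0.5088]`, `(0.5088, 1.3084]` and `(1.3084, f_max]` 1/mm, by the
relative-improvement curve `100·(ref − test)/ref`, and by its
linearly-interpolated zero crossings.

The synthetic generator shapes white Gaussian fields in the frequency domain
with target spectra from the family `A (f/f0)^p exp(-(f/f0)^q)`, calibrated
so the SAFIRE-like and ADMIRE-like textures cross exactly at 0.5088 and
1.3084 1/mm and the FBP-like texture dominates both everywhere; dose
fractions scale noise power as `1/dose` (quantum-noise model).

## Worked example

```r
library(ctnps)

# synthesize 40 slices x 5 repetitions per method and estimate cohort spectra
ph <- make_head_phantom(phantom_spec(matrix_size = 128, n_slice = 40))
profiles <- default_method_profiles(dose_fraction = 1)
curves <- lapply(profiles, function(p) {
  smooth_nps(ensemble_nps(synthesize_ensemble(ph, p, n_rep = 5, seed = 7)), 7)
})

band_integrals(curves$ADMIRE)
#> # A tibble: 1 × 6
#>   low_band mid_band high_band total f_low f_high
#>      <dbl>    <dbl>     <dbl> <dbl> <dbl>  <dbl>
#> 1    0.525     1.20    0.0916  1.82 0.509   1.31

find_crossovers(relative_improvement(curves$SAFIRE, curves$ADMIRE))
#> [1] 0.5105955 1.3096825
```

The two crossover frequencies recovered from the simulated ensembles
(0.511 and 1.310 1/mm) bracket the mid-frequency band where the SAFIRE-like
texture is quieter; outside it the ADMIRE-like texture wins. Band integrals
are in HU²·mm²·(1/mm).

```r
gm <- dplyr::filter(reference_roi_summary(), tissue == "GM", dose == 1)
oneway_anova_summary(gm$mean_hu, gm$sd_hu, 21)
#> # A tibble: 1 × 5
#>   statistic   df1   df2  p_value ms_within
#>       <dbl> <dbl> <dbl>    <dbl>     <dbl>
#> 1      7.90     2    60 0.000899      1.53

partial_eta_sq(1000.731, 8, 160)
#> [1] 0.9804062

effective_dose(638.4)   # mSv from a 638.4 mGy*cm dose-length product
#> [1] 1.34064
```

Gray-matter HU differs between reconstruction methods (p ≈ 0.001, driven by
SAFIRE's ~1.3 HU offset), the pooled subjective-score repeated-measures
effect has partial η² = 0.980, and the cohort-mean DLP converts to a
1.34 mSv effective dose.

An end-to-end run (`run_full(run_config(...))`) produces cohort NPS curves,
band summaries, crossover reports, ROI and Likert score tables with their
full statistical battery, and a dose summary, optionally written as CSV/JSON
with a seeded manifest. `inst/cli/ctnps.R` wraps the same functions as a
command-line tool with `simulate`, `nps`, `compare`, `stats` and `full`
subcommands.

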