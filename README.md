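# impactT2

Quantitative MRI analysis of post-traumatic cartilage degeneration: T2
mapping, depth-wise layer analysis, and GLCM texture features for
longitudinally imaged cartilage explants exposed to standardized drop-tower
impaction.

## The problem

Traumatic cartilage injury initiates a degenerative cascade (post-traumatic
osteoarthritis) long before morphologic damage is visible. The transverse
relaxation time T2 is sensitive to the collagen network and tissue water, so
serial T2 mapping of explants before and after a controlled impaction can
track early degeneration — both as mean T2 per region of interest and as the
*spatial texture* of the T2 map. This package implements that analysis chain
for anyone studying impaction models of cartilage degeneration, and ships a
synthetic-data generator so every step is testable end to end without scanner
data.

## What it computes

- **Impaction energetics.** A drop weight of mass *m* falling from height *h*
  strikes at *v* = √(2*gh*) with energy *E* = *mgh*. The two standard arms are
  low impact (0.5 kg × 100 mm → 0.49 J) and high impact (1.0 kg × 100 mm →
  0.98 J), plus unimpacted controls.
- **T2 relaxometry.** Multi-echo spin-echo signals S(TE) = S₀·exp(−TE/T2) are
  fitted pixel-wise, by default from echoes 2–7 of a 12-echo train with
  8.38 ms spacing (TE < 60 ms, first echo discarded against stimulated-echo
  artefacts). Log-linear least squares by default; damped Gauss–Newton
  refinement optional.
- **Layer ROIs.** The whole-sample mask is split per image column into equally
  thick superficial and deep layers (odd heights give the extra pixel to the
  superficial side).
- **GLCM texture.** T2 maps are quantized (32 levels over 0–120 ms), and
  gray-level co-occurrence matrices at one-pixel offsets in the 0°, 45°, 90°,
  135° orientations yield contrast Σp(i,j)(i−j)², homogeneity
  Σp(i,j)/(1+|i−j|), energy Σp(i,j)², and variance Σp(i,j)(i−μ)²; features
  are averaged over orientations.
- **Longitudinal statistics.** Relative change Δₓ = ((T2ₜₓ/T2ₜ₀) − 1)·100 %;
  Friedman + Dunn post hoc within groups over time; Kruskal–Wallis between
  groups per time point; one-way ANOVA + Tukey HSD on relative changes.
  Significance level 0.01 throughout.
- **Synthetic cohorts.** `generate_cohort()` simulates 7 control / 14
  low-impact / 14 high-impact samples over four time points: depth-graded
  baseline T2 (superficial ≈ 37–43 ms > deep ≈ 26–29 ms), control drift,
  a band-like transitional-zone lesion (low impact), a growing diffuse lesion
  (high impact), and Rician noise at SNR 50.

## Worked example

```r
library(impactT2)

protocol_table()
#>   group mass_g height_mm velocity_m_s energy_J
#> 1  CONT      0         0     0.000000   0.0000
#> 2  LIMP    500       100     1.400714   0.4905
#> 3  HIMP   1000       100     1.400714   0.9810

cohort <- generate_cohort(rng_seed = 42)   # 7/14/14 samples, t0..t3
tab <- cohort_measurements(cohort)

# whole-sample mean T2 [ms] per group and time point
aggregate(value ~ group + time_point,
          subset(tab, roi == "whole" & measure == "t2_mean"), mean)
#>    group time_point    value
#>     CONT         t0 31.83235   ...   CONT t3 34.38171
#>     LIMP         t0 31.28365   ...   LIMP t3 40.87876
#>     HIMP         t0 34.84226   ...   HIMP t3 58.73384

friedman_dunn(tab, "HIMP", "whole", "t2_mean")$p_value
#> [1] 4.012127e-09        # high-impact T2 rises over time
kruskal_wallis(tab, "t3", "whole", "t2_mean")$p_value
#> [1] 1.689942e-06        # groups separate at the last time point
```

Mean T2 rises with impaction energy (controls stay near baseline), the
high-impact texture degrades (contrast and variance up, homogeneity and
energy down), and the statistical battery flags both the longitudinal rise
and the between-group separation — the qualitative signature of progressive
post-traumatic degeneration.

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate.R` → `04_null_calibration.R`) writing their tables to
`results/`; simulated image stacks go to `scratch/`.

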