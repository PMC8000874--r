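---
title: "Methods: T2 mapping and texture analysis of impacted cartilage phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T2 mapping and texture analysis of impacted cartilage phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices, and numerical
decisions behind impactT2. It is the reference for *why* the pipeline is
built the way it is; the README shows *how* to run it.

## Scientific setting

Articular cartilage responds to injurious mechanical loading with a
degenerative cascade whose earliest signs are compositional, not
morphologic. The MRI relaxation time T2 reflects collagen integrity,
fibre organization, and water content, so pixel-wise T2 maps of cartilage
explants imaged serially around a standardized impaction can quantify early
post-traumatic degeneration. Two complementary readouts are used: ROI mean
T2 (whole sample, superficial half, deep half) and texture features of the
T2 map that capture the *spatial arrangement* of T2 values, which changes
when the orderly depth-wise stratification of healthy cartilage breaks down.

The experimental design encoded in `protocol_table()` has three arms —
unimpacted controls (CONT, n = 7), low impact (LIMP, 0.5 kg from 100 mm,
0.49 J, n = 14), and high impact (HIMP, 1.0 kg from 100 mm, 0.98 J, n = 14)
— imaged at four time points: before (t0) and immediately after impaction
(t1), then 24 h (t2) and 72 h (t3) later.

## Signal model and T2 fitting

Each pixel follows a mono-exponential decay
$S(TE) = S_0 \exp(-TE/T_2)$ sampled at $TE_n = n \times 8.38$ ms,
$n = 1..12$. Fitting uses echoes 2–7 only: the first echo is excluded
because stimulated echoes bias it, and echoes with TE ≥ 60 ms are excluded
for insufficient SNR. Two fitters are provided:

- **loglinear** (default): closed-form least squares of $\log S$ on TE.
  Deterministic, exact on noiseless data, and fast enough to fit thousands
  of maps per minute. Its known weakness is noise-floor bias on magnitude
  data at low SNR, because the log transform distorts the Rician error
  distribution.
- **nonlinear**: damped Gauss–Newton (Levenberg–Marquardt) on the signal
  scale, vectorized across pixels, initialized from the loglinear estimate.
  Used where accuracy under noise matters; the two agree to 1e-8 on
  noiseless data (tested).

The model deliberately has no offset/noise-floor term, matching the standard
two-parameter analysis of this experiment class; the resulting small
positive bias at very low SNR is a documented limitation rather than a
corrected one. Fitted T2 is clamped to [1, 300] ms; clamped pixels (e.g.
non-decaying signals) are flagged and excluded downstream, as are pixels
with any non-positive signal in the fit subset (unfittable under the log
transform) and pixels with fit R² below 0.7. The R² threshold and clamp are
configuration, not constants of nature: no published pixel-rejection rule
exists for this design, so conservative defaults sit in `fit_t2_map()`
arguments.

## Layer ROIs

The whole-sample mask (always an *input*; segmentation is out of scope) is
split per image column into two equally thick layers: with the articular
surface at row 1, the top $\lceil h/2 \rceil$ of the $h$ mask pixels in a
column are superficial, the rest deep. Odd heights must break the tie
somewhere; the extra pixel goes to the superficial layer, a documented and
tested convention (the alternative is equally defensible; the choice is
exposed by the ceil rule rather than hidden). Columns are image columns, not
surface-normal chords — adequate for near-flat explant surfaces, and exactly
the regime the phantom's mild surface undulation exercises. Masks must be
vertically contiguous per column; gaps raise an error rather than producing
a silently wrong height.

## GLCM texture features

T2 maps are quantized to L = 32 levels over a **fixed** 0–120 ms range by
default. Fixed binning keeps level images comparable across samples and
time points, so a longitudinal rise in T2 heterogeneity appears in the
features; per-map min–max scaling (available as `range_mode = "roi_minmax"`)
would partially normalize that signal away and exists for sensitivity
analyses. A constant map under min–max scaling collapses to a single level
by convention.

Co-occurrence matrices are accumulated at a single-pixel offset in four
orientations (0°, 45°, 90°, 135°), symmetrically (each pair counted in both
directions), counting only pairs whose two pixels are both inside the ROI
and quantized — no padding, so no fabricated texture at ROI edges. From the
normalized matrix $p(i,j)$ over 0-based levels:

- contrast $\sum p(i,j)(i-j)^2$
- homogeneity $\sum p(i,j)/(1+|i-j|)$
- energy (angular second moment) $\sum p(i,j)^2$
- variance $\sum p(i,j)(i-\mu)^2$, $\mu = \sum i\, p(i,j)$

Feature *values* are averaged over orientations (not the matrices): averaging
matrices first would mix orientation-specific structure before the nonlinear
feature maps and is the less common reading of orientation averaging.
Variance is reported in quantized-level units, with an optional ms² version
via the bin centres; absolute texture magnitudes therefore depend on L, the
range, and the SNR, and only *within-pipeline* comparisons (across groups
and time points) are meaningful. Energy is the angular second moment itself,
not its square root.

## Relative changes and the statistical battery

Relative change is $\Delta_x = ((T2_{t_x}/T2_{t_0}) - 1)\times 100\,\%$,
computed per sample against that sample's own baseline; group summaries are
means of per-sample changes (mean-of-ratios), never the ratio of group
means — the two differ and the per-sample form is what a paired design
measures. The battery is:

- **Friedman + Dunn** within each group across the four time points
  (rank-based, no normality assumption; samples are blocks; mid-ranks for
  ties). Dunn's z statistics use the rank-sum standard error
  $\sqrt{k(k+1)/6n}$; p-values are reported unadjusted by default with
  Holm/Bonferroni available, since no single adjustment convention dominates
  for this design.
- **Kruskal–Wallis** between groups at each time point (tie-corrected H,
  chi-square approximation). Fully tied data yield H = 0 by convention
  (the tie-corrected statistic is otherwise 0/0).
- **One-way ANOVA + Tukey HSD** on relative changes and on
  histology-change-style score tables. Using a parametric test here while
  using rank tests elsewhere is an inconsistency of the original analysis
  design that this package intentionally preserves rather than repairs.
  All-degenerate inputs (zero within-group variance everywhere) are flagged
  as undefined rather than reported as a numeric F.

Significance is declared at p ≤ 0.01 (inclusive), a deliberately strict
level for an exploratory, many-comparison setting; no additional
multiple-testing control is applied across the result grid.

## The phantom: what it emulates, and what it does not

`generate_cohort()` synthesizes the study conditions directly:

- **Geometry.** A ~15 mm wide, ~2.5 mm thick cartilage cross-section at
  0.23 mm/pixel (≈ 65 × 11 pixels of tissue), single mid-sagittal slice,
  with ±1 px surface undulation so the layer split is exercised on
  non-rectangular masks.
- **Baseline stratification.** T2 interpolates linearly with depth from a
  superficial to a deep baseline; per-sample baselines are drawn from
  group-specific normals (superficial 37.0 ± 6.4 / 38.2 ± 4.3 / 42.9 ± 5.8 ms
  and deep 29.4 ± 5.1 / 26.1 ± 2.8 / 27.7 ± 6.0 ms for CONT/LIMP/HIMP),
  truncated so superficial exceeds deep.
- **Lesions.** CONT: multiplicative drift (0, 3.3, 6.6, 5.4 % at t0..t3),
  matching the observed control trajectory of the design this emulates.
  LIMP: an additive full-width Gaussian band in depth (SD 0.15 of thickness)
  centred mid-depth — the transitional-zone band-like hyperintensity — with
  amplitudes 0/8/20/23 ms. HIMP: an additive 2D Gaussian centred at the
  impaction site (lateral SD growing 3.0 → 4.5 → 6.0 mm, amplitude
  0/13/21/40 ms) — the diffuse, widespread, growing hyperintensity. The
  amplitudes were calibrated once so the cohort's mean relative changes
  land near the reference trajectories (≈ +5 % control, ≈ +27 % low impact,
  ≈ +60 % high impact at t3) and then frozen.
- **Heterogeneity.** Each sample draws a lognormal lesion-severity factor
  (log-SD 0.3, constant over time) and a multiplicative response jitter at
  each follow-up (SD 0.05, anchored to the observed spread of control
  relative changes, 3–7 %). Without these, all samples would move in
  lockstep and within-group spread would be implausibly small.
- **Noise.** Rician by default: each value is replaced by the magnitude of a
  complex Gaussian perturbation with per-channel SD $S_0/\mathrm{SNR}$,
  SNR = 50. No published noise level exists for this design, so 50 was
  chosen to give fitted-map pixel scatter in the range implied by the
  reported ROI standard deviations; Gaussian and noiseless modes exist for
  testing linearized fits and exactness checks.

What the phantom does **not** model: proteoglycan-loss biophysics, collagen
fibre orientation and magic-angle effects, B1/stimulated-echo physics (the
echo-2–7 convention is inherited, not re-derived), partial-volume mixing at
edges, 3D volumes, or scanner drift. Consequently, passing tests demonstrate
that the *pipeline* is correct and directionally sensitive under controlled
conditions — not that real impacted cartilage will show effects of these
exact magnitudes.

## Determinism and problem sizes

Every stochastic step flows from explicit integer seeds; a cohort is
bit-reproducible from `rng_seed`. The default test and acceptance runs use
the study-sized cohort (7/14/14 samples × 4 time points, ≈ 700 tissue
pixels per sample), 10 000 pixel replicates for the Monte-Carlo T2 recovery
check, 100 random images for the GLCM oracle, and 500 single-time-point
null cohorts for the type-I-error calibration of the between-group test —
sizes chosen to make Monte-Carlo noise small relative to the tested margins
while keeping a full run in the minutes range on one core.

## Known limitations

- The log-linear fitter is biased at low SNR on magnitude data; use the
  nonlinear fitter (or raise SNR) where that matters.
- Texture magnitudes are not comparable across different quantization
  settings or noise levels; treat them as within-study quantities.
- The Kruskal–Wallis chi-square approximation is slightly conservative at
  the study's group sizes (the shipped 500-cohort calibration lands around
  0.006 at nominal 0.01, with seed-to-seed spread of roughly 0.004–0.016),
  which is the cost of the standard approximation rather than an
  implementation artifact.
- The layer split assumes a roughly horizontal surface; strongly tilted or
  curved samples would need surface-normal chords, which are out of scope.
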