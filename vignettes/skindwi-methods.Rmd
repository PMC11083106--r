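---
title: "Methods: quantitative DWI of breast-skin pathologies with skindwi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative DWI of breast-skin pathologies with skindwi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skindwi)
```

## The problem

Several pathologies affect the skin of the breast — Paget's disease of the
nipple (PD), inflammatory breast cancer (IBC), secondary skin involvement
of breast cancer (SIBC), and benign skin inflammation (BSI) — and their
clinical pathways differ sharply while their appearance on conventional
imaging can overlap. Diffusion-weighted MRI (DWI) offers a quantitative
handle: the apparent diffusion coefficient (ADC) is lower in densely
cellular (typically malignant) tissue. skindwi implements the full
quantitative chain for this setting — signal model, ADC estimation,
noise-floor quality control, and group-level statistics — together with a
seeded digital-phantom generator, so every step can be validated against
known ground truth.

## Signal model and ADC estimation

Voxel signal is modelled as mono-exponential decay over the
diffusion-weighting factor $b$:

$$ S(b) = S_0 \, e^{-b \, D(\mathbf{x})}, $$

with $D$ in mm$^2$/s and $b$ in s/mm$^2$. Two b-values are used: the low
one at 50 s/mm$^2$ (not 0, to suppress perfusion effects) and the high one
at 750 or 800 s/mm$^2$; `select_bvalue_pair()` encodes this rule (smallest
available; high value in [700, 900], preferring exactly 800, then 750).
The two-point ADC is

$$ \mathrm{ADC} = \frac{\ln(\bar S_{b_2} / \bar S_{b_1})}{b_1 - b_2}, $$

computed two ways: on the VOI-mean signals (`adc_from_mean_signal()`,
"ADC of mean signal"), and voxel-wise (`adc_map()`) followed by
first-order statistics of the map over the VOI — mean, median, minimum,
maximum (`first_order_stats()`). Without noise and on a homogeneous VOI
the two routes coincide (log of a constant mean equals mean of constant
logs); under noise they differ, and no equality is asserted there. Even
with more than two b-values acquired, only the selected pair enters the
estimate; multi-b least-squares fitting is deliberately out of scope.

Numerical policies, chosen where the procedure was genuinely open:

* **Nonpositive voxel signals** make the log undefined. Such voxels are
  *excluded* from map statistics (stored as `NA`, counts reported) rather
  than clamped, so summary statistics remain interpretable.
* **Negative ADCs** (high-b mean above low-b mean, possible in
  noise-dominated VOIs) are *retained and flagged*, never floored at zero
  — otherwise noise-bias studies would be distorted.
* **Median of an even count** is the midpoint average.

## Noise floor, SNR and quality control

Magnitude MRI noise is Rician: each voxel is
$\sqrt{(s + n_1)^2 + n_2^2}$ with $n_1, n_2 \sim N(0, \sigma)$. In a
signal-free background region the signal is Rayleigh with mean
$\sigma\sqrt{\pi/2}$, so the noise floor is estimated from a 2D background
ROI as

$$ \sigma = \sqrt{2/\pi}\; \bar S_{\text{noise}}. $$

(This is the standard single-channel estimator; for multi-channel
reconstructions it is only an approximation, and non-central-chi models
are a non-goal.) Tissue signal is corrected for the floor by

$$ S_{\text{corrected}} = \sqrt{S^2 - \sigma^2}, $$

clipped to 0 with an underflow flag when $S \le \sigma$, and
$\mathrm{SNR} = S_{\text{corrected}} / \sigma$ (`compute_snr()`; a switch
allows the raw signal in the numerator, since published workflows are
often ambiguous on this point — the corrected signal is the default
because the correction exists precisely to feed the SNR estimate).

The inclusion rule (`snr_qc_filter()`): pathology cases whose **high-b**
SNR falls *strictly below 2* are excluded (the high-b image is the
limiting one); a case exactly at the cutoff is retained. Healthy-skin
cases are exempt from the cutoff — their skin signal at high b is
regularly near the noise floor — but are flagged `"biased"`, because the
Rician floor inflates the high-b mean signal and therefore biases their
measured ADC *downward*. The package reproduces this mechanism in
simulation rather than hiding it.

## The phantom generator: what it emulates, and what not

`make_skin_phantom()` builds a cylindrical "body" of breast tissue on a
32×32×12 grid (defaults; voxels 1.5×1.5×3 mm, matching clinical DWI
resolution), whose outer two-voxel shell is a skin rim, with a spherical
lesion seated on the rim and a signal-free corner hosting an 8×8
single-slice noise ROI. Noise-free signal follows the mono-exponential
model; Rician noise is applied at a controlled $\sigma$. Identical
`(spec, seed)` reproduce voxel data bit-for-bit.

Default diffusivities (mm²/s ×10⁻³): background breast tissue 1.85 (the
conventional normal-tissue range is 1.7–2.0), skin rim 1.2 (a
dermis-like literature value), lesion 1.5; $S_0 = 1000$ arbitrary units.

`simulate_cohort()` layers the study population on top: per-group
truncated-normal laws of the *true* VOI diffusivity
(`default_group_distributions()`), group sizes (PD 3, IBC 5, BSI 11,
SIBC 11, H 58 — 88 cases), group-typical VOI voxel counts (35 / 258 /
197 / 46 / 29), and group-typical high-b SNR targets (14 / 59 / 56 / 37 /
2.04). The noise sigma of each case is set so the noise-free VOI signal
at the high b-value divided by sigma equals the SNR target. Healthy-skin
VOIs are a single axial slice of the rim (~29 voxels, delineated as a
contiguous arc); pathology VOIs are 3D spheres spanning at least three
slices.

Two distribution choices deserve emphasis:

* **Dispersion.** The published group tables print "mean ± value" with a
  caption claiming SD, but with n = 11 and a printed range of 1.04–2.30
  an SD of 0.11 is arithmetically impossible — the printed value must be
  the SEM. The generator therefore uses SD = SEM·√n, truncated to the
  printed ranges (which also forbids non-physical diffusivities). A side
  effect worth knowing: where the printed range is strongly asymmetric
  about the mean (BSI, IBC), the truncated law's mean sits ~4% below the
  printed group mean; cohort means recovered by the pipeline reproduce
  the truncated law, not the printed headline number, to that accuracy.
* **Healthy skin.** The true healthy-skin diffusivity is unknown — the
  published value (0.48–0.49 ×10⁻³) is acknowledged to be noise-biased.
  The generator keeps it a free parameter; the default H distribution
  uses the published (biased) values with the published low SNR target,
  so the default cohort reproduces the *measured* healthy-skin behaviour,
  including the bias, rather than asserting an unknown truth.

What the phantom does **not** emulate: breast anatomy, fat suppression
and EPI distortion artifacts, multi-channel (non-central chi) noise,
partial-volume mixtures at the skin boundary, scanner/field-strength
variability. A green cohort-level test therefore establishes that the
*estimation chain* is correct under the stated generative model — not
that the model captures every property of clinical data.

## Group statistics

Features (per included case): ADC of mean signal plus mean/median/min/max
of the voxel-wise map, reported in 10⁻³ mm²/s. The analysis follows the
conventional small-cohort path:

* `ks_normality()` — one-sample Kolmogorov–Smirnov screen against a
  normal with sample-estimated mean/SD. Estimating the parameters from
  the same sample makes the naive screen *conservative* (the Lilliefors
  issue); it is documented as approximate and used only to justify
  nonparametric testing.
* `ranksum()` — two-sided Wilcoxon rank-sum; exact null when both
  groups have ≤ 10 observations without ties, normal approximation with
  tie and continuity correction otherwise.
* `pairwise_group_tests()` — all unordered group pairs × features at
  α = 0.05. Groups smaller than `min_group_n = 5` (PD, with n = 3) are
  reported descriptively, never tested. No multiplicity correction by
  default — mirroring common practice in feasibility cohorts — with an
  optional `p_adjust` flag for Holm/Bonferroni.
* `roc_analysis()` — empirical ROC over all distinct thresholds,
  trapezoidal AUC with midrank tie handling, which makes AUC exactly
  equal Mann–Whitney U/(n₁n₂). Orientation `"lower"` (default) treats
  lower ADC as the positive, more malignant class. The operating point
  maximizes the Youden index; sensitivity/specificity are reported at
  that point, with the full curve available, since published
  operating-point rules are rarely stated.
* `summarize_groups()` — per group × feature: mean, SD, SEM and min–max
  range, all three dispersion measures printed to avoid the ambiguity
  that motivated the SEM reconstruction above.

## Pipeline and reproducibility

`run_simulate()` writes a cohort to disk (float32 NIfTI stacks, FSL
`.bval`, JSON sidecars, uint8 masks, manifest and ground-truth CSV);
`run_analyze()` ingests a manifest, applies the SNR QC, quantifies ADC,
and writes the feature table, QC table, group summary, normality screen,
pairwise tests, ROC summary and a JSON run report with the config echo
and a machine-readable exclusion log. Both are deterministic under the
recorded seed. A thin CLI (`skindwi_cli()`, wrapper in `inst/cli/`)
exposes `simulate` and `analyze` with exit codes 0/1/2
(ok/usage/data error).

Because no NIfTI reader exists in the supporting R stack available here,
the package carries a minimal NIfTI-1 single-file reader/writer covering
the subset it emits (3D/4D; uint8/int16/int32/float32/float64; gzip;
scl_slope/inter on read); it is cross-validated against an independent
Python reader in the test suite. Orientation handling is minimal (a
diagonal sform from the voxel spacing); no reorientation is performed.

## Known limitations

* The mono-exponential model ignores perfusion (IVIM), kurtosis and
  multi-compartment effects; these are out of scope by design.
* The phantom's piecewise-constant geometry cannot probe partial-volume
  behaviour at the skin boundary, the very effect that motivates keeping
  a one-voxel delineation rim (`erode_mask()` is provided for that
  workflow but defaults to no erosion on phantom masks).
* Cohort-level expectations inherit the ~4% truncation shift for groups
  with asymmetric published ranges (see above); this is a property of
  the stated generative model, not an estimation error.
* The KS screen's p-values are approximate (conservative) by
  construction; treat them as a screen, not a test.
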