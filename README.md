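# skindwi

Quantitative diffusion-weighted MRI (DWI) analysis of breast-skin
pathologies, with a seeded digital-phantom generator for validation.

Skin-affecting breast pathologies — Paget's disease (PD), inflammatory
breast cancer (IBC), skin-involved breast cancer (SIBC) and benign skin
inflammation (BSI) — can look alike on conventional imaging while
demanding very different clinical pathways. DWI offers a quantitative
discriminator: the apparent diffusion coefficient (ADC) is reduced in
densely cellular, typically malignant tissue. This package implements the
full measurement chain for that setting, aimed at imaging scientists who
want every step testable against ground truth:

* **Signal model** — mono-exponential decay `S(b) = S0 · exp(−b·D)`;
  two-point ADC `ADC = ln(S̄_b2 / S̄_b1) / (b1 − b2)` with the low b at
  50 s/mm² and the high b at 750/800 s/mm², computed both from the
  VOI-mean signal and voxel-wise with first-order statistics
  (mean/median/min/max) of the ADC map.
* **Noise machinery** — Rician noise simulation; single-channel noise
  floor `σ = √(2/π) · S̄_noise` from a background ROI; Rician correction
  `S_corr = √(S² − σ²)`; `SNR = S_corr/σ` with an inclusion cutoff of 2
  at the high b-value (healthy skin exempt but flagged as biased).
* **Phantoms** — cylindrical breast "body" with a skin rim, rim-seated
  spherical lesions, signal-free noise corner; cohort simulation from
  per-group truncated-normal diffusivity laws with the study's group
  sizes (PD 3, IBC 5, BSI 11, SIBC 11, healthy 58), VOI sizes and SNR
  levels; bit-for-bit reproducible under a seed.
* **Statistics** — KS normality screen, exact/approximate Wilcoxon
  rank-sum tests, descriptive-only handling of groups with n < 5,
  empirical ROC with trapezoidal AUC (= Mann–Whitney U/(n₁n₂)) and
  Youden operating points, group summary tables printing SD, SEM and
  range.
* **I/O and pipeline** — NIfTI-1 volumes (minimal built-in reader/writer,
  cross-validated against nibabel), FSL `.bval`, JSON sidecars, CSV
  manifests/results; `run_simulate()`/`run_analyze()` plus a CLI wrapper
  (`inst/cli/skindwi`) with `simulate` and `analyze` subcommands.

See `vignettes/skindwi-methods.Rmd` for the model, parameter choices,
generator assumptions and limitations.

## Worked example

```r
library(skindwi)

co  <- simulate_cohort(seed = 42)      # 88-case default cohort
res <- analyze_cohort(co$phantoms)     # SNR QC -> ADC -> statistics
res
#> <skin_analysis> 88 cases retained, 0 excluded by SNR QC
#>   AUC (adc_mean_signal): SIBC vs BSI = 0.851, SIBC vs IBC = 0.855, IBC vs BSI = 0.455

subset(res$group_summary, feature == "adc_mean_signal")
#>  group         feature  n  mean    sd    sem     min   max
#>    BSI adc_mean_signal 11 1.724 0.194 0.0585  1.5156 2.158
#>      H adc_mean_signal 58 0.448 0.173 0.0228 -0.0172 0.927
#>    IBC adc_mean_signal  5 1.810 0.290 0.1299  1.5117 2.176
#>     PD adc_mean_signal  3 0.974 0.201 0.1162  0.8178 1.201
#>   SIBC adc_mean_signal 11 1.363 0.275 0.0831  0.9338 1.680
```

ADC values are in 10⁻³ mm²/s. The malignant, skin-involved group (SIBC)
sits well below the inflammatory groups; healthy skin is lowest of all —
not because its true diffusivity is that low, but because its high-b
signal is near the noise floor and the Rician floor biases the measured
ADC downward (those cases are exempt from QC and flagged `"biased"`; one
healthy case even shows a retained, flagged negative ADC). The pairwise
tests reproduce the expected pattern — SIBC differs from both BSI
(p = 0.006) and IBC (p = 0.031), while BSI and IBC are indistinguishable
(p = 0.82):

```r
res$roc$SIBC_vs_BSI
#> <roc_result> SIBC (n=11) vs BSI (n=11) on adc_mean_signal
#>   AUC = 0.8512; Youden threshold 1.487 (sens 63.64%, spec 100%)
```

Single-case quantification and QC:

```r
ph <- co$phantoms[[20]]                       # an SIBC case, true D = 1.375
adc_quantify(ph$study, ph$voi)
#> <adc_result> b = (50,800) s/mm^2
#>   ADC of mean signal: 1.371 1e-3 mm^2/s
#>   map summary (1e-3 mm^2/s): mean 1.372, median 1.372, min 1.283, max 1.463
#>   voxels used 51, excluded 0
compute_snr(ph$study, ph$voi, ph$noise_roi)
#> <snr_report> SIBC_001: SNR(b=50) = 96, SNR(b=800) = 37.89, sigma = 8.802
#>   PASS (cutoff 2)
```

From the shell:

```sh
Rscript inst/cli/skindwi simulate --out cohort_dir --seed 42
Rscript inst/cli/skindwi analyze --manifest cohort_dir/manifest.csv --out report_dir
```

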