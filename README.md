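# mpmri

Multiparametric MR quantification and group comparison for a rat
high-grade glioma model.

Preclinical studies of C6-glioma-bearing rats detect sexual dimorphism in
tumour biology through quantitative MRI: magnetization transfer ratio
(MTR) maps track the macromolecular microenvironment, diffusion-tensor
maps of mean diffusivity (MD) and fractional anisotropy (FA) track
cellularity and microstructural integrity, and dynamic-susceptibility-
contrast (DSC) bolus tracking yields relative cerebral blood volume
(CBV), flow (CBF) and mean transit time (MTT). This package implements
that whole pipeline — pixel-wise map computation, ROI summarization,
the relative-change statistic and Welch group tests, plus the circadian
respiratory-exchange-ratio (RER) analysis — and drives it with a digital
phantom whose ground truth is the study's four experimental groups
(male/female × tumour/sham, n = 8), so every stage is testable without
animal data.

## The quantities

- **MTR**, from an MT-off/MT-on pair:
  `%MTR = (S0 − S_MT) / S0 × 100`.
- **Diffusion tensor**, per voxel by ordinary least squares on the
  log-signals of the Stejskal–Tanner model `S = S0 exp(−b gᵀDg)`
  (b ∈ {0, 300, 1400} s/mm², 7 directions). From the eigenvalues
  λ1 ≥ λ2 ≥ λ3:
  `MD = (λ1 + λ2 + λ3)/3`,
  `FA = √(3/2) · √Σ(λi − MD)² / √Σλi²`.
- **DSC perfusion**, per voxel: signal → concentration
  `C(t) = −ln(S/S_base)/TE`, gamma-variate fit
  `C(t) = K (t−t0)^α e^{−(t−t0)/β}`, then
  `CBV = K β^{α+1} Γ(α+1)`, `MTT = β(α+1)` and `CBF = CBV/MTT`
  (central-volume relation; no arterial input function is available, so
  all maps are normalized to a contralateral reference region).
- **Group statistics**: per-ROI
  `%Δ = (Data_glioma − Data_sham)/Data_sham × 100` and unpaired
  two-tailed Welch t tests (Welch–Satterthwaite df), from summary
  statistics (mean ± SEM, n) or raw per-subject values.

## Worked example

```r
library(mpmri)

# percent change and Welch test straight from the group-effect tables
eff    <- default_group_effects()
glioma <- group_summary(mean = effect_value(eff, "female/tumour", "core", "md"),
                        sem  = effect_value(eff, "female/tumour", "core", "md", "sem"),
                        n = 8)
sham   <- group_summary(mean = effect_value(eff, "female/sham", "core", "md"),
                        sem  = effect_value(eff, "female/sham", "core", "md", "sem"),
                        n = 8)
pc <- percent_change(glioma, sham)
cat(sprintf("Core MD change, females: %+.2f%% (SEM %.2f)\n", pc$pct, pc$sem))
#> Core MD change, females: +13.36% (SEM 0.77)

welch_test(group_summary(mean = 16.77, sem = 0.34, n = 8, label = "male"),
           group_summary(mean = 13.37, sem = 0.22, n = 8, label = "female"))
#> <welch_result> t = 8.396, df = 11.99, p = 2.3e-06 ****

# one phantom subject: simulate a noisy MT pair and recover the core MTR
truth <- make_truth(group = "male/tumour")
mtr   <- compute_mtr(simulate_mt_pair(truth, snr = 40, seed = 7),
                     truth$masks_map$brain)
s <- roi_summary(mtr, truth$masks_map$core)
cat(sprintf("Core MTR at SNR 40: %.2f%% over %d voxels (truth 14.29%%)\n",
            s$mean, s$n))
#> Core MTR at SNR 40: 14.01% over 438 voxels (truth 14.29%)
```

The first number is the female core-MD increase computed from the
absolute group means; the Welch line shows the male-vs-female comparison
of the core-MD percent changes is significant far below 0.001; the last
line shows the MTR stage recovering its ground truth from a noisy
simulated acquisition (a small downward shift relative to truth is the
expected Rician ratio bias at SNR 40).

## Analysis workflow

The numbered scripts under `analysis/` run the study-level analyses and
write their tables under `results/`:

1. `01_printed_table_stats.R` — percent changes and Welch tests computed
   from the absolute group tables.
2. `02_noiseless_pipeline.R` — zero-noise cohort through the full
   simulate → map → summarize pipeline; verifies the report reproduces
   the generating table to machine precision.
3. `03_noisy_cohort.R` — n = 8 cohort with between-subject variability,
   Rician image noise (SNR 40) and DSC signal noise.
4. `04_rer_circadian.R` — indirect-calorimetry cohort (n = 5, 60 h) and
   the day/night RER group comparison.

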