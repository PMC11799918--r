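# lvdose

How far can the radiation dose of a cardiac CT acquisition be reduced
before left-ventricular (LV) functional metrics derived from automatic
segmentation stop being trustworthy? `lvdose` implements an
*objective-observer* pipeline for that study-design question, aimed at
medical-imaging researchers who want a fully synthetic, fully reproducible
test bed for dose-reduction experiments.

The pipeline:

1. **Phantoms** — parametric truncated-ellipsoid LV phantoms (ED and ES
   phases) with closed-form ground truth for all four functional metrics:
   ejection fraction `EF = 100·(EDV−ESV)/EDV`, global longitudinal strain
   `GLS = 100·(L_ES−L_ED)/L_ED`, circumferential strain
   `CS = 100·(P_ES−P_ED)/P_ED` per short-axis level, and 16-spoke wall
   thickening `WT_k = 100·(t_ES,k−t_ED,k)/t_ED,k`.
2. **CT simulation** — parallel-beam projection, a projection-domain noise
   model inserting Poisson quantum noise and Gaussian electronic noise
   (`N = Poisson(I₀e^(−p)) + N(0,σ_e²)`, `I₀ ∝ mA`), and Hann-apodized
   filtered back-projection. Low-dose scans at 100/50/25/10 mA are
   *emulated* from the ~500 mA standard-dose sinogram by incremental noise
   injection, so every dose level shares the same anatomy and
   standard-dose noise realization (the paired design).
3. **Observers** — a deterministic HU-threshold observer, and a residual
   3D U-Net (two residual blocks at each of four levels, deep
   supervision, generalized Dice loss, Adam) trained in two regimes:
   *Standard* (standard-dose data only) and *Noise-Robust* (standard +
   emulated low-dose data).
4. **Views & metrics** — long-axis estimation, reformatting into
   two-chamber, parasternal long-axis and basal/middle/apical short-axis
   planes, and sub-voxel measurement of EF, GLS, CS and WT.
5. **Study** — every low-dose result is compared with the same case's
   standard-dose result (signed metric deltas, Dice); per-dose summaries
   (mean ± SD of Δ and |Δ|, P90 of |Δ|) feed an explicit threshold rule:
   the lowest mA whose P90(|Δ|) stays ≤ 2.5 pp for EF, GLS and CS at that
   and every higher dose.

See `vignettes/dose-ladder-methods.Rmd` for the models, parameter
defaults, numerical choices and limitations.

## Worked example

Generate a phantom with a 60% target EF, scan it, emulate the dose
ladder, segment with the rule-based observer, and measure:

```r
library(lvdose)

spec <- build_phantom_spec(target_ef_pct = 60, seed = 1)
analytic_ground_truth(spec)$ef_pct
#> [1] 60

grid <- grid_def(c(64L, 64L, 64L), 2.25)        # 144 mm field of view
ed <- voxelize_phase(spec, "ED", grid)
es <- voxelize_phase(spec, "ES", grid)

geom <- scan_geometry(128L, 1.25, 120L, quiet = TRUE)
acq <- acquisition_spec(500)                     # ~500 mA standard flux
ladder_ed <- emulate_dose_ladder(ed$image, geom, acq,
                                 c(500, 100, 50, 25, 10), seed = 1)
ladder_es <- emulate_dose_ladder(es$image, geom, acq,
                                 c(500, 100, 50, 25, 10), seed = 2)

obs <- rule_observer()
for (mA in c("500", "25")) {
  seg_ed <- segment_volume(obs, ladder_ed[[mA]])
  seg_es <- segment_volume(obs, ladder_es[[mA]])
  m <- compute_all(seg_ed, seg_es)
  cat(mA, "mA:  EF", round(m$ef_pct, 2), " GLS", round(m$gls_pct, 2),
      " Dice(myo vs truth)", round(dice(seg_ed, ed$labels, 1), 3), "\n")
}
#> 500 mA:  EF 60.31  GLS -20  Dice(myo vs truth) 0.997
#> 25 mA:  EF 60.33  GLS -19.99  Dice(myo vs truth) 0.886
```

EF survives a factor-20 dose reduction almost untouched (the blood pool
is high-contrast), while the myocardium segmentation — and with it the
strain and thickening metrics — degrades first; the study machinery
quantifies exactly where each metric breaks.

The full experiments live in `analysis/` as numbered scripts
(`01_phantom_cohort.R` … `05_dose_threshold.R`): cohort generation and
metric parameter recovery, Monte-Carlo validation of the noise model, the
ten-phantom rule-observer dose ladder with its exported report and
detected threshold, and the Standard-vs-Noise-Robust network-observer
comparison at 25 mA. Each writes small CSV tables under `results/`.

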