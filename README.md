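# smritrack

Longitudinal analysis of whole-brain spectroscopic MRI (sMRI) for brain
tumor patients — built for the setting of pediatric high-grade glioma,
where tumors are diffusely infiltrating, frequently non-enhancing on
T1w-CE, and where structural MRI alone struggles to separate treatment
effect from regrowth after radiotherapy.

The package implements, as tested reusable functions plus a numbered
analysis workflow:

- **Cho/NAA ≥ 2X segmentation** — the metabolic biomarker region
  `{v : R(v) ≥ 2 · R̄_NAWM}`, where `R(v)` is the voxelwise
  choline-to-N-acetyl-aspartate ratio and `R̄_NAWM` is its mean over
  contralateral normal-appearing white matter (manual mask or mid-sagittal
  mirror fallback), with an inclusive threshold and a connected-component
  size filter.
- **Coverage-matched difference maps** — signed voxel-level change in Cho
  and Cho/NAA between scans, restricted to voxels with valid
  spectroscopic data at *both* timepoints.
- **Volume trajectories** — per-scan volumes (cc) and percent change from
  the previous scan, for the metabolic (2X) and structural (T2-FLAIR)
  mask families.
- **Overlap battery** — Dice similarity coefficient
  `DSC = 2|A∩B| / (|A|+|B|)` and the full (maximum) Hausdorff distance in
  mm between boundary voxels, comparing the pre-RT mask to each post-RT
  mask.
- **Progression rule** — per interval, the medians of the voxelwise
  ΔCho and Δ(Cho/NAA) over the lesion ROI: both up ⇒ *true progression*;
  ratio up with Cho paradoxically down ⇒ *pseudoprogression*; otherwise
  stable/response.
- **Cohort statistics** — OLS regression of FLAIR on 2X volumes with a
  95% mean-line band; Shapiro–Wilk/Levene-gated choice between the paired
  t-test and the exact Wilcoxon signed-rank test; paired-sample Cohen's
  d; Holm–Bonferroni control over the two primary hypotheses.
- **Synthetic phantom cohorts** — seeded longitudinal head phantoms with
  elevated Cho / depressed NAA lesions, additive noise, partial
  spectroscopic coverage, and four evolution modes (stable, response,
  true progression, pseudoprogression) with known ground truth, so every
  stage is testable without patient data.

## Worked example

Simulate one pseudoprogressing patient, segment every timepoint, and run
the overlap battery and the progression rule:

```r
library(smritrack)
cfg <- phantom_config(grid_shape = c(48, 48, 40), voxel_spacing_mm = c(4, 4, 4),
                      brain_semi_axes_mm = c(80, 85, 70),
                      tumor_center_mm = c(-35, 10, 5), tumor_radius_mm = 18,
                      noise_sd = 0.1, seed = 7)
series <- make_series(cfg, "PSEUDOPROGRESSION", timepoints_months = c(-1, 1, 4))
series$timepoints <- lapply(series$timepoints, segment_timepoint)

series$timepoints[[1]]$nawm_ref
#> nawm_reference: mean ratio 1.0167 over 392 voxels (MANUAL_MASK)
series$timepoints[[1]]$masks$CHO_NAA_2X
#> binary_mask <CHO_NAA_2X> on 48x48x40@4x4x4; 391 voxels (25.024 cc)

overlap_battery(series, "CHO_NAA_2X")[, c("post_months", "dsc", "hd_mm")]
#>   post_months       dsc    hd_mm
#> 1           1 0.9987229 5.656854
#> 2           4 0.9987229 5.656854

series_progression(series)$calls[, c("later_months", "delta_cho_median",
                                     "delta_ratio_median", "label")]
#>   later_months delta_cho_median delta_ratio_median             label
#> 1            1       -0.1375642          0.3836233 PSEUDOPROGRESSION
#> 2            4       -0.1262756          0.5356798 PSEUDOPROGRESSION
```

Reading the output: the NAWM reference ratio is ≈1 (by construction of
the phantom), so the 2X mask recovers the planted lesion (25 cc, Dice
≈0.999 against later scans of this spatially stable lesion). The interval
medians show Cho falling (≈−0.14 in NAWM-Cho units) while Cho/NAA rises
(≈+0.4), the metabolic signature of pseudoprogression, and the rule
labels both intervals accordingly.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on the default
6-patient phantom cohort and write tables under `results/` (volumes under
`scratch/`):

```sh
Rscript analysis/01_simulate_cohort.R    # phantom cohort + manifest (NIfTI/YAML)
Rscript analysis/02_segment_and_track.R  # 2X segmentation, volume trajectories
Rscript analysis/03_overlap_battery.R    # pre- vs post-RT DSC / Hausdorff
Rscript analysis/04_metabolic_change.R   # difference maps, progression calls
Rscript analysis/05_cohort_statistics.R  # regression + gated paired tests
```

`run_study()` performs the same end-to-end computation in one call on an
in-memory cohort.

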