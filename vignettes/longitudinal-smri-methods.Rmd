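---
title: "Methods: longitudinal spectroscopic-MRI tracking of brain tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal spectroscopic-MRI tracking of brain tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smritrack)
```

## The problem and the model

Whole-brain spectroscopic MRI measures per-voxel metabolite levels.
Metabolically active glioma shows elevated choline (Cho, membrane
turnover of proliferating glial cells) and depressed N-acetyl aspartate
(NAA, neuronal integrity). The working biomarker is the ratio map
$R(v) = \mathrm{Cho}(v)/\mathrm{NAA}(v)$ referenced to contralateral
normal-appearing white matter (NAWM): the **Cho/NAA ≥ 2X region** is

$$ S_{2X} = \{\, v \in \mathcal{C} : R(v) \ge 2\,\bar R_{\mathrm{NAWM}} \,\}, $$

where $\mathcal{C}$ is the spectroscopic coverage lattice and
$\bar R_{\mathrm{NAWM}}$ the arithmetic mean of $R$ over the NAWM
region. The threshold comparison is inclusive, matching the biomarker's
name. Longitudinally the package tracks (i) volumes and percent change
of $S_{2X}$ and of the T2-FLAIR hyperintensity mask, (ii) signed
voxelwise change of Cho and $R$ between scans on coverage-matched
lattices, (iii) spatial agreement between the pre-radiotherapy mask and
every post-radiotherapy mask via the Dice coefficient and the Hausdorff
distance, and (iv) an interval classification separating true
progression from pseudoprogression.

All computation assumes inter-timepoint registration has already been
performed upstream; the package harmonizes grids
(`resample_to_grid()`) but never estimates spatial transforms.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `factor` (threshold multiple) | 2.0 | — | the biomarker's definition |
| `min_component_cc` | 0.1 | cc | removes speckle components; a deterministic stand-in for expert contour editing of clinical segmentations |
| NAA floor $\varepsilon$ | $10^{-6}\times$ median NAA | conc. | voxels with near-zero NAA are *excluded* from ratio coverage rather than clipped, so no fabricated extreme ratios enter the mask |
| NAWM minimum size | 50 | voxels | below this the reference mean is too noisy to anchor a threshold; the call fails loudly |
| `dead_band_ratio` | 0.1 | ratio units | median interval changes smaller than this are treated as noise |
| `dead_band_cho` | 0.05 | conc. units | 5% of the nominal NAWM Cho level |
| Hausdorff percentile | 100 | — | the classical maximum-boundary-mismatch definition; HD95 available for robustness studies only |
| `pairing` | consecutive | — | difference maps between adjacent scans; a baseline-anchored mode mirrors the overlap battery's convention |

The NAWM reference uses the arithmetic mean; a median option exists for
sensitivity analyses but is never the default. When no manual NAWM mask
is supplied, `mirror_nawm()` reflects the lesion across the mid-sagittal
grid plane, intersects with brain and with the lesion's complement, and
fails (asking for a manual mask) when the mirrored region vanishes —
how the reference region is best delineated is genuinely open, so both
routes are exposed and the provenance is recorded in the reference
object.

## Overlap metrics

Dice is $2|A\cap B|/(|A|+|B|)$. Two empty masks are defined as Dice 1
with a warning flag — a complete responder whose biomarker region
vanished at both timepoints agrees perfectly, and a cohort battery must
not crash on it; one empty mask gives 0. The Hausdorff distance is
computed between **boundary voxels** (mask voxels with at least one
face-adjacent non-mask or out-of-grid neighbour — the standard surface
voxel definition, deterministic and oracle-checkable), as the larger of
the two directed maximum–minimum Euclidean distances between boundary
voxel centers, reported in mm. Pairs with an empty mask are recorded as
undefined with a distinct error class and flagged in the battery rather
than silently dropped. Both metrics are validated against exhaustive
brute-force oracles on random small grids.

## Interval classification

For a scan pair, Cho and ratio maps are coverage-matched ("voxels
lacking data are excluded from both timepoints"), differenced (later
minus earlier), and summarized by the **median** voxelwise change over
the ROI — the union of the pair's 2X masks, a deterministic and
symmetric choice (config-overridable; ground-truth masks are the
fallback when both 2X masks are empty, e.g. in complete responders).
The rule is:

* both medians above their dead bands ⇒ `TRUE_PROGRESSION`
  (concurrent Cho and Cho/NAA increase — active proliferation);
* ratio median above its band with the Cho median *below* minus its band
  ⇒ `PSEUDOPROGRESSION` (NAA collapses from treatment effect while Cho
  falls — no tumor-driven membrane turnover);
* anything else ⇒ `STABLE_OR_RESPONSE`.

The median (not the mean) makes the rule robust to the heavy-tailed
voxel noise of ratio images; the dead bands make explicit a call that is
otherwise qualitative. No quantitative change threshold is established
for this decision in the clinical literature, so the dead-band defaults
are engineering choices, exposed in `study_config()`.

## The statistical framework

Cohort level, two primary hypotheses: a modality effect on Dice and on
Hausdorff distance between the 2X and FLAIR families, paired by
(patient, pre/post pair).

* Each group is tested for normality with Shapiro–Wilk (α = 0.05) and
  the pair for variance homogeneity with Levene's test (Brown–Forsythe
  median-centred form, the default of the standard implementations).
* Both gates pass ⇒ two-tailed paired t-test; otherwise the two-tailed
  Wilcoxon signed-rank test.
* The Wilcoxon p-value is exact for up to 25 non-zero differences, from
  the full sign-assignment distribution computed by convolution over
  (doubled) midranks — so ties are handled exactly; zero differences
  are dropped. Larger samples use the normal approximation with
  tie-corrected variance and continuity correction. The exact path is
  pinned against full $2^n$ enumeration in the tests.
* Effect size is the paired-sample Cohen's d, mean over SD of the
  differences, with the conventional 0.2/0.5/0.8 qualitative cuts.
* The two test p-values are controlled with the Holm–Bonferroni
  step-down: the smaller faces α/2 = 0.025, and only if it rejects does
  the larger face α = 0.05.

The volume relationship between families is summarized by OLS of FLAIR
volume on 2X volume, reporting slope, intercept, Pearson r, the
two-tailed non-zero-slope p-value, the residual standard error, and the
95% confidence band of the mean response.

## The phantom: what it emulates and what it does not

`phantom_config()` defines an ellipsoidal brain of NAWM metabolite
levels containing a spherical lesion. The lesion's contrast splits the
planted ratio multiple $m$ symmetrically: Cho is raised by $\sqrt m$ and
NAA lowered by $\sqrt m$, giving elevated Cho, depressed NAA and a
lesion ratio of exactly $m \times$ NAWM in the noiseless limit. Shapes
are analytic and rasterized by voxel-center inclusion, so ground truth
is exact and needs no mesh machinery; coverage erosion (shrunken
ellipsoid) and the FLAIR margin (enlarged sphere, default 4 mm — the
structural abnormality is broader than and correlated with the
metabolic lesion) are likewise analytic. Noise is additive Gaussian per
metabolite, truncated at a small positive floor so ratios stay defined
everywhere in coverage. One config seed drives everything through
per-timepoint substreams (`seed * 1009 + timepoint`), making cohorts
bit-reproducible.

Evolution modes apply geometric per-step multipliers to lesion radius,
Cho and NAA, so a mode extends to any scan schedule (default
{−1, 1, 4, 7, 10} months, mirroring a 1-month-post-RT then every-3-months
follow-up):

| Mode | radius | Cho | NAA | effect per step |
|---|---|---|---|---|
| STABLE | 1.00 | 1.00 | 1.00 | nothing changes |
| RESPONSE | 0.90 | 0.85 | 1.12 | ratio decays toward NAWM (×0.76) |
| TRUE_PROGRESSION | 1.10 | 1.12 | 0.94 | Cho and ratio strictly rise (ratio ×1.19) |
| PSEUDOPROGRESSION | 1.00 | 0.92 | 0.80 | Cho falls while ratio rises (×1.15) |

The NAWM reference region is the lesion mirrored across the
mid-sagittal plane *at the baseline radius* — a fixed tissue region that
does not track lesion evolution, which also guarantees it stays above
the 50-voxel minimum in responders.

The phantom does **not** emulate spectral lineshapes, lipid/water
suppression or k-space acquisition, partial-volume mixing at lesion
boundaries (rasterized voxels are purely lesion or purely background),
registration error, field inhomogeneity, or anatomically realistic
lesion shapes. Passing recovery tests therefore demonstrates the
correctness of the computational pipeline under controlled contrast and
noise — not clinical segmentation or classification accuracy on real
pediatric data, where partial volume and registration error dominate.

## Numerical choices

* Voxel indices are 0-based; physical coordinates come from the affine
  in mm; volumes are reported in cc and distances in mm.
* Coverage is an explicit companion lattice, never a sentinel value.
* Resampling: masks and coverage nearest-neighbour (they stay binary);
  metabolite values trilinear, with a target voxel covered only when
  every contributing source corner is inside the source grid and
  covered, so interpolation never manufactures data from missing voxels.
* Connected components of the 2X mask use 26-connectivity (a diagonal
  touch keeps a component together); boundary extraction uses
  6-connectivity (the surface definition).
* Degenerate inputs fail loudly and specifically: constant samples in
  the normality gates, all-zero Wilcoxon differences, empty masks in
  the Hausdorff, sub-minimum NAWM regions, lesions outside the brain.

## Problem sizes

The default cohort for the end-to-end study is 6 patients on 64³ grids
at 3 mm spacing, five timepoints, completing in well under five minutes
on one CPU. Monte-Carlo validation stages (segmentation recovery over
20 seeds, classification recovery over 200 series per mode at 10%
noise, 2000-repetition null calibration of the gated comparison) run on
a reduced 28×28×20 grid at 4 mm spacing — the statistical properties
under test depend on contrast, noise and voxel counts in the regions of
interest, not on the absolute grid size, and the reduced grid keeps the
full validation battery fast enough to run routinely.

## Known limitations

* Inter-scan Cho intensities are assumed comparable after upstream
  institutional normalization; an NAWM-Cho rescaling is available but
  off by default, since nothing in the pipeline can verify calibration.
* The progression rule is a two-summary decision on medians; it ignores
  spatial pattern within the ROI and will average away focal change in
  a large stable region.
* The mirror-NAWM fallback presumes gross left–right symmetry and an
  off-midline lesion.
* Surgical-cavity enhancement is handled only via a user-supplied
  exclusion mask; there is no automatic cavity detection.
* Cohort-level statistics treat (patient, pair) records as exchangeable
  paired observations; no within-patient correlation structure is
  modeled.
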