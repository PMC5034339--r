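# qpianiso

Scattering anisotropy of tissue from quantitative phase images, with the
full biomarker-validation statistics around it.

## The problem

After radical prostatectomy, identifying which patients will suffer
biochemical recurrence (a defined post-surgical PSA rise) decides who
should receive adjuvant treatment. Beyond clinical nomograms such as
CAPRA-S, the spatial disorganization of the stroma immediately adjoining
cancerous glands carries prognostic signal: in quantitative phase images
(optical path-length delay φ per pixel, radians), the scattering-phase
theorem turns the spatial statistics of φ over a stromal region into the
scattering anisotropy factor

    g = 1 − ⟨|∇φ|²⟩ / (2 k₀² ⟨Δφ²⟩),      k₀ = 2π/λ₀  (λ₀ = 552 nm),

the mean cosine of the single-scattering angle. Fragmented stroma scatters
at wider angles: low g flags patients at risk. Both moments scale together
under φ → cφ, so g is independent of section thickness.

`qpianiso` implements this pipeline for R:

* **Measurement** — phase variance and mean gradient intensity over
  polygonal ROIs, their combination into g, and first-order propagation of
  background phase noise into an uncertainty Δg (validated against Monte
  Carlo).
* **Imaging I/O** — float32 phase TIFFs with JSON sidecars, ImageJ/JSON
  ROI polygons, even-odd rasterization, feather-blended tile mosaics,
  core cropping.
* **Synthetic ground truth** — Gaussian random phase fields whose
  covariance C(r) = σ² exp(−r²/a²) gives the closed form
  g = 1 − 2/(k₀²a²); synthetic tissue cores (gland lumens + annular
  stromal ROIs) tuned to any target g; synthetic patient cohorts with the
  reported class structure (192 patients, 33 recurrent; g of
  0.913 ± 0.028 vs 0.932 ± 0.023); a PSA-series recurrence-labelling
  rule.
* **Statistics** — CAPRA-S scoring, rank-based ROC/AUC with bootstrap or
  DeLong CIs and Youden cutoffs, Kaplan–Meier curves and log-rank tests,
  one-way ANOVA, Gleason- and CAPRA-S-stratified sensitivity/specificity,
  and a harness that reconstructs the published contingency tables from
  their printed percentages.

## Worked example

Tune a texture to g = 0.93, build a six-gland synthetic core, and measure
each annular stromal ROI:

```r
library(qpianiso)

corr_length_for_g(0.93)
#> [1] 0.4695969        # um: the correlation length that yields g = 0.93

core <- generate_core_image(0.93, n_glands = 6, pixel_size = 0.05, seed = 1)
m <- measure_rois(core$image, core$rois)
round(m$g, 4)
#> [1] 0.9301 0.9303 0.9345 0.9275 0.9308 0.9297
```

Each ROI recovers the target within ±0.015 (central-difference
discretization contributes a small upward bias, included in that band).
Now a full synthetic cohort at the reported composition, analyzed at the
published 0.93 cutoff:

```r
co   <- generate_cohort(cohort_spec(seed = 1), gleason_matched = TRUE)
meas <- data.frame(patient_id = co$patients$patient_id, g = co$patients$g_true)
res  <- analyze_study(meas, co$patients, config = run_config(seed = 1, n_boot = 500))

res$anova$p
#> [1] 0.000186         # the two classes differ strongly in g
res$roc$anisotropy$auc
#> [1] 0.667            # one cohort draw; replicate mean is ~0.70
res$roc$capra_s$auc
#> [1] 0.854            # CAPRA-S comparator on the same patients
100 * res$confusion_at_threshold$sensitivity
#> [1] 69.7             # recurrent patients below g = 0.93
```

`run_pipeline(run_config(seed = 1), "study_dir")` runs the whole chain on
disk instead: it writes core TIFFs + ROI files + a cohort CSV, measures
every ROI back from the files, and emits `report.json`, ROC/KM curve CSVs
and a stratified-performance table. The run is byte-identical for a fixed
seed.

The published per-stratum operating points are reconstructed (not
simulated) from the printed tables:

```r
v <- verify_published_tables()
all(v$pass)
#> [1] TRUE             # 22 checks: counts, margins, sens/spec per stratum
```

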