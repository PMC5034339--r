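---
title: "Stromal scattering anisotropy from quantitative phase images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stromal scattering anisotropy from quantitative phase images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpianiso)
```

## The measurement model

Quantitative phase imaging (QPI) records, per pixel, the optical
path-length delay $\phi(\mathbf{r})$ (radians) through a thin tissue
section. The scattering-phase theorem links the spatial statistics of
$\phi$ over a region to bulk scattering parameters of the tissue; for the
anisotropy factor $g$ (the mean cosine of the single-scattering angle)
this package uses

$$ g \;=\; 1 \;-\; \frac{\langle |\nabla \phi|^2 \rangle}{2 k_0^2 \,\langle \Delta\phi^2 \rangle}, \qquad k_0 = \frac{2\pi}{\lambda_0}, $$

where $\langle |\nabla\phi|^2\rangle$ is the mean phase-gradient
intensity (rad^2^/µm^2^), $\langle\Delta\phi^2\rangle$ the phase variance
about the regional mean (rad^2^), and $\lambda_0 = 552$ nm the default
center wavelength of a white-light QPI system. Forward-directed
scattering gives $g$ near 1; a more fragmented, disorganized
microstructure raises the gradient content relative to the variance and
lowers $g$. In prostatectomy tissue, low $g$ in the single stromal layer
adjoining cancerous glands has been proposed as a biomarker of
biochemical recurrence (BCR) after surgery; this package implements that
analysis end to end.

Both moments scale as $c^2$ under $\phi \to c\,\phi$, so $g$ is invariant
to any multiplicative rescaling of the phase. Because section thickness
enters the phase multiplicatively for a thin, homogeneous slice, $g$ is
thickness-independent; the test-suite asserts this invariance to float
precision, together with invariance to phase offsets and to 90°
rotations.

Numerical choices:

* gradients use central differences scaled by the physical pixel size;
  pixels whose stencil leaves the region are excluded rather than
  estimated one-sided, which makes the estimator exact on linear ramps;
* the variance is the population variance about the ROI mean, so results
  are offset-invariant;
* regions below `min_pixels` (default 10,000 px) are rejected: on
  stromal-scale textures, smaller regions make the two moments too noisy
  for a stable ratio;
* $g$ values below $-1$ are non-physical for an anisotropy; they are
  returned (pathological inputs stay visible) but flagged;
* a monotone calibration hook is applied to the raw ratio (identity by
  default), mirroring system-specific calibration of measured $g$.

## Synthetic phase fields with known anisotropy

No public imaging data accompany the clinical study, so the package
generates its own ground truth. A stationary zero-mean Gaussian random
field (GRF) with Gaussian covariance
$C(r) = \sigma^2 e^{-r^2/a^2}$ has
$\langle|\nabla\phi|^2\rangle = 4\sigma^2/a^2$, hence

$$ g_{\mathrm{theory}} = 1 - \frac{2}{k_0^2 a^2}, $$

independent of $\sigma$ — a closed-form oracle reached through exactly
the statistics the measurement chain computes. `generate_grf_phase()`
samples the field by circulant embedding (FFT colouring of white noise),
which reproduces the covariance exactly on the periodic domain;
`corr_length_for_g()` inverts the oracle so textures can be tuned to any
target $g < 1$.

Two discretization guards matter. First, correlation lengths below 4
pixels are rejected: the central-difference gradient of an unresolved
texture is badly aliased. Second, even above that limit the finite
stencil underestimates $\langle|\nabla\phi|^2\rangle$ slightly (the
stencil spans $2h$), biasing $g$ upward by about $+0.006$ at $a = 4.7$ px
and less for smoother fields; the package's accuracy claims
($|g_{\mathrm{meas}} - g_{\mathrm{theory}}| \le 0.01$ on 1024^2^ fields
for $a \ge 5$ px, averaged over seeds) include this bias. The synthetic
tissue cores (`generate_core_image()`) place low-phase elliptical gland
lumens inside annular stromal ROIs whose GRF texture is tuned per gland;
measured ROI values land within ±0.015 of target.

This texture model is a deliberate idealization: real stroma is neither
Gaussian nor isotropic at all scales, and no optical artifacts (halo,
defocus) are simulated. Passing tests therefore demonstrate correctness
of the measurement chain, not fidelity of the texture model to tissue.

## Phase-noise propagation into $\Delta g$

Instrument precision is estimated from a tissue-free background region:
the image is split into non-overlapping windows (at least 20), and the
window-level mean gradient intensity and variance are summarized.
Following the convention that $f_1$ and $f_2$ are the *squares* of those
two statistics, $1-g = \sqrt{f_1/f_2}\,/\,(2k_0^2)$, and the first-order
delta method gives

$$ \Delta g = \frac{1}{2k_0^2}\cdot\frac{1}{2\sqrt{f_1/f_2}}
   \sqrt{\frac{\mathrm{Var}\,f_1}{\bar f_2^2}
       + \frac{\bar f_1^2\,\mathrm{Var}\,f_2}{\bar f_2^4}
       - \frac{2 \bar f_1\,\mathrm{Cov}(f_1, f_2)}{\bar f_2^3}}. $$

The covariance term is essential: both statistics are computed from the
same pixels and are strongly correlated (about 0.9 for white phase
noise), so dropping it overestimates $\Delta g$ roughly threefold. With
it, the propagated value matches the Monte-Carlo spread of single-window
$g$ within a few percent (the tests require 15%). A noiseless constant
background returns $\Delta g = 0$ exactly. Whether a hardware system's
quoted precision derives from windowed statistics or repeated
acquisitions is system-dependent; this implementation defines the
windowed convention and documents it.

## The synthetic cohort

`generate_cohort()` builds a patient table with the structure the
statistics assume, defaulting to the validation-cohort conditions: 192
patients, 33 recurrent; patient-level anisotropy drawn from
$\mathcal N(0.913, 0.028)$ (recurrent) and $\mathcal N(0.932, 0.023)$
(non-recurrent), truncated to $(0,1)$; 6–18 stromal ROIs per patient
with follow-up spanning 2–180 months.

Design choices where the study conditions leave the model open:

* **Hierarchical ROI draws.** ROI-level targets scatter around the
  patient value with `sd_intra = 0.01` rather than being drawn i.i.d.
  from the class distribution; i.i.d. draws would shrink the
  patient-level SD by $\sqrt{n_\mathrm{roi}}$ and destroy the class
  spread the analysis relies on. The intra-patient SD is set well below
  the class SDs so patient means recover the class moments (verified at
  n = 5,000 per class).
* **Survival times.** Exponential event times per class with uniform
  censoring. No event-time model is stated anywhere, so the hazards were
  fixed once at 0.05/month (recurrent; most events within ~3 years) and
  0.0005/month (non-recurrent, nearly event-free), aligning with 3- and
  5-year recurrence-free probabilities in the high-90s for high-$g$
  patients.
* **Covariates.** Pre-surgical PSA is lognormal around the published
  median 5.6 ng/ml with a mild upward shift in the recurrent class
  (keeping PSA a weak predictor, AUC ≈ 0.6); pathology flags use
  class-conditional rates that match the published margins (33 positive
  margins, 14 SVI, 3 EPE of 192) in expectation. Gleason strata are
  sampled from the class-conditional frequencies implied by the
  published per-stratum recurrence rates, or fixed exactly to the
  margins 67/89/14/22 (with 2/11/6/14 recurrent) in `gleason_matched`
  mode.
* **Known infidelity.** The reported class summaries have median ≠ mean
  (0.92 vs 0.913 recurrent; 0.938 vs 0.932 non-recurrent), implying
  left-skewed real distributions that a (truncated) Normal cannot match
  in both moments. Consequences at the fixed 0.93 cutoff: the synthetic
  non-recurrent class puts ~47% of patients below the cutoff (observed
  specificity ~73% in the study would require the skewed shape), and the
  Kaplan–Meier split at 0.93 separates much less sharply than the
  published curves. The generator reproduces the *stated* moments and
  leaves the skew unmodelled rather than guessing a shape; statistics
  that depend only on the recurrent class (for instance the fraction of
  recurrent patients below 0.93, ~73%) and the class-separation AUC
  (~0.70, inside the reported CI 0.64–0.84) are reproduced.

The BCR labelling rule for PSA follow-up series is implemented as a
single predicate, `bcr_label()`: recurrence iff any reading ≥ 0.4 ng/ml,
or some reading ≥ 0.2 ng/ml is followed by strictly increasing values
through the end of the series. "Followed by increasing values" is read
literally — one later decrease voids that trigger point, though a later
reading ≥ 0.2 may re-trigger — and the predicate is checked against a
brute-force suffix scan on thousands of random series.

## Imaging I/O and geometry

Phase maps are stored as single-channel 32-bit IEEE-float TIFFs with a
JSON sidecar (`pixel_size_um`, `wavelength_nm`). Floating-point storage
is required because phase in radians is signed and unbounded; integer
TIFFs are rejected with an explicit error. The package ships a minimal
uncompressed float32 TIFF reader/writer (values outside [0, 1] rule out
the common raster writers for R), and its output is cross-checked in the
tests against an independent scientific TIFF implementation.

ROIs are simple polygons in 0-based pixel units (x = column, y = row),
serialized as JSON (exact round trip) or ImageJ `.roi`/`.zip` (integer
precision). Rasterization uses the even-odd rule on pixel centers at
$(c+0.5, r+0.5)$, implemented as a scanline fill and verified against
brute-force point-in-polygon on random polygons; annular stromal ROIs
are encoded as simple "keyhole" polygons. Mosaics are stitched by grid
arithmetic with a default 10% overlap and linear feather blending in the
overlap strips — equal constant tiles reproduce the constant exactly, a
0|1 pair ramps linearly. No registration is attempted by default (the
original pipeline delegated stitching to an external tool without
registration details), and core crops default to 5,000 × 5,000 px with
zero-padding and an explicit pad fraction when the crop leaves the
mosaic.

## Cohort statistics

* **Aggregation.** ROI-level $g$ is aggregated per patient by mean
  (default), median, or pixel-weighted pooling of the raw moments; the
  aggregation rule is not specified by the source analysis, so it is a
  configurable choice.
* **ANOVA.** Classical equal-variance one-way F test
  (`stats::oneway.test`), cross-checked against a brute-force
  sums-of-squares decomposition.
* **ROC.** AUC by the rank/Mann–Whitney method with ties counted ½,
  identical to brute-force pair counting by construction (and verified
  against it, plus an external implementation). The 95% CI uses a
  stratified bootstrap (cases and controls resampled separately, 2,000
  replicates by default); DeLong's interval is available behind a flag.
  The operating point maximizes Youden's J and is reported as the
  midpoint between adjacent observed scores. Orientation is explicit:
  low anisotropy calls recurrence, high PSA/Gleason/CAPRA-S do.
* **Kaplan–Meier / log-rank.** Product-limit estimation and the
  two-group log-rank test delegate to the survival package, exposed as
  tidy step-function tables with step lookup; they are verified against
  hand product-limit computation and the empirical survival function.
* **CAPRA-S.** PSA points (≤6: 0; 6.01–10: 1; 10.01–20: 2; >20: 3, bins
  half-open at the printed boundaries) + Gleason points (no pattern 4/5:
  0; 3+4: 1; 4+3: 2; GS 8–10: 3) + 2 each for positive margins and SVI +
  1 each for EPE and LNI; groups are 0–2 low, 3–5 intermediate, ≥6 high.
  The rubric maximum is 12 points even though the accompanying text
  quotes "0–11"; grouping uses ≥6, so the discrepancy cannot affect any
  output.
* **Dichotomized and stratified performance** fixes the anisotropy
  threshold at $g = 0.93$ (the only normative boundary; the printed
  low-range endpoints are inconsistent between text and figure legend)
  and cross-tabulates low/high against recurrence within Gleason or
  CAPRA-S strata, reporting the 2×2 counts alongside the rates.
  Percentages are compared to printed values with round-half-up at the
  printed precision; the one cell where the printed value reflects
  truncation (92.8 vs 13/14 = 92.86) is matched at 0.1.

`verify_published_tables()` ties these pieces together: it reconstructs
the integer contingency tables behind every printed per-stratum
percentage with `counts_from_rate()` (round-half-up of n × %), recomputes
sensitivity and specificity from realized score/label vectors, and
checks margins (strata sizes 67/89/14/22 summing to 192, reconstructed
recurrent counts summing to 33) and the overall operating point
(sens 72.7% = 24/33, spec 73.6% = 117/159, printed as 73%/73%).

## Problem sizes and determinism

Every stochastic routine takes an explicit seed, and each stage derives
per-item substreams from the master seed, so the full pipeline is
byte-reproducible: `simulate_study()` → `measure_study()` →
`analyze_study()` run twice with one seed produce identical CSVs and an
identical `report.json`. The test-suite exercises the `tiny` profile
(8 patients, one core each with 2–3 glands at 0.05 µm/px, reduced
bootstrap), which completes in seconds; GRF-oracle recovery uses ten
1024^2^ fields per correlation length; Δg validation uses 144 background
windows against 600 Monte-Carlo draws. The `full` profile carries the
full 192-patient geometry (6–18 ROIs per patient, 5,000-px cores) for
users who want a full-scale synthetic study.

## Known limitations

* The GRF texture and the truncated-Normal class model are idealizations
  chosen for analytic tractability; they validate the software, not the
  biology (see the skew note above).
* Stitching performs no registration and the phase is assumed unwrapped;
  raw interferogram reconstruction is out of scope.
* No scattering mean-free-path output and no sliding-window g maps: g is
  computed per explicit ROI only.
* The exclusion criteria that reduced the source TMA's 217 cases to the
  192 analyzed are unpublished; the synthetic cohort simply starts from
  the 192/33 composition.
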