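---
title: "Methods: OCTA lesion morphometry and outcome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OCTA lesion morphometry and outcome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octacnv)
```

This vignette records the scientific and numerical choices behind
`octacnv`: the processing model, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the
decisions taken where the underlying methodology is conventionally
under-specified.

## 1. Image model and magnification

An en-face OCTA angiogram is a 2-D intensity raster. The default nominal
pixel size, 3000/304 ≈ 9.87 µm/px, corresponds to a 3 × 3 mm macular cube
sampled at 304 × 304 A-scans. Devices calibrate transverse scale for a
standard eye; in longer (myopic) eyes each pixel covers more retina. We
adopt the Bennett-style small-angle approximation in which transverse
magnification is proportional to (AL − 1.82), AL the axial length in mm
and 1.82 mm the distance from the eye's second principal plane to the
nominal corneal vertex:

$$\mathrm{px}_{corr} = \mathrm{px}_{nom}\,\frac{AL - 1.82}{AL_{ref} - 1.82},
\qquad AL_{ref} = 23.95\ \mathrm{mm}.$$

Both constants are configurable. The formula is singular at AL = 1.82 mm;
the plausibility bounds (default 20–36 mm) reject such inputs long before
the singularity. Only the lesion area uses physical units; every other
biomarker is a pixel ratio and therefore magnification-invariant — a
property asserted by test.

## 2. Binarization

Otsu's method maximizes the between-class variance
$\omega_0\omega_1(\mu_0-\mu_1)^2$ over a 256-level histogram. Two choices
matter:

* **Domain.** The threshold is computed over ROI pixels only. The lesion
  is cropped first, so surrounding signal cannot drag the threshold; this
  also means a constant-intensity ROI is an error (no separable classes),
  not a silent all-background mask.
* **Quantization.** Images already within [0, 255] are rounded in place
  (the common 8-bit case is untouched); other ranges are linearly mapped
  to the 256 candidate levels. Foreground is *strictly above* the
  threshold. Ties between candidate thresholds take the lowest level.

The implementation is checked against an exhaustive 256-candidate scan on
random two-mode images.

## 3. Skeletonization and the branch graph

Thinning uses the Zhang–Suen two-subiteration algorithm (8-connectivity,
topology-preserving). Zhang–Suen's crossing-number condition leaves
diagonal-staircase pixels that are not needed for connectivity; naive
branch decomposition would read them as junctions and fragment every
curve. A second pass therefore removes any non-endpoint pixel whose
foreground neighbours remain mutually 8-connected within the punctured
3 × 3 neighbourhood, yielding a minimal 8-connected centerline. This is a
local connectivity-preserving (Hilditch-type) criterion: it cannot
disconnect a curve or delete an endpoint, and closed rings stabilize at
their minimal digital polygon.

Nodes are endpoints (one skeleton neighbour) and junction pixels (three or
more); adjacent junction pixels form one junction cluster
(`n_junctions()`), as in standard skeleton-graph tools. Branches are
corridors of degree-2 pixels between nodes; pure cycles are emitted as
loop branches with chord 0.

**Branch length.** The raw chain-code length (unit and √2 steps)
overestimates smooth curves by up to ~8% (the staircase effect). Branch
path length is therefore measured on a lightly smoothed polyline (moving
average, window 5, endpoints fixed), which leaves straight digital lines
exact and reduces the bias on curved branches to well under 1%. The chord
is the Euclidean distance between the branch's terminal pixel centres.

## 4. The seven biomarkers

| biomarker | definition | units / range |
|---|---|---|
| CNV size | \|ROI\| · px² | mm² |
| vessel density (VD) | 100·\|vessel\|/\|ROI\| | % |
| vessel length density (VLD) | 100·\|skeleton\|/\|ROI\| | % |
| diameter index | VD/VLD | ≥ 1, NA if VLD = 0 |
| tortuosity | mean over eligible branches of path/chord | ≥ 1 |
| fractal dimension | box-count log-log slope | [0, 2] |
| lacunarity | mean over ladder of var/mean² of box mass | ≥ 0 |

Tortuosity aggregation is the **unweighted mean over branches** ("each
branch" ratio, then average); loops (chord 0) and branches shorter than
`min_branch_length` (default 3 px) are excluded and counted in the QC
sidecar. Length-weighting was the main alternative; unweighted was chosen
because the source convention describes a per-branch ratio with no weight,
and the exclusion counts make the denominator auditable.

**Box ladder.** Powers of two from 2 px to ⌊min(dim)/4⌋ of the ROI
bounding box, anchored at the bounding-box origin. At least four boxes
along the short side keeps counts informative; fewer than three usable
sizes is an error. The fractal dimension is the least-squares slope of
log N(s) on log(1/s); the fit's R² is reported and a warning is raised
below 0.95 (the value is still returned). On exactly self-similar
fixtures the grid-aligned ladder recovers the closed form to machine
precision (Sierpinski depth 7 → 1.58496).

**Lacunarity** uses overlapping (gliding, stride 1) boxes and the
population variance: Λ(r) = var(mass)/mean(mass)². A translation-invariant
grid gives Λ = 0 at every r; a single pixel in an n-pixel grid gives
Λ(1) = n − 1 (closed form, asserted by test). The reported summary is the
unweighted mean of Λ(r) over the ladder; the per-size curve is kept in the
QC sidecar, so no information is lost to the summary choice.

**Substrate.** Whether complexity metrics are computed on the skeleton or
on the binarized lesion is ambiguous in common practice; the default is
the **skeleton** (the antecedent vessel-morphometry literature measures
branching complexity) with `fd_substrate = "binary"` available, and the
choice echoed in the QC sidecar.

## 5. Cohort statistics

* **Outcome**: gain ≥ 15 ETDRS letters at 12 months, boundary inclusive.
* **Chi-square**: uncorrected Pearson on 2 × 2 counts. The continuity
  correction is deliberately off: the uncorrected statistic exactly
  reproduces the published p-values from the published counts, which
  fixes the convention the source used. Zero margins are an error naming
  the margin.
* **Mann–Whitney**: exact enumeration of all labelings when
  n₁ + n₂ ≤ 12 with no ties (two-sided p as the probability of a U at
  least as far from its null mean); otherwise the normal approximation
  with tie correction, continuity correction off by default
  (configurable). The approximation agrees with a 10⁵-permutation oracle
  within Monte-Carlo error in test.
* **Logistic regression**: standard non-penalized ML (IRLS, log-likelihood
  tolerance 1e-8, max 100 iterations), Wald CIs and p-values (the SPSS
  convention). For binary predictors with positive cells the MLE equals
  ad/bc exactly; a zero cell (separation) flags the result and suppresses
  the Wald CI. Binary predictor codings follow the published table
  directions (EZ/ELM grade 0 = 1, age < 55 = 1, subretinal fluid
  absent = 1, qualitative OCTA features present = 1) and each result
  carries its `predictor_coding` string. Age enters the screening as the
  binary < 55 indicator — the published univariable OR (3.429 = 120/35)
  is only consistent with that coding.
* **Screening**: variables with univariable p < 0.1 enter one joint
  multivariable model; the rule is monotone in the threshold (tested).
* **Missing data**: complete-case per analysis, exclusions logged. No
  multiplicity correction anywhere, by design.

## 6. What the synthetic generators emulate

**Vessel networks** are thick polylines with sinusoidal perpendicular
wiggle in separated horizontal lanes, plus optional closed elliptical
loops; intensities are two-level with additive Gaussian noise. The
generator returns the exact drawn mask and per-branch arc/chord ratios.
This exercises thresholding, thinning, branch tracing and the ratio
metrics with checkable ground truth. It does **not** emulate real OCTA
texture: no speckle correlation, projection artifacts, branching trees,
crossing vessels or intensity gradients. A green recovery test therefore
establishes that the measurement chain is unbiased on clean geometry —
not that it is robust to device artifacts.

**Cohorts** draw continuous variables from truncated normals at the
published group means/SDs (truncation: letters in [0, 100], SFCT ≥ 10 µm,
tortuosity ≥ 1, etc.) and binary variables as Bernoulli at the published
group proportions. The ≥ 55-year indicator is derived from the drawn age
rather than drawn independently, keeping records internally coherent at
the cost of a slightly different marginal proportion. VLD is capped at VD
and the diameter index is computed as VD/VLD, so the biomarker identities
hold record-wise. When `constrain_outcome` is on, the 12-month BCVA is
drawn so the letter gain matches the group label (truncated at the
15-letter boundary); the null spec pools both groups and draws the
12-month value freely. Variables are drawn independently within a record:
real clinical correlations (age with SFCT, say) are not emulated, so the
generator calibrates test size and power, not multivariable adjustment
behaviour.

## 7. Null calibration: what is attainable

With 17 + 17 eyes, the uncorrected chi-square is a *discrete* test: its
exact size at nominal 0.05 depends on the success probability. By full
binomial enumeration, the exact size is 0.054–0.058 for mid-range
proportions but 0.037 for the cohort's sex split (30/34 female). The
Mann–Whitney normal approximation has exact size 0.0487 at this n.
Consequently a per-variable band of 0.05 ± 0.01 over 2,000 seeds cannot
hold for every variable in this cohort — the sex variable sits outside it
in expectation, and edge variables cross it by Monte-Carlo noise. The
per-variable assertion is kept (and fails, documented); the pooled
rejection rate per procedure, which the stated cohort can deliver, is
asserted separately and holds.

## 8. Known limitations

* Raster I/O is plain-text PGM/CSV (PNG optional); no TIFF/DICOM.
* The ROI is always reader-supplied; no lesion segmentation.
* Skeleton-derived metrics inherit thinning's small-scale arbitrariness:
  branch counts are exact only for non-touching vessels; junction-dense
  plexuses will differ by ±1 branch from intuition near junction
  clusters.
* Continuous-predictor odds ratios are per unit and depend on variable
  scaling; they are reported but cannot be validated against published
  per-eye data.
* The multivariable model is fitted on whatever passes screening; with
  17 + 17 eyes and several predictors the Wald CIs are wide and
  separation is common — both conditions are flagged, not repaired.
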