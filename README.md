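# octacnv

Quantitative morphometry of choroidal neovascularization (CNV) on en-face
OCT angiography, and the two-group cohort statistics used to find baseline
predictors of visual gain after anti-VEGF therapy in highly myopic eyes.

## The problem

Myopic CNV is imaged with OCT angiography as an en-face map of the
neovascular complex. Clinicians want reproducible numbers for how large,
dense, thick, twisted and complex the lesion is, and then want to know which
baseline measurements predict a clinically significant visual gain
(≥ 15 ETDRS letters at 12 months). `octacnv` implements both halves:

**Lesion morphometry.** Given a grayscale en-face angiogram, a
reader-drawn region of interest (ROI) around the CNV complex, and the eye's
axial length *AL*:

1. *Magnification correction.* Long eyes magnify differently; the true
   pixel size is `nominal × (AL − 1.82) / (AL_ref − 1.82)` with
   `AL_ref = 23.95` mm (Bennett-style scaling; areas scale with the
   square).
2. *Otsu binarization* over ROI pixels only: the threshold maximizes the
   between-class variance of the 256-level histogram.
3. *Skeletonization* by topology-preserving thinning to a one-pixel-wide,
   8-connected centerline, decomposed into branches between endpoints and
   junction clusters.
4. Seven biomarkers: CNV size (mm²), vessel density
   `VD = 100·|vessel|/|ROI|`, vessel length density
   `VLD = 100·|skeleton|/|ROI|`, vessel diameter index `VD/VLD`,
   tortuosity (mean over branches of path length / chord length, ≥ 1),
   box-counting fractal dimension (slope of log N(s) vs log 1/s over a
   power-of-two box ladder), and gliding-box lacunarity
   (mean over the ladder of var/mean² of box mass).

**Cohort statistics.** Eyes are grouped by the inclusive ≥ 15-letter rule;
continuous variables are compared with the Mann-Whitney U test (exact for
tiny samples, tie-corrected normal approximation otherwise), categorical
ones with the uncorrected Pearson chi-square,
`χ² = n(ad − bc)²/((a+b)(c+d)(a+c)(b+d))`. Predictors are screened by
univariable logistic regression (Wald CI `exp(β ± 1.96·SE)`; for a binary
predictor the MLE odds ratio equals `ad/bc`); variables with univariable
p < 0.1 enter one multivariable logistic model. Letter change is regressed
on baseline subfoveal choroidal thickness (OLS + Pearson r), and compared
between ellipsoid-zone grades.

A synthetic-data module generates vessel networks, fractal fixtures and
two-group cohorts with exact ground truth, so the whole pipeline is
testable without patient data.

## Worked example

```r
library(octacnv)

# a synthetic angiogram with known ground truth
spec <- vessel_network_spec(image_size = 304, n_branches = 6,
                            thickness = 3, wiggle_amplitude = 6,
                            noise_sd = 10, seed = 42)
net <- make_vessel_network(spec)
img <- en_face_image(net$image, nominal_pixel_size = 3000 / 304,
                     axial_length = 29.20)
roi <- roi_mask(matrix(TRUE, 304, 304), img)
compute_biomarkers(img, roi)
#> <biomarker_set>
#>   cnv_size               13.78
#>   vessel_density         6.311
#>   vessel_length_density  1.806
#>   vessel_diameter_index  3.494
#>   vessel_tortuosity      1.021
#>   fractal_dimension      1.065
#>   lacunarity             7.438
```

The whole 304×304 frame is the ROI here, so `cnv_size` is the full frame
area at the magnification-corrected pixel size (12.21 µm/px at
AL 29.20 mm); density is low because six vessels cover ~6% of the frame;
the diameter index ≈ 3.5 matches the 3-px drawing pen; tortuosity 1.021
recovers the generator's ground truth 1.018 within 0.3%.

```r
d <- make_cohort(cohort_spec(seed = 1))   # 17 + 17 eyes, realistic groups
res <- screen_and_fit_multivariable(
  d, c("age", "sfct", "cft", "ez_grade", "elm_grade", "cnv_size",
       "fractal_dimension"))
res$selected
#> [1] "sfct"     "cnv_size"
linear_regression_change(d, "sfct")
#> slope 0.312, r = 0.469, p = 0.0052
```

Thicker subfoveal choroid predicts larger letter gains in this draw, as in
the cohort whose group parameters the generator copies.

## Command line

```sh
octacnv simulate    --spec spec.json --out sim/
octacnv morphometry --images img/ --rois roi/ --al-table al.csv \
                    --config cfg.json --out results/
octacnv cohort      --cohort cohort.csv --out results/
```

Exit status: 0 clean, 1 partial per-eye failures, 2 config/schema error.
Every run writes `run_report.json` with per-stage logs and output
checksums.

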