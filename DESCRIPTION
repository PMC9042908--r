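Package: octacnv
Title: Quantitative Morphometry of OCTA Neovascular Lesions and Cohort
    Statistics for Myopic CNV
Version: 0.1.0
Authors@R: person("OCTA", "Morphometry Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies choroidal neovascularization (CNV) lesions on en-face
    optical coherence tomography angiography (OCTA) images: axial-length
    magnification correction, Otsu binarization within a reader-supplied
    region of interest, topology-preserving skeletonization with branch
    decomposition, vessel density, vessel length density, vessel diameter
    index, branch tortuosity, box-counting fractal dimension and gliding-box
    lacunarity. Also implements the downstream two-group cohort analysis for
    anti-VEGF visual-outcome studies: chi-square and Mann-Whitney group
    comparisons, univariable and multivariable logistic regression with a
    p-value entry rule, and linear regression of visual-acuity change.
    Includes synthetic generators for vessel networks, fractal fixtures and
    clinical cohorts with known ground truth, plus a file-based pipeline and
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
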