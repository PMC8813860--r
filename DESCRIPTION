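Package: vortexatlas
Title: Right-Ventricular Flow Vorticity and Biventricular Shape Atlas Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking intracardiac 4D-flow vorticity to biventricular shape.
    Implements velocity-field preprocessing for phase-contrast MRI style data
    (phase-velocity antialiasing, background phase correction, pluggable
    denoising), vorticity quantification as the curl of the velocity field with
    spherical region-of-interest summaries over diastolic windows and body
    surface area indexing, transvalvular flow volumes by plane flux integration,
    a statistical shape atlas of corresponded biventricular surface point sets
    (generalized Procrustes alignment of end-diastolic geometry applied to
    end-systole, principal component analysis of the concatenated shapes,
    projection scoring, chamber volumes and mass by mesh integration), and an
    association layer (Bonferroni-corrected univariate correlations, group
    comparisons, covariate-adjusted regression producing morphometric shape
    modes). A synthetic-data module supplies shape populations and analytic
    flow phantoms with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
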