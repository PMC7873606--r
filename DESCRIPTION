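Package: tractfd
Title: Along-Tract Tractometry of Paired Hemispheres with Fixel-Based
    Fiber Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for bihemispheric along-tract analysis of white-matter
    bundles in diffusion MRI. Simulates paired-hemisphere diffusion-weighted
    phantoms with a lateralized focal lesion; fits the diffusion tensor by
    iteratively reweighted linear least squares and derives FA/ADC maps;
    estimates fiber orientation distributions by constrained spherical
    deconvolution; performs probabilistic FOD-based tractography; resamples
    streamlines to 100 equal-arc-length segments and extracts per-segment
    median profiles; segments FODs into fixels and computes tract-specific
    apparent fiber density in four steps; and runs the segment-wise
    hemispheric statistics (linear mixed models with a random subject
    intercept, Bonferroni-corrected paired tests, Cliff's delta effect
    gating, and lesional-segment detection sensitivity/specificity).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
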