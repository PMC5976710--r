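Package: ablafuse
Title: CT to Cone-Beam CT Fusion for Intraprocedural Liver Ablation Assessment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Multimodal fusion of pre-ablation contrast-enhanced CT with
    intraprocedural contrast-enhanced cone-beam CT (CBCT) of the liver, and
    quantitative assessment of thermal-ablation completeness. Implements the
    four-step registration scheme (resampling at CBCT resolution, three-landmark
    rigid initialisation, normalized-mutual-information driven affine and cubic
    B-spline free-form registration), the supporting segmentation stack
    (Perona-Malik diffusion denoising, fast-marching plus geodesic active
    contour liver segmentation, fuzzy c-means plus random-walker lesion
    segmentation), residual-tumor and ablative-margin quantification with a
    retreatment classification, summary statistics for five-point reader
    scores, and a synthetic liver phantom generator with ground-truth
    deformations for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
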