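Package: asdlmri
Title: Adaptive-Size Dictionary Learning for Undersampled MRI Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs magnetic-resonance images from undersampled k-space
    measurements by alternating patch-based dictionary learning with a
    closed-form k-space data-consistency update. The dictionary size is
    adapted online: atoms are ranked by representation power and candidate
    sub-dictionary sizes are scored with information-theoretic criteria
    (extended BIC and extended renormalized maximum likelihood), so the
    number of atoms grows or shrinks to match the content of the image being
    reconstructed. Includes Shepp-Logan-style phantom and k-space sampling
    mask generators, orthogonal matching pursuit and approximate K-SVD
    routines, and PSNR/SNR/high-frequency-error-norm quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
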